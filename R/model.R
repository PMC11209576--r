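# Full model assembly: shared backbone -> cross-mammogram attention ->
# (bilateral contrastive loss, dual classification heads) -> weighted
# joint objective.

#' Model configuration
#'
#' The defaults describe the full-size network: 1280 x 640 breast inputs,
#' 1280 feature channels on a 40 x 20 map, 8 attention heads, 5 x 5
#' contrastive patches, loss weights 5/6 and 1/6. Reduced configurations
#' (smaller inputs and widths) are used for desk-scale experiments; any
#' input size divisible by 32 whose feature map is divisible by `patchK`
#' is valid.
#'
#' @param inputHeight,inputWidth breast input size (multiples of 32).
#' @param stageChannels backbone stage widths.
#' @param featureChannels feature channels C of the extractor output.
#' @param heads attention head count M.
#' @param scaleMode,roleSplit see [attentionConfig()].
#' @param patchK contrastive patch size k.
#' @param temperature contrastive temperature t.
#' @param eps similarity stabilisation constant.
#' @param headHidden,headDropout classification head width and dropout.
#' @param u1,u2 joint loss weights.
#' @return list of class `ModelConfig`.
#' @export
modelConfig <- function(inputHeight = 1280L, inputWidth = 640L,
                        stageChannels = c(16L, 32L, 64L, 128L, 256L),
                        featureChannels = 1280L, heads = 8L,
                        scaleMode = "sqrt_dim", roleSplit = "segment",
                        patchK = 5L, temperature = 0.5, eps = 1e-6,
                        headHidden = 512L, headDropout = 0.2,
                        u1 = 5 / 6, u2 = 1 / 6) {
  stopifnot(inputHeight %% 32L == 0L, inputWidth %% 32L == 0L,
            u1 > 0, u2 > 0, temperature > 0)
  fh <- inputHeight %/% 32L; fw <- inputWidth %/% 32L
  if (fh %% patchK != 0L || fw %% patchK != 0L) {
    stop("patchK = ", patchK, " must divide the ", fh, " x ", fw,
         " feature map")
  }
  attn <- attentionConfig(featureChannels, heads, scaleMode, roleSplit)
  structure(list(inputHeight = as.integer(inputHeight),
                 inputWidth = as.integer(inputWidth),
                 stageChannels = as.integer(stageChannels),
                 featureChannels = as.integer(featureChannels),
                 attention = attn, patchK = as.integer(patchK),
                 temperature = temperature, eps = eps,
                 headHidden = as.integer(headHidden),
                 headDropout = headDropout, u1 = u1, u2 = u2,
                 featureHeight = fh, featureWidth = fw),
            class = "ModelConfig")
}

#' Desk-scale model configuration
#'
#' A reduced configuration for CPU experiments on 256 x 256 synthetic
#' views: 512 x 256 concatenated inputs, a slim backbone, 256 feature
#' channels on a 16 x 8 map, and 4 x 4 contrastive patches (the largest
#' patch size dividing that map on both axes).
#'
#' @param ... overrides passed to [modelConfig()].
#' @export
deskConfig <- function(...) {
  args <- list(inputHeight = 512L, inputWidth = 256L,
               stageChannels = c(8L, 16L, 24L, 32L, 48L),
               featureChannels = 256L, heads = 8L, patchK = 4L,
               headHidden = 128L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(modelConfig, args)
}

#' Build the full bilateral classification model
#'
#' @param cfg a [modelConfig()].
#' @param seed RNG seed for all weight initialization.
#' @return object of class `CrossMammoModel`.
#' @export
buildModel <- function(cfg = modelConfig(), seed = 1L) {
  withSeed(seed, {
    structure(list(
      backbone = buildBackbone(3L, cfg$stageChannels,
                               cfg$featureChannels),
      attention = buildCrossAttention(cfg$attention),
      headLeft = buildHead(cfg$featureChannels, cfg$headHidden,
                           cfg$headDropout),
      headRight = buildHead(cfg$featureChannels, cfg$headHidden,
                            cfg$headDropout),
      cfg = cfg), class = "CrossMammoModel")
  })
}

#' @export
print.CrossMammoModel <- function(x, ...) {
  cat(sprintf(
    paste0("CrossMammoModel: input %d x %d, C = %d, %d heads (d = %d), ",
           "patch k = %d, %s parameters\n"),
    x$cfg$inputHeight, x$cfg$inputWidth, x$cfg$featureChannels,
    x$cfg$attention$heads, x$cfg$attention$d, x$cfg$patchK,
    format(paramCount(modelParams(x)), big.mark = ",")))
  invisible(x)
}

modelParams <- function(model) {
  list(backbone = backboneParams(model$backbone),
       attention = model$attention$params,
       headLeft = model$headLeft$params,
       headRight = model$headRight$params)
}

setModelParams <- function(model, params) {
  model$backbone <- setBackboneParams(model$backbone, params$backbone)
  model$attention$params <- params$attention
  model$headLeft$params <- params$headLeft
  model$headRight$params <- params$headRight
  model
}

#' Forward pass for one case
#'
#' @param model a `CrossMammoModel`.
#' @param xL,xR breast input arrays `H x W x 3`.
#' @param yLeft,yRight labels (needed for the contrastive branch and the
#'   losses; may be omitted for pure prediction).
#' @param train training mode (dropout active)?
#' @param cache keep intermediates for [modelBackward()]?
#' @return list with per-breast scores/probabilities and, when labels are
#'   given, the loss components (`lSim`, `lClsLeft`, `lClsRight`, `loss`).
#' @export
modelForward <- function(model, xL, xR, yLeft = NULL, yRight = NULL,
                         train = FALSE, cache = FALSE) {
  cfg <- model$cfg
  bL <- backboneForward(model$backbone, xL, cache = cache)
  bR <- backboneForward(model$backbone, xR, cache = cache)
  fl <- if (cache) bL$out else bL
  fr <- if (cache) bR$out else bR
  at <- crossAttentionForward(model$attention, fl, fr, cache = cache)
  hL <- headForward(model$headLeft, at$FL2, train = train, cache = cache)
  hR <- headForward(model$headRight, at$FR2, train = train, cache = cache)
  out <- list(scoreLeft = hL$score, scoreRight = hR$score,
              probLeft = hL$prob, probRight = hR$prob)
  withLoss <- !is.null(yLeft) && !is.null(yRight)
  if (withLoss) {
    contrast <- bilateralContrastLoss(at$FL2, at$FR2, yLeft, yRight,
                                      k = cfg$patchK,
                                      temperature = cfg$temperature,
                                      eps = cfg$eps, grad = cache)
    out$lSim <- contrast$loss
    out$lClsLeft <- bceLoss(hL$score, yLeft)
    out$lClsRight <- bceLoss(hR$score, yRight)
    out$loss <- totalLoss(out$lSim, out$lClsLeft, out$lClsRight,
                          cfg$u1, cfg$u2)
  }
  if (cache) {
    out$cache <- list(bL = bL$cache, bR = bR$cache, at = at,
                      hL = hL$cache, hR = hR$cache,
                      contrast = if (withLoss) contrast,
                      yLeft = yLeft, yRight = yRight)
  }
  out
}

#' Backward pass for one case
#'
#' Computes gradients of the total joint loss with respect to every
#' parameter. The shared backbone receives the sum of the left- and
#' right-path gradients.
#'
#' @param model a `CrossMammoModel`.
#' @param fwd result of [modelForward()] with `cache = TRUE` and labels.
#' @return nested gradient list parallel to the model parameters.
#' @export
modelBackward <- function(model, fwd) {
  cfg <- model$cfg
  cc <- fwd$cache
  dScoreL <- cfg$u2 * drop(bceGrad(fwd$scoreLeft, cc$yLeft))
  dScoreR <- cfg$u2 * drop(bceGrad(fwd$scoreRight, cc$yRight))
  gHL <- headBackward(model$headLeft, cc$hL, dScoreL)
  gHR <- headBackward(model$headRight, cc$hR, dScoreR)
  dFL2 <- gHL$dFm + cfg$u1 * cc$contrast$dFL2
  dFR2 <- gHR$dFm + cfg$u1 * cc$contrast$dFR2
  gAt <- crossAttentionBackward(model$attention, cc$at$cache, dFL2, dFR2)
  gBL <- backboneBackward(model$backbone, cc$bL, gAt$dFL)
  gBR <- backboneBackward(model$backbone, cc$bR, gAt$dFR)
  list(backbone = addGrads(gBL$grads, gBR$grads),
       attention = gAt$grads,
       headLeft = gHL$grads,
       headRight = gHR$grads)
}

#' Predict per-breast cancer probabilities for prepared inputs
#'
#' @param model a `CrossMammoModel`.
#' @param xL,xR breast input arrays.
#' @return named numeric vector `c(left = , right = )`.
#' @export
predictBreasts <- function(model, xL, xR) {
  fwd <- modelForward(model, xL, xR)
  c(left = fwd$probLeft, right = fwd$probRight)
}

#' Prepare a case for the model
#'
#' Optionally preprocesses each raw view (orientation, crop, CLAHE,
#' truncated normalization), then concatenates CC above MLO per breast at
#' the configured input size with the grayscale channel replicated.
#'
#' @param case a [MammoCase-class].
#' @param cfg a [modelConfig()].
#' @param preprocess run [preprocessView()] on each view first?
#' @return list `(xL, xR, yLeft, yRight, caseId)`.
#' @export
prepareCase <- function(case, cfg, preprocess = TRUE) {
  pv <- function(v) if (preprocess) preprocessView(v) else toUnitRange(v)
  xL <- concatViews(pv(case@views$L_CC), pv(case@views$L_MLO),
                    cfg$inputHeight, cfg$inputWidth)
  xR <- concatViews(pv(case@views$R_CC), pv(case@views$R_MLO),
                    cfg$inputHeight, cfg$inputWidth)
  list(xL = xL, xR = xR, yLeft = case@yLeft, yRight = case@yRight,
       caseId = case@caseId)
}

#' Save / load model checkpoints
#'
#' @param model a `CrossMammoModel`.
#' @param path file path.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(cfg = model$cfg, params = modelParams(model)), path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  setModelParams(buildModel(ck$cfg, seed = 0L), ck$params)
}
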