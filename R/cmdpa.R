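# Cross-mammogram dual-pathway multi-head attention. Each breast's feature
# map is flattened to L = H*W tokens; a per-breast linear branch maps the
# C-dimensional tokens to 3C channels; the channel axis is cut into M
# contiguous head segments of width d = 3C/M. For head i, the own-side
# segment acts as the Query and the contralateral segment acts as both Key
# and Value, so each local feature attends over the full contralateral
# token set. Head outputs are concatenated and projected back to C, and
# the token matrix is reshaped to the original spatial layout, giving
# reconstructed maps FL'' and FR'' with unchanged shape.
#
# The conventional three-way split (Q/K/V thirds, d = C/M) is available as
# roleSplit = "qkv"; dot products are scaled by the key dimension d
# (scaleMode "dim") or by sqrt(d) ("sqrt_dim").

#' Attention configuration for the cross-mammogram module
#'
#' @param channels feature channels C of the input maps.
#' @param heads number of attention heads M (default 8).
#' @param scaleMode `"sqrt_dim"` (default) divides dot products by
#'   sqrt(d), the standard scaled dot-product convention; `"dim"` divides
#'   by the key dimension d itself, which shrinks the logits so strongly
#'   that attention stays near-uniform and trains poorly.
#' @param roleSplit `"segment"`: Q, K and V of head i are the same
#'   d = 3C/M channel segment, with the role set by breast side;
#'   `"qkv"`: conventional disjoint Q/K/V thirds with d = C/M.
#' @return list of class `AttentionConfig`.
#' @export
attentionConfig <- function(channels, heads = 8L,
                            scaleMode = c("sqrt_dim", "dim"),
                            roleSplit = c("segment", "qkv")) {
  scaleMode <- match.arg(scaleMode)
  roleSplit <- match.arg(roleSplit)
  channels <- as.integer(channels)
  heads <- as.integer(heads)
  if (roleSplit == "segment") {
    if ((3L * channels) %% heads != 0L) {
      stop("3*channels must be divisible by the head count")
    }
    d <- (3L * channels) %/% heads
  } else {
    if (channels %% heads != 0L) {
      stop("channels must be divisible by the head count")
    }
    d <- channels %/% heads
  }
  if (d < 1L) stop("per-head dimension must be >= 1")
  structure(list(channels = channels, heads = heads, d = d,
                 scaleMode = scaleMode, roleSplit = roleSplit,
                 scale = if (scaleMode == "dim") d else sqrt(d)),
            class = "AttentionConfig")
}

# Column indices of Q, K, V for each head.
headIndices <- function(cfg) {
  M <- cfg$heads; d <- cfg$d; C <- cfg$channels
  lapply(seq_len(M), function(i) {
    seg <- ((i - 1L) * d + 1L):(i * d)
    if (cfg$roleSplit == "segment") list(q = seg, k = seg, v = seg)
    else list(q = seg, k = C + seg, v = 2L * C + seg)
  })
}

#' Flatten a feature map to its token matrix
#'
#' Spatial positions are enumerated row-major: token `(r-1)*W + c`
#' corresponds to map position (r, c). The operation is exactly inverted
#' by [tokensToMap()].
#'
#' @param fm feature map array `H x W x C`.
#' @return `L x C` matrix with attribute `mapDim`.
#' @export
tokensFromMap <- function(fm) {
  d <- dim(fm)
  t_ <- matrix(aperm(fm, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
  attr(t_, "mapDim") <- d
  t_
}

#' Reshape a token matrix back to its spatial feature map
#'
#' @param tokens `L x C` matrix (row-major token order).
#' @param h,w spatial size; defaults to the `mapDim` attribute.
#' @return feature map array `h x w x C`.
#' @export
tokensToMap <- function(tokens, h = NULL, w = NULL) {
  if (is.null(h)) {
    d <- attr(tokens, "mapDim")
    h <- d[1]; w <- d[2]
  }
  aperm(array(tokens, dim = c(w, h, ncol(tokens))), c(2L, 1L, 3L))
}

#' Project tokens through a per-breast linear branch
#'
#' @param tokens `L x C` token matrix.
#' @param weights list `(w, b)`: a `C x 3C` weight and 3C bias.
#' @return `L x 3C` projected token matrix.
#' @export
projectTokens <- function(tokens, weights) {
  linearForward(weights, tokens)
}

#' Cut a projected token matrix into per-head Q/K/V segments
#'
#' @param p `L x 3C` projected tokens.
#' @param cfg an [attentionConfig()].
#' @param role which role's columns to extract (`"q"`, `"k"`, `"v"`).
#' @return array `L x d x M`.
#' @export
splitHeads <- function(p, cfg, role = "q") {
  idx <- headIndices(cfg)
  out <- array(0, dim = c(nrow(p), cfg$d, cfg$heads))
  for (i in seq_len(cfg$heads)) out[, , i] <- p[, idx[[i]][[role]]]
  out
}

#' Scaled dot-product cross-attention over contralateral tokens
#'
#' Per head: `softmax(Q K^T / scale) V`, the softmax running over the
#' contralateral positions so every attention-weight row sums to one.
#'
#' @param qh,kh,vh arrays `L x d x M` (query from the own side, key and
#'   value from the contralateral side).
#' @param cfg an [attentionConfig()].
#' @param returnWeights also return the `L x L x M` attention weights?
#' @return array `L x d x M`, or a list `(out, weights)`.
#' @export
crossAttend <- function(qh, kh, vh, cfg, returnWeights = FALSE) {
  L <- dim(qh)[1]
  out <- array(0, dim = dim(qh))
  wts <- if (returnWeights) array(0, dim = c(L, dim(kh)[1], cfg$heads))
  for (i in seq_len(cfg$heads)) {
    s <- (qh[, , i] %*% t(kh[, , i])) / cfg$scale
    a <- softmaxRows(s)
    out[, , i] <- a %*% vh[, , i]
    if (returnWeights) wts[, , i] <- a
  }
  if (returnWeights) list(out = out, weights = wts) else out
}

#' Merge attention heads and project back to the feature map
#'
#' Head outputs are concatenated along channels and linearly projected to
#' C, then reshaped row-major to the spatial layout.
#'
#' @param headedOut array `L x d x M`.
#' @param weights output projection `(w, b)` with `M*d x C` weight.
#' @param h,w spatial size of the output map.
#' @return feature map array `h x w x C`.
#' @export
mergeAndProject <- function(headedOut, weights, h, w) {
  L <- dim(headedOut)[1]
  concat <- matrix(headedOut, nrow = L)  # L x (d*M), heads contiguous
  tokensToMap(linearForward(weights, concat), h, w)
}

#' Build the cross-attention module parameters
#'
#' Two per-breast input branches (C -> 3C) and two per-path output
#' projections back to C.
#'
#' @param cfg an [attentionConfig()].
#' @param seed optional RNG seed.
#' @return object of class `mcCrossAttention`.
#' @export
buildCrossAttention <- function(cfg, seed = NULL) {
  C <- cfg$channels
  outIn <- cfg$d * cfg$heads
  build <- function() list(
    projL = makeLinear(C, 3L * C), projR = makeLinear(C, 3L * C),
    outL = makeLinear(outIn, C), outR = makeLinear(outIn, C))
  params <- if (is.null(seed)) build() else withSeed(seed, build())
  structure(list(params = params, cfg = cfg), class = "mcCrossAttention")
}

#' Dual-pathway forward pass
#'
#' Left path: queries from the left breast, keys/values from the right;
#' right path symmetric. Output shapes equal input shapes.
#'
#' @param attn an `mcCrossAttention`.
#' @param fl,fr feature maps `H x W x C` (equal shapes).
#' @param cache keep intermediates for the backward pass?
#' @return list `(FL2, FR2)` of reconstructed maps (plus `cache`).
#' @export
crossAttentionForward <- function(attn, fl, fr, cache = FALSE) {
  if (!identical(dim(fl), dim(fr))) stop("feature map shape mismatch")
  cfg <- attn$cfg
  if (dim(fl)[3] != cfg$channels) {
    stop("feature maps must have ", cfg$channels, " channels")
  }
  H <- dim(fl)[1]; W <- dim(fl)[2]
  p <- attn$params
  alRaw <- tokensFromMap(fl); arRaw <- tokensFromMap(fr)
  # token-wise layer norm before the projections (pre-LN) keeps the
  # attention logits well-scaled for any upstream initialization
  lnL <- layerNormRowsForward(alRaw)
  lnR <- layerNormRowsForward(arRaw)
  al <- lnL$y; ar <- lnR$y
  pl <- projectTokens(al, p$projL); pr <- projectTokens(ar, p$projR)
  idx <- headIndices(cfg)
  L <- nrow(al)
  onePath <- function(pOwn, pOther) {
    o <- array(0, dim = c(L, cfg$d, cfg$heads))
    aw <- vector("list", cfg$heads)
    for (i in seq_len(cfg$heads)) {
      q <- pOwn[, idx[[i]]$q]; k <- pOther[, idx[[i]]$k]
      v <- pOther[, idx[[i]]$v]
      a <- softmaxRows((q %*% t(k)) / cfg$scale)
      o[, , i] <- a %*% v
      aw[[i]] <- a
    }
    list(o = o, aw = aw)
  }
  pathL <- onePath(pl, pr)
  pathR <- onePath(pr, pl)
  outTokL <- linearForward(p$outL, matrix(pathL$o, nrow = L))
  outTokR <- linearForward(p$outR, matrix(pathR$o, nrow = L))
  fl2 <- tokensToMap(outTokL, H, W)
  fr2 <- tokensToMap(outTokR, H, W)
  if (!cache) return(list(FL2 = fl2, FR2 = fr2))
  list(FL2 = fl2, FR2 = fr2,
       cache = list(al = al, ar = ar, lnL = lnL, lnR = lnR,
                    pl = pl, pr = pr,
                    pathL = pathL, pathR = pathR, H = H, W = W, L = L))
}

# Backward pass: gradients w.r.t. both input maps and all four branches.
crossAttentionBackward <- function(attn, cache, dFL2, dFR2) {
  cfg <- attn$cfg
  p <- attn$params
  idx <- headIndices(cfg)
  L <- cache$L
  dOutTokL <- tokensFromMap(dFL2)
  dOutTokR <- tokensFromMap(dFR2)
  gOutL <- linearBackward(p$outL, matrix(cache$pathL$o, nrow = L), dOutTokL)
  gOutR <- linearBackward(p$outR, matrix(cache$pathR$o, nrow = L), dOutTokR)
  dPl <- matrix(0, L, 3L * cfg$channels)
  dPr <- matrix(0, L, 3L * cfg$channels)
  backPath <- function(dO, path, pOwn, pOther, dPOwn, dPOther) {
    dO <- array(dO, dim = c(L, cfg$d, cfg$heads))
    for (i in seq_len(cfg$heads)) {
      q <- pOwn[, idx[[i]]$q]; k <- pOther[, idx[[i]]$k]
      v <- pOther[, idx[[i]]$v]
      a <- path$aw[[i]]
      dOi <- dO[, , i]
      dA <- dOi %*% t(v)
      dV <- t(a) %*% dOi
      dS <- softmaxRowsBackward(a, dA) / cfg$scale
      dQ <- dS %*% k
      dK <- t(dS) %*% q
      dPOwn[, idx[[i]]$q] <- dPOwn[, idx[[i]]$q] + dQ
      dPOther[, idx[[i]]$k] <- dPOther[, idx[[i]]$k] + dK
      dPOther[, idx[[i]]$v] <- dPOther[, idx[[i]]$v] + dV
    }
    list(own = dPOwn, other = dPOther)
  }
  r <- backPath(gOutL$dx, cache$pathL, cache$pl, cache$pr, dPl, dPr)
  dPl <- r$own; dPr <- r$other
  r <- backPath(gOutR$dx, cache$pathR, cache$pr, cache$pl, dPr, dPl)
  dPr <- r$own; dPl <- r$other
  gProjL <- linearBackward(p$projL, cache$al, dPl)
  gProjR <- linearBackward(p$projR, cache$ar, dPr)
  dAl <- layerNormRowsBackward(cache$lnL, gProjL$dx)
  dAr <- layerNormRowsBackward(cache$lnR, gProjR$dx)
  list(dFL = tokensToMap(dAl, cache$H, cache$W),
       dFR = tokensToMap(dAr, cache$H, cache$W),
       grads = list(projL = list(w = gProjL$dw, b = gProjL$db),
                    projR = list(w = gProjR$dw, b = gProjR$db),
                    outL = list(w = gOutL$dw, b = gOutL$db),
                    outR = list(w = gOutR$dw, b = gOutR$db)))
}
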