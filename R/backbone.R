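# Shared stride-32 convolutional feature extractor. Five 3x3 stride-2
# convolutions (cumulative downsampling 32 per axis) followed by a 1x1
# projection to the feature channel count; each convolution is followed by
# per-channel instance normalization and ReLU (the single-image analogue
# of the conv/norm/activation blocks standard in image backbones, which
# keeps deep stacks trainable from random initialization). No pooling and
# no classifier, so the full spatial feature map is preserved. The same
# parameter set is applied to both breasts (weight sharing). With the
# default 1280 feature channels a 1280 x 640 input maps to a
# 1280-channel 40 x 20 feature map: each output position summarises a
# 32 x 32 input block, a 1024-fold reduction of spatial positions.

#' Build the shared breast feature extractor
#'
#' @param inChannels input channels (3: grayscale replicated).
#' @param stageChannels widths of the five stride-2 stages.
#' @param outChannels feature channels of the output map (default 1280).
#' @param seed optional RNG seed for weight initialization.
#' @return object of class `mcBackbone`.
#' @export
buildBackbone <- function(inChannels = 3L,
                          stageChannels = c(16L, 32L, 64L, 128L, 256L),
                          outChannels = 1280L, seed = NULL) {
  build <- function() {
    chans <- c(inChannels, stageChannels)
    layers <- lapply(seq_along(stageChannels), function(i) {
      makeConvLayer(3L, chans[i], chans[i + 1L], stride = 2L, pad = 1L)
    })
    layers$proj <- makeConvLayer(1L, chans[length(chans)], outChannels,
                                 stride = 1L, pad = 0L)
    layers
  }
  layers <- if (is.null(seed)) build() else withSeed(seed, build())
  structure(list(layers = layers, inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels),
                 downsample = as.integer(2^length(stageChannels))),
            class = "mcBackbone")
}

backboneParams <- function(bb) lapply(bb$layers, function(l) l[c("w", "b")])

setBackboneParams <- function(bb, params) {
  for (i in seq_along(bb$layers)) {
    bb$layers[[i]]$w <- params[[i]]$w
    bb$layers[[i]]$b <- params[[i]]$b
  }
  bb
}

checkBackboneInput <- function(bb, x) {
  d <- dim(x)
  if (length(d) != 3L || d[3] != bb$inChannels) {
    stop("input must be an H x W x ", bb$inChannels, " array")
  }
  if (d[1] %% bb$downsample != 0L || d[2] %% bb$downsample != 0L) {
    stop("input height and width must be multiples of ", bb$downsample)
  }
}

#' Forward pass of the feature extractor
#'
#' @param bb an `mcBackbone`.
#' @param x input array `H x W x C`, sides multiples of 32.
#' @param cache keep per-layer inputs for the backward pass?
#' @return feature map array `(H/32) x (W/32) x outChannels`; with
#'   `cache = TRUE`, a list `(out, cache)`.
#' @export
backboneForward <- function(bb, x, cache = FALSE) {
  checkBackboneInput(bb, x)
  inputs <- if (cache) vector("list", length(bb$layers)) else NULL
  norms <- if (cache) vector("list", length(bb$layers)) else NULL
  h <- x
  for (i in seq_along(bb$layers)) {
    if (cache) inputs[[i]] <- h
    z <- convForward(bb$layers[[i]], h)
    nrm <- instNormForward(z)
    if (cache) norms[[i]] <- nrm
    h <- relu(nrm$y)
  }
  if (!cache) return(h)
  list(out = h, cache = list(inputs = inputs, norms = norms))
}

# dOut -> gradients of all conv layers plus the input.
backboneBackward <- function(bb, cache, dOut) {
  grads <- vector("list", length(bb$layers))
  names(grads) <- names(bb$layers)
  dy <- dOut
  for (i in rev(seq_along(bb$layers))) {
    nrm <- cache$norms[[i]]
    dn <- reluBackward(nrm$y, dy)
    dz <- instNormBackward(nrm, dn)
    g <- convBackward(bb$layers[[i]], cache$inputs[[i]], dz)
    grads[[i]] <- list(w = g$dw, b = g$db)
    dy <- g$dx
  }
  list(dx = dy, grads = grads)
}

#' Extract bilateral feature maps with shared weights
#'
#' The identical extractor instance is applied to the left and right
#' breast inputs, so the two pathways share every parameter.
#'
#' @param bb an `mcBackbone`.
#' @param left,right breast input arrays `H x W x C`.
#' @return list `(FL, FR)` of feature maps.
#' @export
extractFeatures <- function(bb, left, right) {
  list(FL = backboneForward(bb, left), FR = backboneForward(bb, right))
}

#' @export
print.mcBackbone <- function(x, ...) {
  cat(sprintf(
    "mcBackbone: stride %d, %d -> %d channels, %s parameters\n",
    x$downsample, x$inChannels, x$outChannels,
    format(paramCount(backboneParams(x)), big.mark = ",")))
  invisible(x)
}
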