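# Grad-CAM explanations. The target layer is the output of the last
# convolution of the shared feature extractor (the attention module and
# the heads contain no convolutions). Channel weights are the spatially
# pooled gradients of the chosen breast's pre-sigmoid cancer score with
# respect to that activation; the weighted, rectified activation sum is
# upsampled to the input size and min-max normalised.

#' Grad-CAM heatmap for one breast of a case
#'
#' @param model a `CrossMammoModel`.
#' @param xL,xR prepared breast inputs (see [prepareCase()]).
#' @param side which breast's cancer score to explain.
#' @return list with `heatmap` (input-sized matrix in [0,1]), `cam`
#'   (feature-map-sized raw map) and `prob` (the predicted probability).
#'   A model with identically zero gradients yields an all-zero map with
#'   a warning.
#' @export
gradCam <- function(model, xL, xR, side = c("left", "right")) {
  side <- match.arg(side)
  cfg <- model$cfg
  bL <- backboneForward(model$backbone, xL, cache = TRUE)
  bR <- backboneForward(model$backbone, xR, cache = TRUE)
  at <- crossAttentionForward(model$attention, bL$out, bR$out,
                              cache = TRUE)
  head <- if (side == "left") model$headLeft else model$headRight
  fm2 <- if (side == "left") at$FL2 else at$FR2
  hf <- headForward(head, fm2, cache = TRUE)
  # d(score)/d(FL2 or FR2), then back through the attention block to the
  # chosen side's backbone activation
  gHead <- headBackward(head, hf$cache, 1)
  zero <- array(0, dim = dim(fm2))
  gAt <- if (side == "left") {
    crossAttentionBackward(model$attention, at$cache, gHead$dFm, zero)
  } else {
    crossAttentionBackward(model$attention, at$cache, zero, gHead$dFm)
  }
  act <- if (side == "left") bL$out else bR$out
  dAct <- if (side == "left") gAt$dFL else gAt$dFR
  weights <- apply(dAct, 3L, mean)
  if (all(weights == 0)) {
    warning("all-zero gradients; returning an empty heatmap")
    cam <- matrix(0, dim(act)[1], dim(act)[2])
  } else {
    cam <- matrix(0, dim(act)[1], dim(act)[2])
    for (c in seq_along(weights)) cam <- cam + weights[c] * act[, , c]
    cam[cam < 0] <- 0
    if (max(cam) > 0) cam <- cam / max(cam)
  }
  heat <- resizeImage(cam, dim(xL)[1], dim(xL)[2])
  heat <- pmin(pmax(heat, 0), 1)
  list(heatmap = heat, cam = cam,
       prob = if (side == "left") {
         sigmoid(hf$score)
       } else sigmoid(hf$score))
}

#' Write a Grad-CAM overlay PNG
#'
#' The grayscale input is rendered with the heatmap blended into the red
#' channel.
#'
#' @param x prepared breast input (array `H x W x 3` or matrix).
#' @param heatmap matrix from [gradCam()].
#' @param path output PNG path.
#' @param alpha blend weight of the heatmap.
#' @export
gradCamOverlay <- function(x, heatmap, path, alpha = 0.5) {
  base <- if (length(dim(x)) == 3L) x[, , 1L] else x
  rgb <- array(0, dim = c(nrow(base), ncol(base), 3L))
  rgb[, , 1] <- pmin(1, (1 - alpha) * base + alpha * heatmap)
  rgb[, , 2] <- (1 - alpha) * base
  rgb[, , 3] <- (1 - alpha) * base
  png::writePNG(rgb, path)
  invisible(path)
}
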