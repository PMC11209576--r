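# Mammogram view preprocessing: orientation normalization, breast-region
# detection and cropping, CLAHE contrast enhancement, percentile-truncated
# normalization. Views are plain numeric matrices (rows = image height),
# either in [0,1] or integer-scaled (8- or 16-bit); outputs are float [0,1].

# Rescale any supported intensity range to [0,1].
toUnitRange <- function(img) {
  mx <- max(img)
  if (mx <= 1) return(img)
  if (mx <= 255) return(img / 255)
  img / 65535
}

checkView <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("a view must be a numeric matrix")
  }
  if (nrow(img) < 1L || ncol(img) < 1L) stop("empty image")
  if (any(img < 0)) stop("intensities must be non-negative")
  invisible(img)
}

# 5x5 Gaussian kernel; sigma follows the common ksize-derived default
# (0.3*((k-1)*0.5 - 1) + 0.8 = 1.1 for k = 5).
gaussianKernel <- function(k = 5L, sigma = 1.1) {
  ax <- seq_len(k) - (k + 1) / 2
  g <- exp(-ax^2 / (2 * sigma^2))
  kern <- outer(g, g)
  kern / sum(kern)
}

smoothImage <- function(img, k = 5L, sigma = 1.1) {
  as.matrix(EBImage::imageData(
    EBImage::filter2(img, gaussianKernel(k, sigma), boundary = "replicate")))
}

#' Orient a mammogram so the breast tissue points to the right
#'
#' Mammograms are acquired with the chest wall on either image edge. To give
#' the model a single orientation convention, the view is mirrored
#' horizontally whenever the bulk of the foreground (tissue above an Otsu
#' threshold on the smoothed image) lies in the left half of the frame.
#' The test is a deterministic comparison of summed foreground intensity in
#' the two half-images, so the operation is idempotent and maps a view and
#' its mirror image to the same output.
#'
#' @param img numeric matrix, one grayscale view (rows = height).
#' @return the view, possibly mirrored, with attribute `flipped` (logical).
#' @export
normalizeOrientation <- function(img) {
  checkView(img)
  u <- toUnitRange(img)
  if (max(u) == 0) stop("degenerate input: all-zero image")
  thr <- EBImage::otsu(smoothImage(u), range = c(0, 1))
  fg <- u * (u > thr)
  w <- ncol(fg)
  half <- w %/% 2
  leftMass <- sum(fg[, seq_len(half)])
  rightMass <- sum(fg[, (w - half + 1L):w])
  flipped <- leftMass > rightMass
  out <- if (flipped) img[, rev(seq_len(w)), drop = FALSE] else img
  attr(out, "flipped") <- flipped
  out
}

#' Detect the breast region of a view
#'
#' Gaussian smoothing (5x5 kernel), Otsu automatic thresholding,
#' connected-component labelling, and the axis-aligned bounding box of the
#' largest foreground component. Ties in component area are broken by the
#' lowest top-left corner (row-major).
#'
#' @param img numeric matrix view.
#' @param file optional file name used in error messages.
#' @return a `BreastBox`: named integer vector (x0, y0, x1, y1), 0-based,
#'   half-open on the right/bottom.
#' @export
detectBreastRegion <- function(img, file = NULL) {
  checkView(img)
  u <- toUnitRange(img)
  if (max(u) == 0) {
    stop("no foreground pixels", if (!is.null(file)) paste0(" in ", file))
  }
  sm <- smoothImage(u)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  bin <- sm > thr
  if (!any(bin)) {
    stop("no foreground after Otsu thresholding",
         if (!is.null(file)) paste0(" in ", file))
  }
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(bin)))
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # lowest top-left corner in row-major order wins
    corner <- vapply(best, function(l) {
      idx <- which(lab == l, arr.ind = TRUE)
      min((idx[, 1] - 1) * ncol(lab) + (idx[, 2] - 1))
    }, numeric(1))
    best <- best[which.min(corner)]
  }
  idx <- which(lab == best, arr.ind = TRUE)
  box <- c(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
           x1 = max(idx[, 2]), y1 = max(idx[, 1]))
  storage.mode(box) <- "integer"
  class(box) <- "BreastBox"
  box
}

cropToBox <- function(img, box) {
  img[(box[["y0"]] + 1L):box[["y1"]], (box[["x0"]] + 1L):box[["x1"]],
      drop = FALSE]
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit, applied on the unit
#' intensity range (16-bit inputs are rescaled first). The default clip
#' limit of 1.0 is deliberately conservative for mammograms, where strong
#' equalization amplifies noise in the fatty tissue.
#'
#' @param img numeric matrix view.
#' @param clipLimit histogram clip limit (default 1.0).
#' @param tileGrid tiles per axis, `c(nx, ny)` (default 8x8).
#' @return matrix in [0,1], same shape.
#' @export
claheEnhance <- function(img, clipLimit = 1.0, tileGrid = c(8L, 8L)) {
  checkView(img)
  u <- toUnitRange(img)
  if (diff(range(u)) == 0) return(u)  # no contrast to redistribute
  h <- nrow(u); w <- ncol(u)
  # keep tiles at least 8 px and the grid within the image; the
  # equalizer needs at least 2 x 2 contextual regions
  nRow <- max(2L, min(tileGrid[2], h %/% 8L))
  nCol <- max(2L, min(tileGrid[1], w %/% 8L))
  # the tile-wise equalizer needs dims divisible by the grid: pad by edge
  # replication, then crop back
  ph <- ceiling(h / nRow) * nRow
  pw <- ceiling(w / nCol) * nCol
  padded <- u[c(seq_len(h), rep(h, ph - h)), c(seq_len(w), rep(w, pw - w)),
              drop = FALSE]
  # EBImage's first image dimension is our row dimension
  out <- EBImage::clahe(padded, nx = nRow, ny = nCol,
                        bins = 256L, limit = clipLimit)
  out <- as.matrix(EBImage::imageData(out))[seq_len(h), seq_len(w),
                                            drop = FALSE]
  pmin(pmax(out, 0), 1)
}

#' Percentile-truncated min-max normalization
#'
#' Clips the view to its own low/high intensity percentiles (defaults: 5th
#' and 99th) and rescales that range linearly to [0,1], discarding the
#' extreme dark background and bright specular values.
#'
#' @param img numeric matrix view.
#' @param pLow,pHigh percentile thresholds in percent.
#' @return matrix in [0,1]; a constant image maps to all zeros with a
#'   warning.
#' @export
truncateNormalize <- function(img, pLow = 5, pHigh = 99) {
  checkView(img)
  q <- stats::quantile(img, c(pLow, pHigh) / 100, names = FALSE)
  if (q[1] == q[2]) {
    warning("constant image after truncation; returning zeros")
    return(matrix(0, nrow(img), ncol(img)))
  }
  out <- pmin(pmax(img, q[1]), q[2])
  (out - q[1]) / (q[2] - q[1])
}

#' Full single-view preprocessing chain
#'
#' Composition: orientation normalization, breast-region detection, crop,
#' CLAHE, truncated normalization. The ordered list of applied steps is
#' recorded in the `provenance` attribute.
#'
#' @param img numeric matrix view.
#' @param clipLimit CLAHE clip limit.
#' @param tileGrid CLAHE tile grid.
#' @param pLow,pHigh truncation percentiles.
#' @return float matrix in [0,1], cropped to the breast region.
#' @export
preprocessView <- function(img, clipLimit = 1.0, tileGrid = c(8L, 8L),
                           pLow = 5, pHigh = 99) {
  oriented <- normalizeOrientation(img)
  box <- detectBreastRegion(oriented)
  cropped <- cropToBox(oriented, box)
  enhanced <- claheEnhance(cropped, clipLimit, tileGrid)
  out <- truncateNormalize(enhanced, pLow, pHigh)
  attr(out, "provenance") <- c("orient", "detect_region", "crop",
                               "clahe", "truncate_normalize")
  attr(out, "box") <- box
  out
}

#' @export
print.BreastBox <- function(x, ...) {
  cat(sprintf("BreastBox [%d, %d) x [%d, %d)\n",
              x[["x0"]], x[["x1"]], x[["y0"]], x[["y1"]]))
  invisible(x)
}
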