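# Bilateral patch-wise contrastive joint learning. The reconstructed
# feature maps of the two breasts are cut into non-overlapping k x k
# spatial patches; every left-breast patch (anchor) is compared against
# all right-breast patches by eps-stabilised cosine similarity. The most
# similar pair is the positive sample, the least similar the negative.
# When both breasts are normal the loss only rewards positive-pair
# similarity, exp(-posSim/t); otherwise positive and negative terms are
# combined, (exp(-posSim/t) + exp(negSim/t)) / 2, averaged over anchors.

#' Partition a feature map into flattened non-overlapping patches
#'
#' @param fm feature map array `H x W x C`, H and W divisible by `k`.
#' @param k patch side length (default 5, matching a 40 x 20 map).
#' @return object of class `PatchSet`: list with `vectors`
#'   (`N x C*k^2` matrix, patches in row-major grid order), `grid`,
#'   `k` and `dims`.
#' @export
partitionPatches <- function(fm, k = 5L) {
  d <- dim(fm)
  if (d[1] %% k != 0L || d[2] %% k != 0L) {
    ok <- Filter(function(x) d[1] %% x == 0L && d[2] %% x == 0L,
                 seq_len(min(d[1], d[2])))
    stop("patch size ", k, " does not divide the ", d[1], " x ", d[2],
         " feature map; valid sizes: ", paste(ok, collapse = ", "))
  }
  gh <- d[1] %/% k; gw <- d[2] %/% k
  n <- gh * gw
  vectors <- matrix(0, n, d[3] * k * k)
  for (gr in seq_len(gh)) {
    for (gc in seq_len(gw)) {
      block <- fm[((gr - 1L) * k + 1L):(gr * k),
                  ((gc - 1L) * k + 1L):(gc * k), , drop = FALSE]
      vectors[(gr - 1L) * gw + gc, ] <- as.vector(block)
    }
  }
  structure(list(vectors = vectors, grid = c(gh, gw), k = as.integer(k),
                 dims = d),
            class = "PatchSet")
}

#' Reassemble a PatchSet into its feature map
#'
#' Exact inverse of [partitionPatches()].
#'
#' @param ps a `PatchSet`.
#' @return feature map array.
#' @export
reassemblePatches <- function(ps) {
  d <- ps$dims; k <- ps$k
  gh <- ps$grid[1]; gw <- ps$grid[2]
  fm <- array(0, dim = d)
  for (gr in seq_len(gh)) {
    for (gc in seq_len(gw)) {
      fm[((gr - 1L) * k + 1L):(gr * k),
         ((gc - 1L) * k + 1L):(gc * k), ] <-
        array(ps$vectors[(gr - 1L) * gw + gc, ], dim = c(k, k, d[3]))
    }
  }
  fm
}

#' Eps-stabilised cosine similarity of two vectors
#'
#' Each vector is divided by its L2 norm plus a small constant before the
#' dot product, so zero vectors are handled without special cases and the
#' value lies in [-1, 1] (shrunk slightly by eps).
#'
#' @param x,y numeric vectors of equal length.
#' @param eps stabilisation constant (default 1e-6).
#' @return scalar similarity.
#' @export
normalizedSimilarity <- function(x, y, eps = 1e-6) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  sum((x / (sqrt(sum(x^2)) + eps)) * (y / (sqrt(sum(y^2)) + eps)))
}

patchMatrix <- function(x) {
  if (inherits(x, "PatchSet")) x$vectors else as.matrix(x)
}

#' All-pairs similarity between two patch sets
#'
#' @param left,right `PatchSet`s (or plain `N x p` matrices) with equal
#'   patch counts and lengths.
#' @param eps stabilisation constant.
#' @return `N x N` matrix; entry (i, j) compares left patch i with right
#'   patch j.
#' @export
similarityMatrix <- function(left, right, eps = 1e-6) {
  x <- patchMatrix(left); y <- patchMatrix(right)
  if (!all(dim(x) == dim(y))) stop("patch sets must have matching shape")
  xn <- x / (sqrt(rowSums(x^2)) + eps)
  yn <- y / (sqrt(rowSums(y^2)) + eps)
  xn %*% t(yn)
}

#' Select positive and negative patch pairs per anchor
#'
#' Per row i of the similarity matrix the positive partner is the argmax
#' and the negative partner the argmin; ties resolve to the lowest index.
#'
#' @param s `N x N` similarity matrix.
#' @return list of class `PairSelection`: `pos`, `neg` (1-based indices),
#'   `posSim`, `negSim`.
#' @export
selectPairs <- function(s) {
  s <- as.matrix(s)
  pos <- apply(s, 1L, which.max)
  neg <- apply(s, 1L, which.min)
  structure(list(pos = pos, neg = neg,
                 posSim = s[cbind(seq_len(nrow(s)), pos)],
                 negSim = s[cbind(seq_len(nrow(s)), neg)]),
            class = "PairSelection")
}

#' Bilateral contrastive joint loss from a pair selection
#'
#' Both-normal branch: `mean(exp(-posSim / t))` -- only positive-pair
#' similarity is rewarded. Otherwise the positive and negative terms are
#' combined: `sum(exp(-posSim/t) + exp(negSim/t)) / (2N)`.
#'
#' @param sel a [selectPairs()] result.
#' @param bothNormal are both breasts labelled normal?
#' @param temperature temperature t > 0 (default 0.5).
#' @return positive scalar loss.
#' @export
contrastiveJointLoss <- function(sel, bothNormal, temperature = 0.5) {
  if (temperature <= 0) stop("temperature must be positive")
  n <- length(sel$posSim)
  if (bothNormal) {
    mean(exp(-sel$posSim / temperature))
  } else {
    sum(exp(-sel$posSim / temperature) +
          exp(sel$negSim / temperature)) / (2 * n)
  }
}

# Gradient of normalizedSimilarity w.r.t. x (y fixed), given the value s.
simGradX <- function(x, y, s, eps) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  yn <- y / (ny + eps)
  yn / (nx + eps) - s * x / (max(nx, 1e-12) * (nx + eps))
}

#' Full bilateral contrastive module: loss and (optional) gradients
#'
#' Partitions both reconstructed maps, selects pairs with left-breast
#' patches as anchors, and evaluates the joint loss with
#' `bothNormal = (yLeft == 0 && yRight == 0)`. Pair indices are treated
#' as constants of the current step; gradients flow through the
#' similarity values only.
#'
#' @param fl2,fr2 reconstructed feature maps `H x W x C`.
#' @param yLeft,yRight per-breast labels.
#' @param k patch size.
#' @param temperature temperature t.
#' @param eps similarity stabilisation constant.
#' @param grad also return `dFL2`, `dFR2`?
#' @return list with `loss`, `selection`, and gradients when requested.
#' @export
bilateralContrastLoss <- function(fl2, fr2, yLeft, yRight, k = 5L,
                                  temperature = 0.5, eps = 1e-6,
                                  grad = FALSE) {
  if (!identical(dim(fl2), dim(fr2))) stop("feature map shape mismatch")
  psL <- partitionPatches(fl2, k)
  psR <- partitionPatches(fr2, k)
  s <- similarityMatrix(psL, psR, eps)
  sel <- selectPairs(s)
  bothNormal <- (yLeft == 0L && yRight == 0L)
  loss <- contrastiveJointLoss(sel, bothNormal, temperature)
  out <- list(loss = loss, selection = sel, bothNormal = bothNormal)
  if (!grad) return(out)
  n <- length(sel$pos)
  t_ <- temperature
  dPos <- if (bothNormal) -exp(-sel$posSim / t_) / (n * t_)
          else -exp(-sel$posSim / t_) / (2 * n * t_)
  dNeg <- if (bothNormal) numeric(n)
          else exp(sel$negSim / t_) / (2 * n * t_)
  dL <- matrix(0, nrow(psL$vectors), ncol(psL$vectors))
  dR <- matrix(0, nrow(psR$vectors), ncol(psR$vectors))
  for (i in seq_len(n)) {
    xi <- psL$vectors[i, ]
    jp <- sel$pos[i]; jn <- sel$neg[i]
    yp <- psR$vectors[jp, ]
    dL[i, ] <- dL[i, ] + dPos[i] * simGradX(xi, yp, sel$posSim[i], eps)
    dR[jp, ] <- dR[jp, ] + dPos[i] * simGradX(yp, xi, sel$posSim[i], eps)
    if (dNeg[i] != 0) {
      yn <- psR$vectors[jn, ]
      dL[i, ] <- dL[i, ] + dNeg[i] * simGradX(xi, yn, sel$negSim[i], eps)
      dR[jn, ] <- dR[jn, ] + dNeg[i] * simGradX(yn, xi, sel$negSim[i], eps)
    }
  }
  psLg <- psL; psLg$vectors <- dL
  psRg <- psR; psRg$vectors <- dR
  out$dFL2 <- reassemblePatches(psLg)
  out$dFR2 <- reassemblePatches(psRg)
  out
}
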