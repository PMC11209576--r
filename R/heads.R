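# Dual non-shared classification heads and the weighted joint objective.
# Each head: global average pooling over the reconstructed feature map,
# then fully connected C -> hidden -> 1 with ReLU and dropout, sigmoid for
# the probability. Binary cross-entropy is computed on the pre-sigmoid
# scores (numerically stable, mathematically identical to the
# probability-space form).

#' Build one classification head
#'
#' @param inChannels pooled feature length (feature channels C).
#' @param hidden hidden layer width (default 512).
#' @param dropout dropout rate on the hidden layer during training.
#' @param seed optional RNG seed.
#' @return object of class `mcHead`.
#' @export
buildHead <- function(inChannels, hidden = 512L, dropout = 0.2,
                      seed = NULL) {
  build <- function() list(fc1 = makeLinear(inChannels, hidden),
                           fc2 = makeLinear(hidden, 1L))
  params <- if (is.null(seed)) build() else withSeed(seed, build())
  structure(list(params = params, dropout = dropout,
                 inChannels = as.integer(inChannels)),
            class = "mcHead")
}

#' Global average pooling of a feature map
#'
#' @param fm array `H x W x C`.
#' @return numeric vector of length C (the per-channel spatial mean).
#' @export
globalAveragePool <- function(fm) {
  apply(fm, 3L, mean)
}

#' Head forward pass: feature map to score and probability
#'
#' @param head an `mcHead`.
#' @param fm reconstructed feature map `H x W x C`.
#' @param train apply dropout (drawn from the current RNG)?
#' @param cache keep intermediates for the backward pass?
#' @return list with `score` (pre-sigmoid), `prob`, and optionally `cache`.
#' @export
headForward <- function(head, fm, train = FALSE, cache = FALSE) {
  pooledRaw <- globalAveragePool(fm)
  # z-score the pooled vector so the head sees a consistent input scale
  # regardless of how the upstream initialization scales the features
  mu <- mean(pooledRaw)
  sd_ <- sqrt(mean((pooledRaw - mu)^2) + 1e-5)
  pooled <- (pooledRaw - mu) / sd_
  z1 <- drop(linearForward(head$params$fc1, pooled))
  h1 <- relu(z1)
  mask <- if (train) dropoutMask(length(h1), head$dropout)
          else rep(1, length(h1))
  hd <- h1 * mask
  score <- drop(linearForward(head$params$fc2, hd))
  out <- list(score = score, prob = sigmoid(score))
  if (cache) {
    out$cache <- list(pooled = pooled, sd = sd_, z1 = z1, hd = hd,
                      mask = mask, mapDim = dim(fm))
  }
  out
}

headBackward <- function(head, cache, dScore) {
  g2 <- linearBackward(head$params$fc2, cache$hd, matrix(dScore, 1L, 1L))
  dHd <- drop(g2$dx) * cache$mask
  dZ1 <- reluBackward(cache$z1, dHd)
  g1 <- linearBackward(head$params$fc1, cache$pooled,
                       matrix(dZ1, nrow = 1L))
  dNorm <- drop(g1$dx)
  # back through the pooled z-score (y = (x - mean)/sd)
  y <- cache$pooled
  dPooled <- (dNorm - mean(dNorm) - y * mean(dNorm * y)) / cache$sd
  d <- cache$mapDim
  dFm <- array(rep(dPooled, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
  list(dFm = dFm,
       grads = list(fc1 = list(w = g1$dw, b = g1$db),
                    fc2 = list(w = g2$dw, b = g2$db)))
}

#' Mean binary cross-entropy on pre-sigmoid scores
#'
#' Stable logits formulation:
#' `mean(max(s, 0) - s*y + log1p(exp(-|s|)))`, identical to
#' `-mean(y log p + (1-y) log(1-p))` with `p = sigmoid(s)`.
#'
#' @param scores numeric vector of pre-sigmoid scores.
#' @param labels 0/1 vector of the same length.
#' @return scalar loss.
#' @export
bceLoss <- function(scores, labels) {
  if (length(scores) < 1L) stop("need at least one sample")
  mean(pmax(scores, 0) - scores * labels + log1p(exp(-abs(scores))))
}

# d(bceLoss)/d(scores)
bceGrad <- function(scores, labels) {
  (sigmoid(scores) - labels) / length(scores)
}

#' Weighted total training objective
#'
#' `u1 * lSim + u2 * (lClsLeft + lClsRight)`, combining the bilateral
#' contrastive loss with the two per-breast classification losses. The
#' defaults u1 = 5/6 and u2 = 1/6 put most of the weight on the
#' contrastive term.
#'
#' @param lSim contrastive loss.
#' @param lClsLeft,lClsRight per-breast BCE losses.
#' @param u1,u2 positive weights.
#' @return scalar total loss.
#' @export
totalLoss <- function(lSim, lClsLeft, lClsRight, u1 = 5 / 6, u2 = 1 / 6) {
  comps <- c(lSim, lClsLeft, lClsRight)
  if (any(!is.finite(comps))) {
    stop("non-finite loss component: ",
         paste(signif(comps, 4), collapse = ", "))
  }
  u1 * lSim + u2 * (lClsLeft + lClsRight)
}
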