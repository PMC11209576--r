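# Independent brute-force oracles and small fixtures used across tests.

# Direct-loop 2-D convolution (stride, zero padding), independent of the
# package implementation.
naiveConv2d <- function(x, w, b, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; k <- dim(w)[1]
  cin <- dim(w)[3]; cout <- dim(w)[4]
  Ho <- (H + 2 * pad - k) %/% stride + 1
  Wo <- (W + 2 * pad - k) %/% stride + 1
  y <- array(0, c(Ho, Wo, cout))
  for (co in seq_len(cout)) {
    for (i in seq_len(Ho)) {
      for (j in seq_len(Wo)) {
        acc <- b[co]
        for (di in seq_len(k)) {
          for (dj in seq_len(k)) {
            xi <- (i - 1) * stride + di - pad
            xj <- (j - 1) * stride + dj - pad
            if (xi >= 1 && xi <= H && xj >= 1 && xj <= W) {
              acc <- acc + sum(x[xi, xj, ] * w[di, dj, , co])
            }
          }
        }
        y[i, j, co] <- acc
      }
    }
  }
  y
}

# Triple-loop scaled dot-product attention for one head.
naiveAttention <- function(q, k, v, scale) {
  L <- nrow(q); Lk <- nrow(k)
  out <- matrix(0, L, ncol(v))
  wts <- matrix(0, L, Lk)
  for (i in seq_len(L)) {
    s <- numeric(Lk)
    for (j in seq_len(Lk)) s[j] <- sum(q[i, ] * k[j, ]) / scale
    e <- exp(s - max(s))
    a <- e / sum(e)
    wts[i, ] <- a
    for (j in seq_len(Lk)) out[i, ] <- out[i, ] + a[j] * v[j, ]
  }
  list(out = out, weights = wts)
}

# Double-loop eps-stabilised cosine similarity matrix.
naiveSimilarityMatrix <- function(x, y, eps = 1e-6) {
  n <- nrow(x)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      xn <- x[i, ] / (sqrt(sum(x[i, ]^2)) + eps)
      yn <- y[j, ] / (sqrt(sum(y[j, ]^2)) + eps)
      s[i, j] <- sum(xn * yn)
    }
  }
  s
}

# All-loops reference for the bilateral contrastive module on a full
# feature-map pair: partition, similarity, argmax/argmin, loss.
naiveContrastLoss <- function(fl2, fr2, bothNormal, k, t = 0.5,
                              eps = 1e-6) {
  d <- dim(fl2)
  gh <- d[1] %/% k; gw <- d[2] %/% k
  getPatch <- function(fm, gr, gc) {
    as.vector(fm[((gr - 1) * k + 1):(gr * k),
                 ((gc - 1) * k + 1):(gc * k), , drop = FALSE])
  }
  n <- gh * gw
  xs <- ys <- vector("list", n)
  idx <- 1
  for (gr in seq_len(gh)) {
    for (gc in seq_len(gw)) {
      xs[[idx]] <- getPatch(fl2, gr, gc)
      ys[[idx]] <- getPatch(fr2, gr, gc)
      idx <- idx + 1
    }
  }
  total <- 0
  for (i in seq_len(n)) {
    sims <- numeric(n)
    for (j in seq_len(n)) {
      xn <- xs[[i]] / (sqrt(sum(xs[[i]]^2)) + eps)
      yn <- ys[[j]] / (sqrt(sum(ys[[j]]^2)) + eps)
      sims[j] <- sum(xn * yn)
    }
    best <- max(sims); worst <- min(sims)
    if (bothNormal) {
      total <- total + exp(-best / t) / n
    } else {
      total <- total + (exp(-best / t) + exp(worst / t)) / (2 * n)
    }
  }
  total
}

# A light-weight case with 1x1 views, for counting/splitting tests where
# image content does not matter.
stubCase <- function(id, yLeft, yRight) {
  v <- matrix(0.5, 1, 1)
  MammoCase(id, list(L_CC = v, L_MLO = v, R_CC = v, R_MLO = v),
            yLeft, yRight)
}

stubCases <- function(nNormal, nBoth, nOne) {
  n <- nNormal + nBoth + nOne
  ys <- rbind(matrix(0L, nNormal, 2),
              matrix(1L, nBoth, 2),
              cbind(rep(1L, nOne), rep(0L, nOne)))
  lapply(seq_len(n), function(i) {
    stubCase(sprintf("p%05d", i), ys[i, 1], ys[i, 2])
  })
}

# Small synthetic spec for fast pipeline tests (views 64x64).
tinySynthSpec <- function(nCases = 12L, seed = 5L, ...) {
  synthSpec(nCases = nCases, imageSize = c(64L, 64L),
            lesionRadius = c(4, 8), seed = seed, ...)
}

# Tiny model configuration (input 64x32) for structural tests.
tinyModelConfig <- function(...) {
  args <- list(inputHeight = 64L, inputWidth = 32L,
               stageChannels = c(2L, 3L, 4L, 5L, 6L),
               featureChannels = 8L, heads = 2L, patchK = 1L,
               headHidden = 4L, headDropout = 0)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(modelConfig, args)
}
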