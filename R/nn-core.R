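# Minimal neural-network primitives with explicit backward passes.
# Parameters live in nested named lists of plain numeric arrays; gradients
# mirror the same structure. All randomness goes through R's RNG.

#' @useDynLib mammocross, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

heInit <- function(dims, fanIn) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fanIn)), dim = dims)
}

makeConvLayer <- function(k, cin, cout, stride = 2L, pad = 1L) {
  list(w = heInit(c(k, k, cin, cout), fanIn = k * k * cin),
       b = numeric(cout),
       k = as.integer(k), stride = as.integer(stride), pad = as.integer(pad))
}

convForward <- function(layer, x) {
  cout <- dim(layer$w)[4]
  cpp_conv2d(x, matrix(layer$w, ncol = cout), layer$b,
             layer$k, layer$stride, layer$pad)
}

convBackward <- function(layer, x, dy) {
  cout <- dim(layer$w)[4]
  g <- cpp_conv2d_bwd(x, matrix(layer$w, ncol = cout), dy,
                      layer$k, layer$stride, layer$pad)
  dw <- g$dw
  dim(dw) <- dim(layer$w)
  list(dx = g$dx, dw = dw, db = as.numeric(g$db))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

reluBackward <- function(x, dy) {
  dy[x <= 0] <- 0
  dy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Per-channel spatial (instance) normalization of an H x W x C activation:
# each channel map is centred and scaled to unit variance. Returns the
# normalized activation plus the quantities needed for the backward pass.
instNormForward <- function(x, eps = 1e-5) {
  cpp_instnorm_fwd(x, eps)
}

# Row-wise (per-token) layer normalization of an L x C matrix: each row
# is centred and scaled to unit variance across channels.
layerNormRowsForward <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  ctr <- x - mu
  sd_ <- sqrt(rowMeans(ctr^2) + eps)
  list(y = ctr / sd_, sd = sd_)
}

layerNormRowsBackward <- function(cacheLN, dy) {
  y <- cacheLN$y
  (dy - rowMeans(dy) - y * rowMeans(dy * y)) / cacheLN$sd
}

instNormBackward <- function(cacheIN, dy) {
  cpp_instnorm_bwd(cacheIN$y, cacheIN$sd, dy)
}

# Row-wise softmax, numerically stabilised.
softmaxRows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# d(loss)/d(logits) given softmax output p and upstream gradient dp.
softmaxRowsBackward <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

makeLinear <- function(nin, nout) {
  list(w = heInit(c(nin, nout), fanIn = nin), b = numeric(nout))
}

# x: n x nin matrix (or length-nin vector)
linearForward <- function(layer, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sweep(x %*% layer$w, 2L, layer$b, "+")
}

linearBackward <- function(layer, x, dy) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  list(dx = dy %*% t(layer$w),
       dw = t(x) %*% dy,
       db = colSums(dy))
}

# ---- nested-list parameter utilities --------------------------------------

isParamArray <- function(x) is.numeric(x)

paramMap <- function(f, p) {
  if (isParamArray(p)) return(f(p))
  out <- lapply(p, paramMap, f = f)
  names(out) <- names(p)
  out
}

paramMap2 <- function(f, a, b) {
  if (isParamArray(a)) return(f(a, b))
  out <- mapply(function(x, y) paramMap2(f, x, y), a, b, SIMPLIFY = FALSE)
  names(out) <- names(a)
  out
}

zeroLike <- function(p) paramMap(function(x) x * 0, p)

addGrads <- function(a, b) paramMap2(`+`, a, b)

scaleGrads <- function(p, s) paramMap(function(x) x * s, p)

paramCount <- function(p) {
  if (isParamArray(p)) return(length(p))
  sum(vapply(p, paramCount, numeric(1)))
}

# ---- Adam ------------------------------------------------------------------

adamInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

#' @noRd
adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     weightDecay = 0) {
  state$t <- state$t + 1L
  t <- state$t
  step <- function(p, g, m, v) {
    if (weightDecay > 0) g <- g + weightDecay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (isParamArray(p)) return(step(p, g, m, v))
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (i in seq_along(p)) out[[i]] <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
    list(p = lapply(out, `[[`, "p"),
         m = lapply(out, `[[`, "m"),
         v = lapply(out, `[[`, "v"))
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = t))
}

# Dropout mask; at eval time (or rate 0) the identity.
dropoutMask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (stats::runif(n) >= rate) / (1 - rate)
}

# Evaluate a thunk under a temporary RNG seed, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}
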