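# Cross-mammogram attention: token bookkeeping, head splitting, oracle
# equivalence, dual-path symmetry, and exact gradients.

test_that("token flattening is row-major and exactly invertible", {
  set.seed(1)
  fm <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  tk <- tokensFromMap(fm)
  expect_equal(nrow(tk), 4L)
  # token at (r-1)*W + c equals map[r, c, ]
  for (r in 1:2) for (c in 1:2) {
    expect_equal(tk[(r - 1) * 2 + c, ], fm[r, c, ])
  }
  expect_equal(tokensToMap(tk), fm)

  fm2 <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  expect_equal(tokensToMap(tokensFromMap(fm2)), fm2)
})

test_that("token projection is affine with the right output width", {
  cfg <- attentionConfig(channels = 1280L, heads = 8L)
  expect_equal(cfg$d, 480L)  # 3 * 1280 / 8
  w <- mammocross:::makeLinear(4L, 12L)
  a <- matrix(rnorm(8), 2, 4)
  b <- matrix(rnorm(8), 2, 4)
  expect_equal(ncol(projectTokens(a, w)), 12L)
  expect_equal(projectTokens(a + b, w),
               projectTokens(a, w) + projectTokens(b, w) -
                 projectTokens(a * 0, w),
               tolerance = 1e-12)
})

test_that("head splitting partitions the channels exactly", {
  cfg <- attentionConfig(channels = 4L, heads = 2L)  # d = 6
  p <- matrix(rnorm(3 * 12), 3, 12)
  q <- splitHeads(p, cfg, "q")
  expect_equal(dim(q), c(3L, 6L, 2L))
  expect_equal(cbind(q[, , 1], q[, , 2]), p)

  one <- attentionConfig(channels = 4L, heads = 1L)
  q1 <- splitHeads(p, one, "q")
  expect_equal(q1[, , 1], p)

  expect_error(attentionConfig(channels = 5L, heads = 4L), "divisible")
})

test_that("cross-attention matches the triple-loop oracle and normalises
          weights", {
  set.seed(2)
  for (mode in c("sqrt_dim", "dim")) {
    for (rep in 1:5) {
      L <- sample(2:6, 1)
      cfg <- attentionConfig(channels = 2L, heads = 2L, scaleMode = mode)
      d <- cfg$d  # 3
      qh <- array(rnorm(L * d * 2), c(L, d, 2))
      kh <- array(rnorm(L * d * 2), c(L, d, 2))
      vh <- array(rnorm(L * d * 2), c(L, d, 2))
      got <- crossAttend(qh, kh, vh, cfg, returnWeights = TRUE)
      for (h in 1:2) {
        want <- naiveAttention(qh[, , h], kh[, , h], vh[, , h], cfg$scale)
        expect_equal(got$out[, , h], want$out, tolerance = 1e-5)
        expect_equal(got$weights[, , h], want$weights, tolerance = 1e-5)
        expect_equal(rowSums(got$weights[, , h]), rep(1, L),
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("identical queries give identical outputs; permuting the
          contralateral tokens leaves the output unchanged", {
  set.seed(3)
  cfg <- attentionConfig(channels = 2L, heads = 1L)
  d <- cfg$d
  qh <- array(rep(rnorm(d), each = 4), c(4, d, 1))
  kh <- array(rnorm(4 * d), c(4, d, 1))
  vh <- array(rnorm(4 * d), c(4, d, 1))
  out <- crossAttend(qh, kh, vh, cfg)
  for (i in 2:4) expect_equal(out[i, , 1], out[1, , 1], tolerance = 1e-12)

  qh2 <- array(rnorm(4 * d), c(4, d, 1))
  perm <- c(3, 1, 4, 2)
  a <- crossAttend(qh2, kh, vh, cfg, returnWeights = TRUE)
  b <- crossAttend(qh2, kh[perm, , , drop = FALSE],
                   vh[perm, , , drop = FALSE], cfg, returnWeights = TRUE)
  expect_equal(a$out, b$out, tolerance = 1e-12)
  expect_equal(a$weights[, perm, 1], b$weights[, , 1], tolerance = 1e-12)
})

test_that("the dual-pathway module preserves shape and swaps outputs
          under tied branches", {
  set.seed(4)
  cfg <- attentionConfig(channels = 4L, heads = 2L)
  attn <- buildCrossAttention(cfg, seed = 11L)
  fl <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  fr <- array(rnorm(3 * 2 * 4), c(3, 2, 4))
  fw <- crossAttentionForward(attn, fl, fr)
  expect_equal(dim(fw$FL2), dim(fl))
  expect_equal(dim(fw$FR2), dim(fr))

  # tie the two branches: swapping inputs must swap outputs
  attn$params$projR <- attn$params$projL
  attn$params$outR <- attn$params$outL
  a <- crossAttentionForward(attn, fl, fr)
  b <- crossAttentionForward(attn, fr, fl)
  expect_equal(a$FL2, b$FR2, tolerance = 1e-12)
  expect_equal(a$FR2, b$FL2, tolerance = 1e-12)

  expect_error(crossAttentionForward(attn, fl, array(0, c(2, 2, 4))),
               "mismatch")
})

test_that("attention backward matches finite differences for both role
          splits", {
  set.seed(5)
  for (split in c("segment", "qkv")) {
    cfg <- attentionConfig(channels = 4L, heads = 2L, roleSplit = split)
    attn <- buildCrossAttention(cfg, seed = 7L)
    fl <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
    fr <- array(rnorm(2 * 2 * 4), c(2, 2, 4))
    fw <- crossAttentionForward(attn, fl, fr, cache = TRUE)
    dFL2 <- array(rnorm(length(fw$FL2)), dim(fw$FL2))
    dFR2 <- array(rnorm(length(fw$FR2)), dim(fw$FR2))
    bk <- mammocross:::crossAttentionBackward(attn, fw$cache, dFL2, dFR2)
    loss <- function() {
      f <- crossAttentionForward(attn, fl, fr)
      sum(f$FL2 * dFL2) + sum(f$FR2 * dFR2)
    }
    eps <- 1e-6
    num <- fl * 0
    for (i in seq_along(fl)) {
      fl[i] <- fl[i] + eps; lp <- loss()
      fl[i] <- fl[i] - 2 * eps; lm <- loss()
      fl[i] <- fl[i] + eps
      num[i] <- (lp - lm) / (2 * eps)
    }
    expect_equal(num, bk$dFL, tolerance = 1e-5)
    numr <- fr * 0
    for (i in seq_along(fr)) {
      fr[i] <- fr[i] + eps; lp <- loss()
      fr[i] <- fr[i] - 2 * eps; lm <- loss()
      fr[i] <- fr[i] + eps
      numr[i] <- (lp - lm) / (2 * eps)
    }
    expect_equal(numr, bk$dFR, tolerance = 1e-5)
    expect_gt(sum(abs(bk$dFL)), 0)
    expect_gt(sum(abs(bk$dFR)), 0)
  }
})
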