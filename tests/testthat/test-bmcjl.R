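# Bilateral patch contrast: partition bookkeeping, similarity, pair
# selection, closed-form losses, oracle equivalence, gradients.

test_that("patch partition counts and reassembly are exact", {
  set.seed(1)
  # canonical geometry: 40 x 20 map, k = 5 -> 32 patches
  fm <- array(rnorm(40 * 20 * 4), c(40, 20, 4))
  ps <- partitionPatches(fm, 5L)
  expect_equal(nrow(ps$vectors), 32L)
  expect_equal(ncol(ps$vectors), 4L * 25L)
  expect_equal(reassemblePatches(ps), fm)

  # k == H == W: single patch equals the flattened map
  sq <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  one <- partitionPatches(sq, 3L)
  expect_equal(nrow(one$vectors), 1L)
  expect_equal(as.vector(one$vectors), as.vector(sq))

  expect_error(partitionPatches(fm, 3L), "valid sizes")
})

test_that("normalized similarity matches hand computations", {
  expect_equal(normalizedSimilarity(c(3, 4), c(4, 3)), 24 / 25,
               tolerance = 1e-4)
  expect_equal(normalizedSimilarity(c(1, 0), c(0, 1)), 0,
               tolerance = 1e-12)
  v <- rnorm(10) * 100
  expect_equal(normalizedSimilarity(v, v), 1, tolerance = 1e-4)
  expect_error(normalizedSimilarity(1:3, 1:4), "equal length")
})

test_that("the similarity matrix matches the double-loop oracle and is
          bounded", {
  set.seed(2)
  x <- matrix(rnorm(4 * 6), 4, 6)
  y <- matrix(rnorm(4 * 6), 4, 6)
  s <- similarityMatrix(x, y)
  expect_equal(s, naiveSimilarityMatrix(x, y), tolerance = 1e-6)
  expect_true(all(abs(s) <= 1))

  # orthogonal identical sets give an identity-like matrix
  e <- diag(4)
  sI <- similarityMatrix(e, e)
  expect_equal(diag(sI), rep(1, 4), tolerance = 1e-4)
  expect_true(all(abs(sI[upper.tri(sI)]) < 1e-8))
})

test_that("pair selection takes argmax/argmin with lowest-index ties", {
  sel <- selectPairs(matrix(c(0.2, 0.9, -0.5), 1, 3))
  expect_equal(sel$pos, 2L)
  expect_equal(sel$neg, 3L)

  tie <- selectPairs(matrix(0.3, 2, 4))
  expect_equal(tie$pos, c(1L, 1L))
  expect_equal(tie$neg, c(1L, 1L))

  set.seed(3)
  for (rep in 1:10) {
    s <- matrix(rnorm(36), 6, 6)
    sel <- selectPairs(s)
    for (i in 1:6) {
      o <- order(s[i, ])
      expect_equal(sel$neg[i], o[1])
      expect_equal(sel$pos[i], o[6])
      expect_gte(sel$posSim[i], sel$negSim[i])
    }
  }
})

test_that("the joint loss reproduces its closed forms", {
  # identical bilateral patch sets, both normal, t = 0.5 -> exp(-2)
  set.seed(4)
  fm <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  r <- bilateralContrastLoss(fm, fm, 0L, 0L, k = 2L)
  expect_true(r$bothNormal)
  expect_equal(r$loss, exp(-2), tolerance = 1e-3)

  # zero similarities give loss 1 in both branches
  zeroSel <- structure(list(pos = 1L, neg = 1L, posSim = 0, negSim = 0),
                       class = "PairSelection")
  expect_equal(contrastiveJointLoss(zeroSel, TRUE, 0.5), 1)
  expect_equal(contrastiveJointLoss(zeroSel, FALSE, 0.5), 1)
  expect_error(contrastiveJointLoss(zeroSel, TRUE, 0), "positive")

  # both-normal loss bounded by (exp(-1/t), exp(1/t))
  set.seed(5)
  for (rep in 1:10) {
    a <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
    b <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
    l <- bilateralContrastLoss(a, b, 0L, 0L, k = 2L)$loss
    expect_gt(l, exp(-2))
    expect_lt(l, exp(2))
  }
})

test_that("the full module matches an all-loops reference", {
  set.seed(6)
  for (labels in list(c(0L, 0L), c(1L, 0L), c(1L, 1L))) {
    fl2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    fr2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    got <- bilateralContrastLoss(fl2, fr2, labels[1], labels[2], k = 2L)
    want <- naiveContrastLoss(fl2, fr2,
                              bothNormal = all(labels == 0L), k = 2L)
    expect_equal(got$loss, want, tolerance = 1e-5)
  }
})

test_that("the loss falls as the contralateral map approaches the anchor
          map (both normal)", {
  set.seed(7)
  fl2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  fr2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  losses <- sapply(seq(0, 1, by = 0.25), function(alpha) {
    morph <- (1 - alpha) * fr2 + alpha * fl2
    bilateralContrastLoss(fl2, morph, 0L, 0L, k = 2L)$loss
  })
  # decreasing trend (one violation allowed while the argmax pairing
  # still switches), ending at the identical-map optimum exp(-2)
  expect_lte(sum(diff(losses) >= 0), 1L)
  expect_equal(losses[5], min(losses))
  expect_equal(losses[5], exp(-2), tolerance = 1e-3)
})

test_that("permuting the contralateral patches leaves the loss
          unchanged", {
  set.seed(8)
  fl2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  fr2 <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  base <- bilateralContrastLoss(fl2, fr2, 1L, 0L, k = 2L)$loss
  # permute right patches spatially (2 x 2 grid of 2 x 2 patches)
  psR <- partitionPatches(fr2, 2L)
  psR$vectors <- psR$vectors[c(3, 1, 4, 2), ]
  permuted <- reassemblePatches(psR)
  expect_equal(bilateralContrastLoss(fl2, permuted, 1L, 0L, k = 2L)$loss,
               base, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences and reach both
          maps", {
  set.seed(9)
  for (labels in list(c(0L, 0L), c(1L, 0L))) {
    fl2 <- array(rnorm(4 * 2 * 2), c(4, 2, 2))
    fr2 <- array(rnorm(4 * 2 * 2), c(4, 2, 2))
    r <- bilateralContrastLoss(fl2, fr2, labels[1], labels[2], k = 2L,
                               grad = TRUE)
    eps <- 1e-6
    num <- fl2 * 0
    for (i in seq_along(fl2)) {
      fp <- fl2; fp[i] <- fp[i] + eps
      fm_ <- fl2; fm_[i] <- fm_[i] - eps
      num[i] <- (bilateralContrastLoss(fp, fr2, labels[1], labels[2],
                                       k = 2L)$loss -
                   bilateralContrastLoss(fm_, fr2, labels[1], labels[2],
                                         k = 2L)$loss) / (2 * eps)
    }
    expect_equal(num, r$dFL2, tolerance = 1e-5)
    expect_gt(sum(abs(r$dFL2)), 0)
    expect_gt(sum(abs(r$dFR2)), 0)
  }
})
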