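# Preprocessing: orientation, breast-region detection, CLAHE, truncated
# normalization, and the composed chain.

test_that("orientation normalization points tissue to the right and is
          mirror-consistent", {
  # horizontally symmetric image stays unchanged
  sym <- matrix(0, 20, 20)
  sym[6:15, 6:15] <- 1
  expect_equal(unname(normalizeOrientation(sym))[, ], sym[, ],
               ignore_attr = TRUE)
  expect_false(attr(normalizeOrientation(sym), "flipped"))

  # foreground mass already right: unchanged (checked by brute half-sums)
  img <- matrix(0, 16, 16)
  img[4:12, 10:16] <- 0.8
  out <- normalizeOrientation(img)
  expect_false(attr(out, "flipped"))
  expect_equal(matrix(out, nrow(img)), img)

  # f(mirror(x)) == f(x) exhaustively on small random blob images
  set.seed(42)
  for (rep in 1:20) {
    x <- matrix(0, 16, 16)
    r0 <- sample(1:8, 1); c0 <- sample(1:8, 1)
    x[r0:(r0 + 7), c0:(c0 + 5)] <- runif(48, 0.5, 1)
    mx <- x[, rev(seq_len(ncol(x)))]
    a <- normalizeOrientation(x)
    b <- normalizeOrientation(mx)
    expect_equal(matrix(a, 16), matrix(b, 16), tolerance = 1e-12)
    # idempotence
    expect_equal(matrix(normalizeOrientation(matrix(a, 16)), 16),
                 matrix(a, 16))
  }

  expect_error(normalizeOrientation(matrix(0, 5, 5)), "degenerate")
})

test_that("breast region detection finds the largest-component bounding
          box", {
  img <- matrix(0, 100, 100)
  img[41:60, 11:40] <- 1  # white 20(h) x 30(w) rectangle at x=10, y=40
  box <- detectBreastRegion(img)
  expect_true(abs(box[["x0"]] - 10) <= 1)
  expect_true(abs(box[["y0"]] - 40) <= 1)
  expect_true(abs(box[["x1"]] - 40) <= 1)
  expect_true(abs(box[["y1"]] - 60) <= 1)

  # full-foreground image: full-image box
  # (uniform foreground on tiny noise floor)
  full <- matrix(1, 30, 40)
  full[1, 1] <- 0.99
  boxF <- detectBreastRegion(full)
  expect_equal(unname(boxF[c("x0", "y0", "x1", "y1")]), c(0, 0, 40, 30))

  # two blobs: the larger one wins (areas checked by construction)
  two <- matrix(0, 60, 60)
  two[6:30, 6:25] <- 1     # 500 px
  two[46:50, 46:55] <- 1   # 50 px
  boxT <- detectBreastRegion(two)
  expect_true(boxT[["x1"]] <= 30 && boxT[["y1"]] <= 35)

  expect_error(detectBreastRegion(matrix(0, 8, 8), file = "v.png"),
               "v.png")
})

test_that("detected box contains nearly all foreground mass of single-blob
          images", {
  set.seed(7)
  for (rep in 1:10) {
    img <- matrix(0, 64, 64)
    r0 <- sample(5:25, 1); c0 <- sample(5:25, 1)
    rh <- sample(15:30, 1); cw <- sample(15:30, 1)
    img[r0:(r0 + rh), c0:(c0 + cw)] <- runif((rh + 1) * (cw + 1), 0.6, 1)
    box <- detectBreastRegion(img)
    inside <- sum(img[(box[["y0"]] + 1):box[["y1"]],
                      (box[["x0"]] + 1):box[["x1"]]])
    expect_gte(inside / sum(img), 0.99)
  }
})

test_that("CLAHE preserves shape, constants, and responds to the clip
          limit", {
  const <- matrix(0.4, 64, 64)
  expect_equal(claheEnhance(const), const)

  set.seed(1)
  tex <- matrix(runif(96 * 96), 96, 96)
  e1 <- claheEnhance(tex, clipLimit = 1)
  e4 <- claheEnhance(tex, clipLimit = 4)
  expect_equal(dim(e1), dim(tex))
  expect_true(all(e1 >= 0 & e1 <= 1))
  expect_gt(max(abs(e1 - e4)), 0)

  # within a corner block (single contextual region of a 2x2 grid) the
  # equalization mapping is monotone, so intensity ranks are preserved
  g <- claheEnhance(tex, clipLimit = 4, tileGrid = c(2L, 2L))
  corner <- tex[1:24, 1:24]
  gc_ <- g[1:24, 1:24]
  ord <- order(corner)
  expect_true(all(diff(gc_[ord]) >= -1e-9))
})

test_that("truncated normalization matches a sorting oracle and is
          affine-invariant", {
  ramp <- matrix(seq(0, 999, length.out = 1000), 40, 25)
  out <- truncateNormalize(ramp)
  q <- sort(as.vector(ramp))[c(50, 990)]  # close to type-7 percentiles
  expect_true(all(out[ramp <= q[1] - 1] == 0))
  expect_true(all(out[ramp >= q[2] + 1] == 1))
  expect_equal(range(out), c(0, 1))

  expect_warning(z <- truncateNormalize(matrix(3, 5, 5)), "constant")
  expect_true(all(z == 0))

  set.seed(3)
  x <- matrix(runif(400), 20, 20)
  a <- truncateNormalize(x)
  b <- truncateNormalize(7.3 * x + 2.1)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("the composed preprocessing chain crops to the detected box and
          stays in [0,1]", {
  set.seed(11)
  spec <- tinySynthSpec()
  v <- mammocross:::withSeed(2, generateView(TRUE, spec, side = "right"))
  box <- detectBreastRegion(normalizeOrientation(v))
  out <- preprocessView(v)
  expect_equal(dim(out),
               c(box[["y1"]] - box[["y0"]], box[["x1"]] - box[["x0"]]))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(attr(out, "provenance")[1], "orient")

  # re-running the chain does not flip the orientation again
  again <- normalizeOrientation(matrix(out, nrow(out)))
  expect_false(attr(again, "flipped"))
})
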