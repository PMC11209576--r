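# Training loop, metrics, ROC/AUC, Grad-CAM.

makeTinyCases <- function(n = 8L, seed = 31L) {
  spec <- tinySynthSpec(nCases = n, seed = seed,
                        mix = c(both_normal = 0.5, both_cancer = 0.25,
                                one_cancer = 0.25))
  generateCases(spec)
}

test_that("the plateau scheduler drops the learning rate tenfold after
          three flat epochs", {
  st <- list(lr = 1e-4, best = NULL, bad = 0L)
  for (i in 1:4) st <- mammocross:::plateauStep(st, 1.0, 3L, 0.1)
  expect_equal(st$lr, 1e-5, tolerance = 1e-12)
  # an improvement resets the counter
  st <- list(lr = 1e-4, best = NULL, bad = 0L)
  st <- mammocross:::plateauStep(st, 1.0, 3L, 0.1)
  st <- mammocross:::plateauStep(st, 1.0, 3L, 0.1)
  st <- mammocross:::plateauStep(st, 0.5, 3L, 0.1)
  st <- mammocross:::plateauStep(st, 0.6, 3L, 0.1)
  expect_equal(st$lr, 1e-4)
})

test_that("a short smoke training run reduces the loss and is seed
          reproducible", {
  cases <- makeTinyCases()
  cfg <- tinyModelConfig(headDropout = 0.1)
  m <- buildModel(cfg, seed = 21L)
  tc <- trainConfig(lr = 1e-3, maxEpochs = 3L, batchSize = 4L, seed = 21L)
  res <- trainModel(m, cases, tc, preprocess = FALSE, augment = NULL)
  expect_equal(nrow(res$history), 3L)
  # non-increasing trend, allowing one violation
  viol <- sum(diff(res$history$loss) > 0)
  expect_lte(viol, 1L)

  m2 <- buildModel(cfg, seed = 21L)
  res2 <- trainModel(m2, cases, tc, preprocess = FALSE, augment = NULL)
  expect_equal(res2$history$loss[1], res$history$loss[1],
               tolerance = 1e-12)

  expect_error(trainModel(m, list(), tc), "empty")
})

test_that("confusion counts, accuracy and ROC behave as defined", {
  # counts (TP 4, TN 4, FP 1, FN 1) -> ACC 80%
  preds <- data.frame(
    case_id = sprintf("c%d", 1:10), side = "left",
    label = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
    prob = c(0.9, 0.8, 0.7, 0.6, 0.4, 0.1, 0.2, 0.3, 0.35, 0.8))
  rep <- metricsFromPredictions(preds, threshold = 0.5)
  expect_equal(unname(rep@counts[c("tp", "tn", "fp", "fn")]),
               c(4L, 4L, 1L, 1L))
  expect_equal(rep@acc, 80)
  # conservation
  expect_equal(rep@counts[["tp"]] + rep@counts[["fn"]],
               sum(preds$label == 1))
  expect_equal(rep@counts[["tn"]] + rep@counts[["fp"]],
               sum(preds$label == 0))

  # perfect separation
  sep <- within(preds, prob <- ifelse(label == 1, 0.9, 0.1))
  repS <- metricsFromPredictions(sep)
  expect_equal(repS@acc, 100)
  expect_equal(repS@auc, 1)

  # single-class truth: AUC undefined
  one <- preds[preds$label == 1, ]
  expect_true(is.na(metricsFromPredictions(one)@auc))
})

test_that("label-independent scores give chance-level AUC on balanced
          data", {
  set.seed(12)
  n <- 500L
  preds <- data.frame(case_id = sprintf("c%d", seq_len(n)), side = "left",
                      label = rep(c(0L, 1L), n / 2), prob = runif(n))
  rep <- metricsFromPredictions(preds)
  expect_lt(abs(rep@auc - 0.5), 0.05)
})

test_that("rank AUC equals trapezoidal ROC integration and the pROC
          reference", {
  set.seed(13)
  # no ties
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.45)
  a1 <- aucRank(scores, labels)
  a2 <- aucTrapezoid(rocPoints(scores, labels))
  expect_equal(a1, a2, tolerance = 1e-9)
  expect_equal(a1,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<", levels = c(0, 1)))),
               tolerance = 1e-9)
  # with ties (mid-rank handling)
  st <- round(scores, 1)
  expect_equal(aucRank(st, labels),
               as.numeric(pROC::auc(pROC::roc(labels, st, quiet = TRUE,
                                              direction = "<", levels = c(0, 1)))),
               tolerance = 1e-9)
})

test_that("Grad-CAM produces normalised input-sized maps that differ by
          side and localise an implanted lesion after overfitting", {
  spec <- tinySynthSpec(nCases = 4L, seed = 41L,
                        mix = c(both_normal = 0.5, both_cancer = 0.25,
                                one_cancer = 0.25),
                        lesionBoost = 0.6, lesionCount = c(1L, 1L))
  cases <- generateCases(spec)
  # 128 x 64 inputs give the class-activation map a 4 x 2 grid
  cfg <- tinyModelConfig(inputHeight = 128L, inputWidth = 64L,
                         stageChannels = c(4L, 6L, 8L, 10L, 12L),
                         featureChannels = 16L, headHidden = 8L,
                         patchK = 2L)
  m <- buildModel(cfg, seed = 31L)
  tc <- trainConfig(lr = 3e-3, maxEpochs = 6L, batchSize = 2L, seed = 31L)
  res <- trainModel(m, cases, tc, preprocess = FALSE, augment = NULL)
  model <- res$model

  cancerCase <- cases[[which(sapply(cases, scenarioOf) == "both_cancer")[1]]]
  p <- prepareCase(cancerCase, cfg, preprocess = FALSE)
  cam <- gradCam(model, p$xL, p$xR, side = "left")
  expect_equal(dim(cam$heatmap), c(128L, 64L))
  expect_true(all(cam$heatmap >= 0 & cam$heatmap <= 1))

  camR <- gradCam(model, p$xL, p$xR, side = "right")
  expect_false(isTRUE(all.equal(cam$heatmap, camR$heatmap)))

  # localization: heatmap mass inside the (scaled) lesion box of the CC
  # view exceeds the uniform-baseline share
  box <- cancerCase@lesionBoxes$L_CC[1, ]
  h <- nrow(cancerCase@views$L_CC); w <- ncol(cancerCase@views$L_CC)
  # CC occupies the top 64 rows of the 128 x 64 input
  ys <- max(1, floor(box$y0 / h * 64)):min(64, ceiling(box$y1 / h * 64))
  xs <- max(1, floor(box$x0 / w * 64)):min(64, ceiling(box$x1 / w * 64))
  mass <- sum(cam$heatmap[ys, xs])
  share <- mass / sum(cam$heatmap)
  uniform <- length(ys) * length(xs) / (128 * 64)
  expect_gt(share, uniform)
})
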