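# Per-breast evaluation: confusion counts, accuracy, ROC curve, AUC.
# The evaluation unit is the breast, two per case.

#' Rank-statistic AUC (Mann-Whitney, mid-rank tie handling)
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 ground truth.
#' @return AUC in [0,1]; `NA` when a single class is present.
#' @export
aucRank <- function(scores, labels) {
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  if (pos == 0 || neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - pos * (pos + 1) / 2) / (pos * neg)
}

#' ROC curve by threshold sweep over the unique scores
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 ground truth.
#' @return matrix with columns `fpr`, `tpr`, from (0,0) to (1,1).
#' @export
rocPoints <- function(scores, labels) {
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = if (neg > 0) sum(pred & labels == 0) / neg else 0,
      tpr = if (pos > 0) sum(pred & labels == 1) / pos else 0)
  }, numeric(2)))
  rbind(c(fpr = 0, tpr = 0), pts, c(fpr = 1, tpr = 1))
}

#' Trapezoidal integration of an ROC curve
#'
#' @param roc matrix from [rocPoints()].
#' @return area under the curve.
#' @export
aucTrapezoid <- function(roc) {
  o <- order(roc[, "fpr"], roc[, "tpr"])
  x <- roc[o, "fpr"]; y <- roc[o, "tpr"]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

confusionCounts <- function(pred, labels) {
  c(tp = sum(pred == 1 & labels == 1), tn = sum(pred == 0 & labels == 0),
    fp = sum(pred == 1 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

#' Evaluate a model on a set of cases
#'
#' Every breast contributes one prediction (two rows per case). Accuracy
#' is `(TP + TN) / total * 100`; AUC is the rank statistic over the
#' predicted probabilities.
#'
#' @param model a `CrossMammoModel`.
#' @param cases list of [MammoCase-class] objects.
#' @param threshold probability cut-off for the confusion counts.
#' @param preprocess preprocess raw views?
#' @return a [MetricsReport-class].
#' @export
evaluateModel <- function(model, cases, threshold = 0.5,
                          preprocess = TRUE) {
  rows <- lapply(cases, function(case) {
    p <- prepareCase(case, model$cfg, preprocess = preprocess)
    pr <- predictBreasts(model, p$xL, p$xR)
    data.frame(case_id = rep(case@caseId, 2L),
               side = c("left", "right"),
               label = c(p$yLeft, p$yRight),
               prob = as.numeric(pr))
  })
  preds <- do.call(rbind, rows)
  metricsFromPredictions(preds, threshold)
}

#' Build a MetricsReport from per-breast predictions
#'
#' @param preds data.frame with columns `case_id, side, label, prob`.
#' @param threshold probability cut-off.
#' @return a [MetricsReport-class].
#' @export
metricsFromPredictions <- function(preds, threshold = 0.5) {
  preds$pred <- as.integer(preds$prob >= threshold)
  counts <- confusionCounts(preds$pred, preds$label)
  storage.mode(counts) <- "integer"
  acc <- 100 * (counts[["tp"]] + counts[["tn"]]) / sum(counts)
  auc <- aucRank(preds$prob, preds$label)
  roc <- rocPoints(preds$prob, preds$label)
  new("MetricsReport", counts = counts, acc = acc, auc = auc,
      roc = roc, predictions = preds)
}

#' Write a metrics report to JSON
#'
#' Schema: `{acc, auc, tp, tn, fp, fn, roc: [[fpr, tpr], ...]}`.
#'
#' @param report a [MetricsReport-class].
#' @param path output file.
#' @export
writeMetricsJSON <- function(report, path) {
  k <- report@counts
  jsonlite::write_json(
    list(acc = report@acc, auc = report@auc,
         tp = k[["tp"]], tn = k[["tn"]], fp = k[["fp"]], fn = k[["fn"]],
         roc = unname(apply(report@roc, 1L, function(r) as.numeric(r),
                            simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA, na = "null")
}
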