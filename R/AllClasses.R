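#' @import methods
NULL

#' MammoCase: one patient's bilateral four-view mammogram case
#'
#' Holds the four grayscale views (left/right x CC/MLO) as numeric
#' matrices plus the per-breast binary labels. Views may be raw or
#' preprocessed; the pipeline functions do not care about the intensity
#' scale as long as values are non-negative.
#'
#' @slot caseId character, patient/case identifier.
#' @slot views named list with elements `L_CC`, `L_MLO`, `R_CC`, `R_MLO`,
#'   each a numeric matrix.
#' @slot yLeft,yRight integer 0/1 label per breast (1 = cancer).
#' @slot lesionBoxes named list of lesion bounding boxes per view
#'   (generator metadata; may be empty).
#' @export
setClass("MammoCase",
         representation(caseId = "character", views = "list",
                        yLeft = "integer", yRight = "integer",
                        lesionBoxes = "list"),
         prototype(lesionBoxes = list()))

setValidity("MammoCase", function(object) {
  need <- c("L_CC", "L_MLO", "R_CC", "R_MLO")
  if (!all(need %in% names(object@views))) {
    return(paste("views must contain", paste(need, collapse = ", ")))
  }
  if (!all(vapply(object@views[need], is.matrix, logical(1)))) {
    return("each view must be a numeric matrix")
  }
  if (!object@yLeft %in% c(0L, 1L) || !object@yRight %in% c(0L, 1L)) {
    return("labels must be 0 or 1")
  }
  TRUE
})

#' Construct a MammoCase
#'
#' @param caseId case identifier.
#' @param views named list of four view matrices (`L_CC`, `L_MLO`,
#'   `R_CC`, `R_MLO`).
#' @param yLeft,yRight per-breast 0/1 labels.
#' @param lesionBoxes optional generator metadata.
#' @return a validated [MammoCase-class] object.
#' @export
MammoCase <- function(caseId, views, yLeft, yRight, lesionBoxes = list()) {
  views <- lapply(views, function(v) {
    a <- attributes(v)
    v <- as.matrix(v)
    dimnames(v) <- NULL
    v
  })
  new("MammoCase", caseId = as.character(caseId), views = views,
      yLeft = as.integer(yLeft), yRight = as.integer(yRight),
      lesionBoxes = lesionBoxes)
}

#' @describeIn MammoCase case identifier accessor
#' @param object a `MammoCase`.
#' @export
setGeneric("caseId", function(object) standardGeneric("caseId"))

#' @rdname MammoCase
#' @export
setMethod("caseId", "MammoCase", function(object) object@caseId)

#' Per-breast labels of a case
#'
#' @param object a [MammoCase-class].
#' @return named integer vector `c(left = , right = )`.
#' @export
setGeneric("breastLabels", function(object) standardGeneric("breastLabels"))

#' @rdname breastLabels
#' @export
setMethod("breastLabels", "MammoCase", function(object) {
  c(left = object@yLeft, right = object@yRight)
})

#' Bilateral label scenario of a case
#'
#' @param object a [MammoCase-class] (or see the numeric method in
#'   `scenarioOf`).
#' @return one of `"both_normal"`, `"both_cancer"`, `"one_cancer"`.
#' @export
setGeneric("scenarioOf", function(object) standardGeneric("scenarioOf"))

#' @rdname scenarioOf
#' @export
setMethod("scenarioOf", "MammoCase", function(object) {
  s <- object@yLeft + object@yRight
  c("both_normal", "one_cancer", "both_cancer")[s + 1L]
})

setMethod("show", "MammoCase", function(object) {
  d <- dim(object@views$L_CC)
  cat(sprintf("MammoCase '%s': 4 views (%d x %d), labels L=%d R=%d (%s)\n",
              object@caseId, d[1], d[2], object@yLeft, object@yRight,
              scenarioOf(object)))
})

#' MetricsReport: per-breast classification evaluation
#'
#' @slot counts named integer vector `tp, tn, fp, fn`.
#' @slot acc accuracy in percent.
#' @slot auc area under the ROC curve (rank statistic), `NA` if the
#'   ground truth has a single class.
#' @slot roc two-column matrix of (FPR, TPR) points.
#' @slot predictions data.frame with one row per evaluated breast
#'   (case_id, side, label, prob, pred).
#' @export
setClass("MetricsReport",
         representation(counts = "integer", acc = "numeric",
                        auc = "numeric", roc = "matrix",
                        predictions = "data.frame"))

setValidity("MetricsReport", function(object) {
  if (!all(c("tp", "tn", "fp", "fn") %in% names(object@counts))) {
    return("counts must be named tp, tn, fp, fn")
  }
  if (sum(object@counts) != nrow(object@predictions)) {
    return("confusion counts must sum to the number of evaluated breasts")
  }
  if (!is.na(object@auc) && (object@auc < 0 || object@auc > 1)) {
    return("auc must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "MetricsReport", function(object) {
  k <- object@counts
  cat(sprintf(
    "MetricsReport: %d breasts | TP %d TN %d FP %d FN %d | ACC %.2f%% | AUC %s\n",
    sum(k), k[["tp"]], k[["tn"]], k[["fp"]], k[["fn"]], object@acc,
    if (is.na(object@auc)) "undefined (single-class truth)"
    else sprintf("%.4f", object@auc)))
})
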