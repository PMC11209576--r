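# Synthetic four-view phantom generator. Emulates the aspects of screening
# mammograms the pipeline depends on: a bright, textured, roughly
# half-elliptical breast region touching one image edge on a dark
# background, and optional bright lesion blobs whose presence defines the
# per-breast label. The three bilateral label scenarios (both breasts
# normal, both cancerous, one cancerous) are all generated.

#' Specification for a synthetic bilateral mammogram dataset
#'
#' @param nCases number of cases (patients).
#' @param mix named proportions over the scenarios `both_normal`,
#'   `both_cancer`, `one_cancer`; must sum to 1.
#' @param imageSize `c(h, w)` of each generated view in pixels.
#' @param lesionRadius range (pixels) of lesion Gaussian radius.
#' @param lesionBoost peak intensity added by a lesion, on the unit scale.
#' @param lesionCount range of lesion blob counts per cancerous breast.
#' @param textureSigma smoothing radius (pixels) of the background texture.
#' @param seed RNG seed for the whole dataset.
#' @return an object of class `SynthSpec` (a validated list).
#' @export
synthSpec <- function(nCases = 100L,
                      mix = c(both_normal = 0.5, both_cancer = 0.25,
                              one_cancer = 0.25),
                      imageSize = c(256L, 256L),
                      lesionRadius = c(8, 20),
                      lesionBoost = 0.4,
                      lesionCount = c(1L, 3L),
                      textureSigma = 4,
                      seed = 1L) {
  stopifnot(nCases >= 1,
            abs(sum(mix) - 1) < 1e-8,
            all(sort(names(mix)) ==
                  c("both_cancer", "both_normal", "one_cancer")),
            length(imageSize) == 2, all(imageSize >= 32),
            max(lesionRadius) < min(imageSize) / 2,
            lesionBoost >= 0)
  structure(list(nCases = as.integer(nCases), mix = mix,
                 imageSize = as.integer(imageSize),
                 lesionRadius = lesionRadius, lesionBoost = lesionBoost,
                 lesionCount = as.integer(lesionCount),
                 textureSigma = textureSigma, seed = as.integer(seed)),
            class = "SynthSpec")
}

# Half-elliptical breast mask touching the left or right image edge.
breastMask <- function(h, w, side = c("left", "right")) {
  side <- match.arg(side)
  cy <- h / 2
  ay <- 0.42 * h
  ax <- 0.85 * w
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), w), h, w)
  xd <- if (side == "left") x - 1 else w - x
  (xd / ax)^2 + ((y - cy) / ay)^2 <= 1
}

#' Generate one synthetic mammogram view
#'
#' Draws from the current RNG state; wrap in [withSeed()] or `set.seed()`
#' for reproducibility.
#'
#' @param hasLesion add bright lesion blobs inside the breast region?
#' @param spec a [synthSpec()].
#' @param side image edge the chest wall touches (`"left"` or `"right"`).
#' @param lesions optional data.frame (relX, relY, radius) of lesion
#'   placements in region-relative coordinates, used to correlate lesion
#'   positions across the two views of the same breast.
#' @return matrix in [0,1] with attribute `lesionBoxes` (data.frame
#'   x0, y0, x1, y1, 0-based half-open) and `lesions` (the placements).
#' @export
generateView <- function(hasLesion, spec, side = "left", lesions = NULL) {
  h <- spec$imageSize[1]; w <- spec$imageSize[2]
  mask <- breastMask(h, w, side)
  noise <- matrix(stats::rnorm(h * w), h, w)
  texture <- as.matrix(EBImage::imageData(
    EBImage::gblur(noise, sigma = spec$textureSigma)))
  texture <- texture / max(abs(texture), 1e-12)
  img <- matrix(0.02, h, w) + 0.01 * matrix(stats::runif(h * w), h, w)
  img[mask] <- 0.45 + 0.15 * texture[mask]
  boxes <- NULL
  if (hasLesion && spec$lesionBoost > 0) {
    if (is.null(lesions)) {
      n <- sample(spec$lesionCount[1]:spec$lesionCount[2], 1L)
      lesions <- data.frame(
        relX = stats::runif(n, 0.15, 0.6),
        relY = stats::runif(n, 0.25, 0.75),
        radius = stats::runif(n, spec$lesionRadius[1], spec$lesionRadius[2]))
    }
    x <- matrix(rep(seq_len(w), each = h), h, w)
    y <- matrix(rep(seq_len(h), w), h, w)
    for (i in seq_len(nrow(lesions))) {
      cx <- if (side == "left") lesions$relX[i] * w else
        w - lesions$relX[i] * w
      cy <- lesions$relY[i] * h
      r <- lesions$radius[i]
      blob <- spec$lesionBoost *
        exp(-((x - cx)^2 + (y - cy)^2) / (2 * (r / 2)^2))
      img <- img + blob * mask
      boxes <- rbind(boxes, data.frame(
        x0 = max(0L, floor(cx - r)), y0 = max(0L, floor(cy - r)),
        x1 = min(w, ceiling(cx + r)), y1 = min(h, ceiling(cy + r))))
    }
  } else if (hasLesion && is.null(lesions)) {
    lesions <- data.frame(relX = numeric(0), relY = numeric(0),
                          radius = numeric(0))
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "lesionBoxes") <- boxes
  attr(img, "lesions") <- lesions
  img
}

#' Generate one synthetic bilateral four-view case
#'
#' Lesion placements are shared (in region-relative coordinates) between
#' the CC and MLO views of a cancerous breast, giving the cross-view
#' correspondence signal that cross-mammogram attention is meant to use.
#' The left breast's chest wall touches the left image edge and vice versa,
#' so orientation normalization is exercised on real variation.
#'
#' @param caseId case identifier string.
#' @param scenario one of `"both_normal"`, `"both_cancer"`, `"one_cancer"`.
#' @param spec a [synthSpec()].
#' @return a [MammoCase-class] object.
#' @export
generateCase <- function(caseId, scenario, spec) {
  scenario <- match.arg(scenario,
                        c("both_normal", "both_cancer", "one_cancer"))
  cancer <- switch(scenario,
                   both_normal = c(left = FALSE, right = FALSE),
                   both_cancer = c(left = TRUE, right = TRUE),
                   one_cancer = {
                     s <- sample(c("left", "right"), 1L)
                     c(left = s == "left", right = s == "right")
                   })
  views <- list()
  boxes <- list()
  for (sideName in c("left", "right")) {
    has <- cancer[[sideName]]
    lesions <- NULL
    if (has) {
      n <- sample(spec$lesionCount[1]:spec$lesionCount[2], 1L)
      lesions <- data.frame(
        relX = stats::runif(n, 0.15, 0.6),
        relY = stats::runif(n, 0.25, 0.75),
        radius = stats::runif(n, spec$lesionRadius[1], spec$lesionRadius[2]))
    }
    edge <- if (sideName == "left") "left" else "right"
    for (viewName in c("CC", "MLO")) {
      v <- generateView(has, spec, side = edge, lesions = lesions)
      key <- paste0(toupper(substr(sideName, 1, 1)), "_", viewName)
      boxes[[key]] <- attr(v, "lesionBoxes")
      attr(v, "lesions") <- NULL
      views[[key]] <- v
    }
  }
  MammoCase(caseId = caseId, views = views,
            yLeft = as.integer(cancer[["left"]]),
            yRight = as.integer(cancer[["right"]]),
            lesionBoxes = boxes)
}

scenarioCounts <- function(nCases, mix) {
  counts <- round(nCases * mix)
  diff <- nCases - sum(counts)
  counts[which.max(counts)] <- counts[which.max(counts)] + diff
  counts
}

#' Generate a list of synthetic cases in memory
#'
#' @param spec a [synthSpec()].
#' @return list of [MammoCase-class] objects, scenario counts following
#'   `spec$mix` exactly (after rounding to integers).
#' @export
generateCases <- function(spec) {
  counts <- scenarioCounts(spec$nCases, spec$mix)
  scenarios <- rep(names(counts), counts)
  withSeed(spec$seed, {
    scenarios <- sample(scenarios)
    lapply(seq_along(scenarios), function(i) {
      generateCase(sprintf("case_%04d", i), scenarios[i], spec)
    })
  })
}

#' Write a synthetic dataset to disk (PNG views + CSV manifest)
#'
#' The manifest has one row per view with columns
#' `case_id, laterality, view, path, label` -- the schema the dataset
#' module reads back.
#'
#' @param spec a [synthSpec()].
#' @param outDir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
generateDataset <- function(spec, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cases <- generateCases(spec)
  rows <- list()
  for (case in cases) {
    for (key in names(case@views)) {
      lat <- if (substr(key, 1, 1) == "L") "left" else "right"
      vw <- sub("^[LR]_", "", key)
      path <- file.path(outDir, paste0(case@caseId, "_", key, ".png"))
      png::writePNG(case@views[[key]], path)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case@caseId, laterality = lat, view = vw,
        path = basename(path),
        label = if (lat == "left") case@yLeft else case@yRight)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
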