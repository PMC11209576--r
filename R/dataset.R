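# Case assembly: label mapping, dual-view concatenation, patient-disjoint
# stratified splitting, scenario upsampling, balanced batch sampling, and
# training-time augmentation.

#' Map a dataset-specific annotation to a binary breast label
#'
#' Binarization conventions: for Mini-DDSM style labels, normal and benign
#' are negative and cancer positive; for VinDr-Mammo, BI-RADS 1-3 negative,
#' 4-5 positive; for INbreast, BI-RADS 1-3 negative, 4-6 positive.
#'
#' @param datasetKind one of `"mini-ddsm"`, `"vindr"`, `"inbreast"`.
#' @param annotation the raw annotation (label string or BI-RADS score).
#' @return integer 0 or 1.
#' @export
mapLabel <- function(datasetKind = c("mini-ddsm", "vindr", "inbreast"),
                     annotation) {
  datasetKind <- match.arg(datasetKind)
  if (datasetKind == "mini-ddsm") {
    a <- tolower(as.character(annotation))
    if (a %in% c("normal", "benign")) return(0L)
    if (a == "cancer") return(1L)
    stop("unknown mini-ddsm annotation: ", annotation)
  }
  b <- suppressWarnings(as.integer(annotation))
  hi <- if (datasetKind == "vindr") 5L else 6L
  if (is.na(b) || b < 1L || b > hi) {
    stop("invalid BI-RADS score for ", datasetKind, ": ", annotation)
  }
  as.integer(b >= 4L)
}

# Bilinear resize of a matrix to h x w (rows x cols).
resizeImage <- function(img, h, w) {
  if (nrow(img) == h && ncol(img) == w) return(img)
  # EBImage's first dimension is our row dimension
  as.matrix(EBImage::imageData(EBImage::resize(img, w = h, h = w)))
}

#' Concatenate the CC and MLO views of one breast into the model input
#'
#' Each view is resized to (height/2) x width and the two are stacked
#' vertically, CC on top. The single grayscale channel is replicated to
#' three channels so standard RGB-trained extractors apply unchanged.
#'
#' @param cc,mlo numeric matrices, the two views of one breast.
#' @param height,width output size (default 1280 x 640).
#' @param channels output channel count (grayscale replicated).
#' @param lateralityCC,lateralityMLO optional laterality tags; an error is
#'   raised if they disagree.
#' @return array `height x width x channels` in [0,1].
#' @export
concatViews <- function(cc, mlo, height = 1280L, width = 640L,
                        channels = 3L,
                        lateralityCC = NULL, lateralityMLO = NULL) {
  if (!is.null(lateralityCC) && !is.null(lateralityMLO) &&
      lateralityCC != lateralityMLO) {
    stop("laterality mismatch between CC and MLO views")
  }
  half <- height %/% 2L
  stacked <- rbind(resizeImage(cc, half, width),
                   resizeImage(mlo, half, width))
  stacked <- pmin(pmax(stacked, 0), 1)
  array(rep(stacked, channels), dim = c(height, width, channels))
}

caseScenarios <- function(cases) {
  vapply(cases, scenarioOf, character(1))
}

#' Patient-disjoint stratified train/test split
#'
#' Cases are split by case (patient), never by image, so no patient appears
#' in both partitions. The split is stratified by the bilateral label
#' scenario; the total test count equals `round(testFraction * n)`.
#'
#' @param cases list of [MammoCase-class] objects.
#' @param testFraction fraction of cases assigned to the test set.
#' @param seed RNG seed; the same seed always yields the same partition.
#' @return list with elements `train` and `test` (lists of cases).
#' @export
splitCases <- function(cases, testFraction = 0.2, seed = 1L) {
  n <- length(cases)
  if (n < 5L) stop("need at least 5 cases to split")
  scen <- caseScenarios(cases)
  strata <- split(seq_len(n), scen)
  nTest <- round(testFraction * n)
  quota <- vapply(strata, function(idx) round(testFraction * length(idx)),
                  numeric(1))
  # adjust rounding so the total is exact, preferring the largest strata
  delta <- nTest - sum(quota)
  ord <- order(vapply(strata, length, numeric(1)), decreasing = TRUE)
  i <- 1L
  while (delta != 0) {
    s <- ord[(i - 1L) %% length(ord) + 1L]
    step <- sign(delta)
    if (quota[s] + step >= 0 && quota[s] + step <= length(strata[[s]])) {
      quota[s] <- quota[s] + step
      delta <- delta - step
    }
    i <- i + 1L
  }
  testIdx <- withSeed(seed, {
    unlist(lapply(seq_along(strata), function(s) {
      idx <- strata[[s]]
      if (quota[s] == 0) return(integer(0))
      idx[sample.int(length(idx), quota[s])]
    }))
  })
  list(train = cases[setdiff(seq_len(n), testIdx)],
       test = cases[sort(testIdx)])
}

#' Upsample cancer-involved training cases by whole-case replication
#'
#' Cases involving cancer (both-cancer and one-cancer scenarios) are
#' replicated until their combined count equals the count of both-normal
#' cases, which the both-normal pool untouched. Replication is distributed
#' proportionally between the two cancer scenarios; the rounding remainder
#' goes to the both-cancer pool. If cancer-involved cases already match or
#' exceed the both-normal count, the input is returned unchanged.
#'
#' @param cases list of [MammoCase-class] training cases.
#' @return list of cases with duplicates appended (duplicates reference
#'   the same underlying objects).
#' @export
upsampleTraining <- function(cases) {
  scen <- caseScenarios(cases)
  nNormal <- sum(scen == "both_normal")
  idxBoth <- which(scen == "both_cancer")
  idxOne <- which(scen == "one_cancer")
  involved <- length(idxBoth) + length(idxOne)
  if (involved == 0L) stop("no cancer-involved cases to upsample")
  if (length(idxBoth) == 0L || length(idxOne) == 0L || nNormal == 0L) {
    stop("all three scenario counts must be positive")
  }
  extra <- nNormal - involved
  if (extra <= 0L) return(cases)
  extraOne <- floor(extra * length(idxOne) / involved)
  extraBoth <- extra - extraOne
  replicatePool <- function(idx, k) {
    if (k == 0L) return(integer(0))
    rep(idx, length.out = k)
  }
  dup <- c(replicatePool(idxBoth, extraBoth), replicatePool(idxOne, extraOne))
  c(cases, cases[dup])
}

#' Balanced batch sampler over the two case categories
#'
#' Every full batch contains `batchSize/2` cancer-involved cases and
#' `batchSize/2` both-normal cases, mirroring a per-patient balanced
#' sampler. The larger category is covered at most once per epoch; the
#' smaller is cycled (reshuffled each pass).
#'
#' @param cases list of [MammoCase-class] objects.
#' @param batchSize even batch size (default 8).
#' @param seed RNG seed; the same seed reproduces the batch sequence.
#' @return list of integer index vectors into `cases`, one per batch.
#' @export
balancedBatches <- function(cases, batchSize = 8L, seed = 1L) {
  if (batchSize %% 2L != 0L) stop("batchSize must be even")
  scen <- caseScenarios(cases)
  normal <- which(scen == "both_normal")
  cancer <- which(scen != "both_normal")
  if (length(normal) == 0L || length(cancer) == 0L) {
    stop("both case categories (both-normal, cancer-involved) must be non-empty")
  }
  half <- batchSize %/% 2L
  nBatches <- max(1L, floor(max(length(normal), length(cancer)) / half))
  need <- nBatches * half
  stream <- function(idx) {
    out <- integer(0)
    while (length(out) < need) out <- c(out, sample(idx))
    out[seq_len(need)]
  }
  withSeed(seed, {
    sn <- stream(normal)
    sc <- stream(cancer)
    lapply(seq_len(nBatches), function(b) {
      rows <- ((b - 1L) * half + 1L):(b * half)
      sample(c(sn[rows], sc[rows]))
    })
  })
}

#' Augmentation configuration
#'
#' All probabilities set to zero give the exact identity.
#'
#' @param pHflip,pVflip flip probabilities.
#' @param pCrop probability of a random resized crop; `cropScale` is the
#'   retained-area range.
#' @param pAffine probability of a random rotation/translation;
#'   `maxRotate` in degrees, `maxTranslate` as a fraction of each axis.
#' @param pJitter probability of brightness/contrast jitter of strength
#'   `jitter`.
#' @param pErase probability of erasing one random rectangle covering a
#'   fraction of the image in `eraseArea`.
#' @return list of class `AugmentConfig`.
#' @export
augmentConfig <- function(pHflip = 0.5, pVflip = 0.5,
                          pCrop = 0.5, cropScale = c(0.8, 1.0),
                          pAffine = 0.5, maxRotate = 10,
                          maxTranslate = 0.05,
                          pJitter = 0.5, jitter = 0.2,
                          pErase = 0.5, eraseArea = c(0.02, 0.10)) {
  structure(as.list(environment()), class = "AugmentConfig")
}

augmentMatrix <- function(img, cfg) {
  h <- nrow(img); w <- ncol(img)
  if (cfg$pHflip > 0 && stats::runif(1) < cfg$pHflip) {
    img <- img[, rev(seq_len(w)), drop = FALSE]
  }
  if (cfg$pVflip > 0 && stats::runif(1) < cfg$pVflip) {
    img <- img[rev(seq_len(h)), , drop = FALSE]
  }
  if (cfg$pCrop > 0 && stats::runif(1) < cfg$pCrop) {
    area <- stats::runif(1, cfg$cropScale[1], cfg$cropScale[2])
    side <- sqrt(area)
    ch <- max(1L, round(h * side)); cw <- max(1L, round(w * side))
    y0 <- sample.int(h - ch + 1L, 1L); x0 <- sample.int(w - cw + 1L, 1L)
    img <- resizeImage(img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L),
                           drop = FALSE], h, w)
  }
  if (cfg$pAffine > 0 && stats::runif(1) < cfg$pAffine) {
    ang <- stats::runif(1, -cfg$maxRotate, cfg$maxRotate)
    img <- as.matrix(EBImage::imageData(
      EBImage::rotate(img, ang, output.dim = c(h, w))))
    tv <- c(stats::runif(1, -cfg$maxTranslate, cfg$maxTranslate) * h,
            stats::runif(1, -cfg$maxTranslate, cfg$maxTranslate) * w)
    img <- as.matrix(EBImage::imageData(EBImage::translate(img, tv)))
  }
  if (cfg$pJitter > 0 && stats::runif(1) < cfg$pJitter) {
    gain <- 1 + stats::runif(1, -cfg$jitter, cfg$jitter)
    bias <- stats::runif(1, -cfg$jitter, cfg$jitter) * 0.5
    img <- gain * img + bias
  }
  if (cfg$pErase > 0 && stats::runif(1) < cfg$pErase) {
    frac <- stats::runif(1, cfg$eraseArea[1], cfg$eraseArea[2])
    eh <- max(1L, round(h * sqrt(frac))); ew <- max(1L, round(w * sqrt(frac)))
    y0 <- sample.int(h - eh + 1L, 1L); x0 <- sample.int(w - ew + 1L, 1L)
    img[y0:(y0 + eh - 1L), x0:(x0 + ew - 1L)] <- 0
  }
  pmin(pmax(img, 0), 1)
}

#' Randomly augment a breast input tensor
#'
#' Applies, with the configured probabilities: horizontal/vertical flips,
#' random resized crop, random rotation/translation, brightness/contrast
#' jitter, and random rectangular erasing. The same transform is applied
#' to every channel; output shape equals input shape.
#'
#' @param x array `h x w x c` (or matrix) in [0,1].
#' @param cfg an [augmentConfig()].
#' @return augmented array of identical shape.
#' @export
augmentImage <- function(x, cfg = augmentConfig()) {
  if (is.matrix(x)) return(augmentMatrix(x, cfg))
  state <- get(".Random.seed", envir = globalenv())
  out <- x
  for (c in seq_len(dim(x)[3])) {
    assign(".Random.seed", state, envir = globalenv())
    out[, , c] <- augmentMatrix(x[, , c], cfg)
  }
  out
}

#' Read a four-view case manifest CSV
#'
#' Expected columns: `case_id, laterality, view, path, label`.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "laterality", "view", "path", "label")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "))
  }
  if (!all(m$laterality %in% c("left", "right"))) {
    stop("laterality must be 'left' or 'right'")
  }
  if (!all(m$view %in% c("CC", "MLO"))) stop("view must be 'CC' or 'MLO'")
  if (!all(m$label %in% c(0L, 1L))) stop("labels must be binary")
  m
}

#' Load cases from a manifest
#'
#' @param manifest data.frame from [readManifest()] or a CSV path.
#' @param dir directory resolving relative image paths.
#' @return list of [MammoCase-class] objects.
#' @export
loadCases <- function(manifest, dir = ".") {
  if (is.character(manifest)) {
    dir <- dirname(manifest)
    manifest <- readManifest(manifest)
  }
  lapply(split(manifest, manifest$case_id), function(rows) {
    if (nrow(rows) != 4L) {
      stop("case ", rows$case_id[1], " does not have exactly 4 views")
    }
    views <- list()
    yl <- yr <- NA_integer_
    for (i in seq_len(4L)) {
      key <- paste0(toupper(substr(rows$laterality[i], 1, 1)), "_",
                    rows$view[i])
      p <- rows$path[i]
      if (!file.exists(p)) p <- file.path(dir, p)
      views[[key]] <- png::readPNG(p)
      if (rows$laterality[i] == "left") yl <- rows$label[i]
      else yr <- rows$label[i]
    }
    MammoCase(rows$case_id[1], views, yl, yr)
  })
}
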