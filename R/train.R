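# Training loop: balanced batches over prepared cases, Adam with weight
# decay, plateau learning-rate schedule on the epoch training loss.

#' Training configuration
#'
#' Defaults follow the standard protocol for this architecture: Adam with
#' learning rate 1e-4 and weight decay 5e-4, batch size 8, and a
#' reduce-on-plateau schedule dividing the learning rate by 10 after 3
#' epochs without improvement of the epoch loss.
#'
#' @param lr initial learning rate.
#' @param weightDecay L2 weight decay added to the gradients.
#' @param batchSize even batch size (cases per step).
#' @param lrPatience epochs without improvement before the LR drops.
#' @param lrFactor multiplicative LR drop factor.
#' @param maxEpochs number of training epochs.
#' @param clipNorm global gradient-norm clip applied to each averaged
#'   batch gradient (`Inf` disables clipping).
#' @param seed RNG seed controlling batching, dropout and augmentation.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(lr = 1e-4, weightDecay = 5e-4, batchSize = 8L,
                        lrPatience = 3L, lrFactor = 0.1, maxEpochs = 10L,
                        clipNorm = Inf, seed = 1L) {
  stopifnot(lr > 0, batchSize %% 2L == 0L, maxEpochs >= 1L, clipNorm > 0)
  structure(list(lr = lr, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize),
                 lrPatience = as.integer(lrPatience), lrFactor = lrFactor,
                 maxEpochs = as.integer(maxEpochs), clipNorm = clipNorm,
                 seed = as.integer(seed)),
            class = "TrainConfig")
}

# Scale a gradient set so its global L2 norm does not exceed maxNorm.
clipGradients <- function(grads, maxNorm) {
  if (!is.finite(maxNorm)) return(grads)
  total <- sqrt(sum(unlist(paramMap(function(x) sum(x^2), grads))))
  if (total <= maxNorm) return(grads)
  scaleGrads(grads, maxNorm / total)
}

# Plateau LR scheduler state machine (monitors the training epoch loss).
plateauStep <- function(state, loss, patience, factor) {
  if (is.null(state$best) || loss < state$best - 1e-12) {
    state$best <- loss
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad >= patience) {
      state$lr <- state$lr * factor
      state$bad <- 0L
    }
  }
  state
}

#' Train the bilateral classification model
#'
#' Per step: a balanced batch (half both-normal, half cancer-involved
#' cases) is pushed through backbone, cross-attention, contrastive loss
#' and both heads; gradients of the weighted joint objective are averaged
#' over the batch and applied with Adam. Training aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model a `CrossMammoModel`.
#' @param cases list of [MammoCase-class] training cases (typically
#'   upsampled).
#' @param cfg a [trainConfig()].
#' @param preprocess preprocess raw views when preparing inputs?
#' @param augment an [augmentConfig()], or `NULL` to disable
#'   augmentation.
#' @param checkpointDir if non-NULL, a checkpoint and a JSON loss history
#'   are written there after every epoch.
#' @param verbose print per-epoch progress?
#' @return list `(model, history)`; `history` is a data.frame with one
#'   row per epoch (epoch, loss, lSim, lCls, lr).
#' @export
trainModel <- function(model, cases, cfg = trainConfig(),
                       preprocess = TRUE, augment = augmentConfig(),
                       checkpointDir = NULL, verbose = FALSE) {
  if (length(cases) == 0L) stop("empty training manifest")
  prepared <- lapply(cases, prepareCase, cfg = model$cfg,
                     preprocess = preprocess)
  params <- modelParams(model)
  opt <- adamInit(params)
  sched <- list(lr = cfg$lr, best = NULL, bad = 0L)
  history <- NULL
  withSeed(cfg$seed, {
    for (epoch in seq_len(cfg$maxEpochs)) {
      batches <- balancedBatches(cases, cfg$batchSize,
                                 seed = cfg$seed + 104729L * epoch)
      epochLoss <- epochSim <- epochCls <- 0
      nSteps <- 0L
      for (batch in batches) {
        grads <- NULL
        batchLoss <- batchSim <- batchCls <- 0
        for (ci in batch) {
          p <- prepared[[ci]]
          xL <- p$xL; xR <- p$xR
          if (!is.null(augment)) {
            xL <- augmentImage(xL, augment)
            xR <- augmentImage(xR, augment)
          }
          fwd <- modelForward(model, xL, xR, p$yLeft, p$yRight,
                              train = TRUE, cache = TRUE)
          if (!is.finite(fwd$loss)) {
            stop(sprintf(
              "non-finite loss at epoch %d (case %s): lSim=%g lCls=%g/%g",
              epoch, p$caseId, fwd$lSim, fwd$lClsLeft, fwd$lClsRight))
          }
          g <- modelBackward(model, fwd)
          grads <- if (is.null(grads)) g else addGrads(grads, g)
          batchLoss <- batchLoss + fwd$loss
          batchSim <- batchSim + fwd$lSim
          batchCls <- batchCls + fwd$lClsLeft + fwd$lClsRight
        }
        grads <- clipGradients(scaleGrads(grads, 1 / length(batch)),
                               cfg$clipNorm)
        upd <- adamStep(params, grads, opt, lr = sched$lr,
                        weightDecay = cfg$weightDecay)
        params <- upd$params
        opt <- upd$state
        model <- setModelParams(model, params)
        epochLoss <- epochLoss + batchLoss / length(batch)
        epochSim <- epochSim + batchSim / length(batch)
        epochCls <- epochCls + batchCls / length(batch)
        nSteps <- nSteps + 1L
      }
      row <- data.frame(epoch = epoch, loss = epochLoss / nSteps,
                        lSim = epochSim / nSteps, lCls = epochCls / nSteps,
                        lr = sched$lr)
      history <- rbind(history, row)
      if (verbose) {
        message(sprintf(
          "epoch %d: loss %.4f (sim %.4f, cls %.4f), lr %g",
          epoch, row$loss, row$lSim, row$lCls, row$lr))
      }
      sched <- plateauStep(sched, row$loss, cfg$lrPatience, cfg$lrFactor)
      if (!is.null(checkpointDir)) {
        dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
        saveModel(model, file.path(checkpointDir, "model.rds"))
        jsonlite::write_json(history,
                             file.path(checkpointDir, "history.json"),
                             dataframe = "rows", digits = NA)
      }
    }
  })
  list(model = model, history = history)
}
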