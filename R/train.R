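# Training: binary cross-entropy on residue labels, Adam updates one protein
# pair at a time, validation-loss early stopping, best-checkpoint retention.

#' Training configuration
#'
#' @param maxEpochs Maximum number of epochs (default 50).
#' @param patience Early-stopping patience in epochs (default 10): training
#'   stops once the validation loss has not improved for this many
#'   consecutive epochs.
#' @param learningRate Adam learning rate (default 1e-3).
#' @param batchPairs Pairs per optimisation step (default 1; variable
#'   sequence lengths make per-pair steps the natural granularity).
#' @param seed Seed controlling shuffling and dropout masks.
#' @param optimizerTag Free-text optimizer label (default "adam").
#' @param positiveWeight Optional weight multiplying the positive-class term
#'   of the loss (default 1: plain unweighted BCE).
#' @return A `TrainConfig` list.
#' @export
trainConfig <- function(maxEpochs = 50L, patience = 10L, learningRate = 1e-3,
                        batchPairs = 1L, seed = 0L, optimizerTag = "adam",
                        positiveWeight = 1) {
  if (patience > maxEpochs)
    stop("patience must be <= maxEpochs", call. = FALSE)
  if (learningRate <= 0) stop("learningRate must be > 0", call. = FALSE)
  structure(list(maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 learningRate = learningRate,
                 batchPairs = as.integer(batchPairs),
                 seed = as.integer(seed), optimizerTag = optimizerTag,
                 positiveWeight = positiveWeight),
            class = "TrainConfig")
}

#' Mean binary cross-entropy between a probability track and labels
#'
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before taking logs.
#'
#' @param probabilities Numeric vector (or
#'   [ResidueProbabilityTrack-class]) of predicted probabilities.
#' @param labels 0/1 vector of the same length.
#' @return Mean of `-(y log p + (1 - y) log(1 - p))` over residues.
#' @examples
#' bceLoss(c(0.9, 0.2), c(1, 0))
#' @export
bceLoss <- function(probabilities, labels) {
  if (is(probabilities, "ResidueProbabilityTrack"))
    probabilities <- probabilities(probabilities)
  if (length(probabilities) != length(labels))
    stop("shape error: probabilities and labels differ in length", call. = FALSE)
  bceCore(probabilities, as.numeric(labels))
}

#' Advance the early-stopping state by one observed validation loss
#'
#' Strict improvement (`valLoss < bestValLoss`) resets the patience counter
#' and snapshots the parameters; otherwise the counter increments.
#'
#' @param state List with `bestValLoss`, `sinceImprovement`, `bestParams`
#'   (use `NULL` to start).
#' @param valLoss Validation loss observed this epoch.
#' @param params Current parameters (snapshotted on improvement).
#' @return Updated state; `state$stop` is TRUE once `sinceImprovement`
#'   reaches the patience.
#' @export
updateTrainState <- function(state, valLoss, params, patience) {
  if (is.null(state))
    state <- list(bestValLoss = Inf, sinceImprovement = 0L, bestParams = NULL)
  if (valLoss < state$bestValLoss) {
    state$bestValLoss <- valLoss
    state$sinceImprovement <- 0L
    state$bestParams <- params
  } else {
    state$sinceImprovement <- state$sinceImprovement + 1L
  }
  state$stop <- state$sinceImprovement >= patience
  state
}

evalLoss <- function(pairs, params, config, positiveWeight = 1) {
  losses <- vapply(pairs, function(pr) {
    p <- forwardPair(pr$EA, pr$EB, params, config, keep = FALSE, dropout = FALSE)
    if (positiveWeight == 1) bceCore(p, pr$labels)
    else weightedBce(p, pr$labels, positiveWeight)
  }, numeric(1))
  mean(losses)
}

weightedBce <- function(p, y, w, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(w * y * log(p) + (1 - y) * log(1 - p))
}

#' Train the cross-attention model
#'
#' Optimises the model with Adam on one pair per step, evaluates the
#' validation loss after every epoch, and applies early stopping when the
#' validation loss has not improved for `patience` consecutive epochs. The
#' parameters achieving the lowest validation loss are returned.
#'
#' @param trainPairs,valPairs Non-empty lists of
#'   `list(EA = EmbeddingMatrix, EB = EmbeddingMatrix, labels = 0/1 vector)`
#'   with `labels` aligned to the query (EA) residues.
#' @param params Initial `ModelParams` (e.g. from [initModel()]).
#' @param config Training settings from [trainConfig()].
#' @param modelConfig Architecture; defaults to the one stored in `params`.
#' @param verbose Print one log line per epoch.
#' @return List with `bestParams` (with `trained = TRUE`), `history`
#'   (data.frame: epoch, train_loss, val_loss, since_improvement) and
#'   `bestValLoss`.
#' @export
trainModel <- function(trainPairs, valPairs, params, config = trainConfig(),
                       modelConfig = params$config, verbose = FALSE) {
  if (!length(trainPairs) || !length(valPairs))
    stop("data error: training and validation sets must be non-empty",
         call. = FALSE)
  opt <- adamInit(params)
  state <- NULL
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), since_improvement = integer())
  w <- config$positiveWeight
  for (epoch in seq_len(config$maxEpochs)) {
    order <- withSeed(subSeed(config$seed, paste0("epoch", epoch)),
                      sample.int(length(trainPairs)))
    epochLoss <- 0
    withSeed(subSeed(config$seed, paste0("dropout", epoch)), {
      batches <- split(order, ceiling(seq_along(order) / config$batchPairs))
      for (batch in batches) {
        acc <- NULL
        for (i in batch) {
          pr <- trainPairs[[i]]
          gr <- pairGradients(pr$EA, pr$EB, pr$labels, params, modelConfig,
                              dropout = TRUE, posWeight = w)
          if (!is.finite(gr$loss))
            stop("numerical-failure error: non-finite loss at epoch ", epoch,
                 call. = FALSE)
          epochLoss <- epochLoss + gr$loss
          if (is.null(acc)) acc <- gr$grads
          else for (nm in paramNames()) acc[[nm]] <- acc[[nm]] + gr$grads[[nm]]
        }
        if (length(batch) > 1L)
          for (nm in paramNames()) acc[[nm]] <- acc[[nm]] / length(batch)
        upd <- adamStep(params, acc, opt, lr = config$learningRate)
        params <- upd$params; opt <- upd$state
      }
    })
    valLoss <- evalLoss(valPairs, params, modelConfig, w)
    if (!is.finite(valLoss))
      stop("numerical-failure error: non-finite validation loss at epoch ",
           epoch, call. = FALSE)
    state <- updateTrainState(state, valLoss, params, config$patience)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epochLoss / length(trainPairs),
      val_loss = valLoss, since_improvement = state$sinceImprovement))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f  patience %d/%d",
                      epoch, epochLoss / length(trainPairs), valLoss,
                      state$sinceImprovement, config$patience))
    if (state$stop) break
  }
  best <- state$bestParams
  best$trained <- TRUE
  list(bestParams = best, history = history, bestValLoss = state$bestValLoss)
}
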