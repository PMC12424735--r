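#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood of binary labels under predicted
#' probabilities; scores are clamped at 1e-12 from both ends before the
#' logarithms.
#'
#' @param scores predicted probabilities
#' @param labels binary labels (0/1), same length
#' @return Non-negative scalar loss.
#' @examples
#' bceLoss(c(0.5, 0.5), c(1, 0))  # ln 2
#' @export
bceLoss <- function(scores, labels) {
  if (!length(scores)) stop("empty input to bceLoss")
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  p <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Gamma-weighted multitask batch loss
#'
#' For a task-homogeneous batch the multitask loss reduces to the batch's
#' own cross-entropy, weighted by `gamma` when the batch task is
#' methylation; the three other tasks contribute exactly zero for this
#' batch. `gamma >= 1` up-weights methylation errors relative to the more
#' numerous auxiliary-PTM instances (candidate values 1, 13.5, 20; the
#' shipped default is 20).
#'
#' @param scores head probabilities for the batch's task
#' @param labels binary labels
#' @param task the batch's PTM task
#' @param gamma methylation loss weight (>= 1)
#' @return Non-negative scalar loss.
#' @export
multitaskBatchLoss <- function(scores, labels, task, gamma = 20) {
  .assertTask(task)
  if (gamma < 1) stop("gamma must be >= 1")
  w <- if (task == "methylation") gamma else 1
  w * bceLoss(scores, labels)
}

#' Task-homogeneous batch sampler
#'
#' Shuffles each task's instances once per epoch and emits batches drawn
#' from a single task each; the batch order is itself shuffled, so tasks
#' interleave in proportion to their dataset sizes. Every instance appears
#' exactly once per epoch; final partial batches are kept. Tasks with no
#' instances emit nothing (with a message).
#'
#' @param taskIndices named list mapping task -> integer vector of instance
#'   indices
#' @param batchSize maximum batch size (>= 1)
#' @param seed integer RNG seed for this epoch
#' @return List of batches, each a list with `task` and `idx`.
#' @export
taskBatchSampler <- function(taskIndices, batchSize, seed = 1L) {
  if (batchSize < 1L) stop("batchSize must be >= 1")
  set.seed(as.integer(seed))
  batches <- list()
  for (task in names(taskIndices)) {
    idx <- taskIndices[[task]]
    if (!length(idx)) {
      message("task '", task, "' has no instances; emitting no batches")
      next
    }
    idx <- idx[sample.int(length(idx))]
    starts <- seq(1L, length(idx), by = batchSize)
    for (s in starts)
      batches[[length(batches) + 1L]] <-
        list(task = task, idx = idx[s:min(s + batchSize - 1L, length(idx))])
  }
  if (length(batches) > 1L) batches <- batches[sample(length(batches))]
  batches
}

#' Early-stopped Adam training
#'
#' Fits a model by per-batch Adam updates with early stopping on the
#' methylation validation loss. Works for single-task models (all batches
#' one task) and multitask transformers (task-homogeneous batches, gamma
#' weighting, per-head gradient isolation: a step on a task-t batch leaves
#' the other heads' parameters bitwise unchanged).
#'
#' @param model an initialised `TransformerModel` or `MLPModel`
#' @param train embedded training dataset ([embedDataset()]) for transformer
#'   models, or a list `list(x = matrix, label = vector, task = vector)` for
#'   MLPs
#' @param validation validation dataset of the same shape; early stopping
#'   monitors the methylation instances (all instances if
#'   `monitorAllTasks`)
#' @param lr Adam learning rate
#' @param batchSize batch size (64 for MLPs, 128 for transformers, the
#'   shipped defaults)
#' @param gamma methylation loss weight (multitask only; 1 recovers the
#'   single-task loss)
#' @param patience epochs without validation-loss improvement before
#'   stopping (default 10)
#' @param maxEpochs epoch cap (default 100)
#' @param seed integer RNG seed (batch order, dropout)
#' @param monitorAllTasks include non-methylation validation instances in
#'   the early-stopping loss
#' @param verbose print one line per epoch
#' @return A `TrainState` list: `model` (best parameters), `epoch`,
#'   `bestEpoch`, `bestValidationLoss`, `bestValidationAUPRC`, `history`
#'   (per-epoch data.frame).
#' @export
fitEarlyStopping <- function(model, train, validation, lr = 1e-3,
                             batchSize = if (is(model, "MLPModel")) 64L
                                         else 128L,
                             gamma = 1, patience = 10L, maxEpochs = 100L,
                             seed = 1L, monitorAllTasks = FALSE,
                             verbose = FALSE) {
  isMLP <- is(model, "MLPModel")
  tasks <- if (isMLP) "methylation" else names(model@spec$headHidden)
  trainTask <- if (isMLP) rep("methylation", length(train$label))
               else train$task
  taskIndices <- setNames(lapply(tasks, function(t) which(trainTask == t)),
                          tasks)
  monTask <- if (isMLP) rep("methylation", length(validation$label))
             else validation$task
  monIdx <- if (monitorAllTasks) seq_along(validation$label)
            else which(monTask == "methylation")
  if (!length(monIdx))
    stop("validation set has no methylation instances to monitor")
  state <- .adamInit()
  best <- list(loss = Inf, auprc = NA_real_, params = model@params,
               epoch = 0L)
  wait <- 0L
  history <- list()
  for (epoch in seq_len(maxEpochs)) {
    batches <- taskBatchSampler(taskIndices, batchSize,
                                seed = seed + epoch)
    set.seed(seed * 1000L + epoch)  # dropout stream
    epochLoss <- 0
    for (b in batches) {
      if (isMLP) {
        g <- .mlpGrad(model, train$x[b$idx, , drop = FALSE],
                      train$label[b$idx])
      } else {
        scale <- if (b$task == "methylation") gamma else 1
        g <- .transformerGrad(model, subsetDataset(train, b$idx), b$task,
                              train$label[b$idx], lossScale = scale)
      }
      if (!is.finite(g$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      model@params <- .adamStep(state, model@params, g$grads, lr)
      epochLoss <- epochLoss + g$loss
    }
    valScores <- if (isMLP) {
      as.vector(.mlpForward(model,
                            validation$x[monIdx, , drop = FALSE])$prob)
    } else {
      vdata <- subsetDataset(validation, monIdx)
      if (monitorAllTasks) {
        out <- numeric(length(monIdx))
        for (t in unique(vdata$task)) {
          sel <- vdata$task == t
          out[sel] <- predictSites(model, subsetDataset(vdata, which(sel)),
                                   task = t)
        }
        out
      } else predictSites(model, vdata, task = "methylation")
    }
    valLabels <- validation$label[monIdx]
    valLoss <- bceLoss(valScores, valLabels)
    valAUPRC <- if (length(unique(valLabels)) == 2L)
      prRocCurves(valScores, valLabels)$auprc else NA_real_
    history[[epoch]] <- data.frame(epoch = epoch,
                                   trainLoss = epochLoss / length(batches),
                                   validationLoss = valLoss,
                                   validationAUPRC = valAUPRC)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  val AUPRC %.4f",
                      epoch, epochLoss / length(batches), valLoss,
                      valAUPRC))
    if (valLoss < best$loss) {
      best <- list(loss = valLoss, auprc = valAUPRC,
                   params = model@params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > patience) break
    }
  }
  model@params <- best$params
  list(model = model, epoch = epoch, bestEpoch = best$epoch,
       bestValidationLoss = best$loss, bestValidationAUPRC = best$auprc,
       history = do.call(rbind, history))
}

#' Randomised hyperparameter search
#'
#' Draws `nTrials` independent configurations from a sampling space and
#' returns the one with the highest objective value (validation AUPRC by
#' convention), with the full trial log. Stands in for a plain random-
#' sampling tuner.
#'
#' @param space named list of samplers; each element is either a function
#'   (called with no arguments to draw a value) or a vector to sample
#'   uniformly from
#' @param objective function(config) -> numeric score (larger is better);
#'   trials whose objective errors are recorded as failed
#' @param nTrials number of draws (>= 1; the reference protocol used 50)
#' @param seed integer RNG seed
#' @return list with `best` (config), `bestScore`, and `trials`
#'   (data.frame log with one row per trial).
#' @export
randomSearch <- function(space, objective, nTrials = 50L, seed = 1L) {
  if (nTrials < 1L) stop("nTrials must be >= 1")
  set.seed(as.integer(seed))
  configs <- vector("list", nTrials)
  for (i in seq_len(nTrials))
    configs[[i]] <- lapply(space, function(s)
      if (is.function(s)) s() else if (length(s) > 1L) sample(s, 1L) else s)
  scores <- rep(NA_real_, nTrials)
  errors <- character(nTrials)
  for (i in seq_len(nTrials)) {
    r <- tryCatch(objective(configs[[i]]), error = function(e)
      structure(NA_real_, msg = conditionMessage(e)))
    scores[i] <- as.numeric(r)
    if (!is.null(attr(r, "msg"))) errors[i] <- attr(r, "msg")
  }
  log <- cbind(data.frame(trial = seq_len(nTrials), score = scores,
                          error = errors),
               do.call(rbind, lapply(configs, function(cf)
                 as.data.frame(lapply(cf, function(v)
                   paste(v, collapse = "/")), stringsAsFactors = FALSE))))
  if (all(is.na(scores)))
    stop("all ", nTrials, " trials failed; first error: ",
         errors[errors != ""][1L])
  bestIdx <- which.max(scores)
  list(best = configs[[bestIdx]], bestScore = scores[bestIdx], trials = log)
}

#' Log-uniform sampler helper for [randomSearch()]
#'
#' @param lo,hi positive range bounds
#' @return A zero-argument sampler function.
#' @export
logUniformSampler <- function(lo, hi) {
  force(lo); force(hi)
  function() exp(runif(1L, log(lo), log(hi)))
}
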