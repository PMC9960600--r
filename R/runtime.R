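.runtimeFeatures <- c("nCells", "k", "cpus", "tasksPerNode", "cpusPerTask")

#' Assemble run-time logs
#'
#' Builds the log table consumed by [fitRuntimeModel()]: dataset size,
#' cluster count, compute resources, and the elapsed wall time of a
#' clustering run.
#'
#' @param nCells,k,cpus,tasksPerNode,cpusPerTask,elapsedSeconds vectors of
#'   equal length (scalars recycled); all positive.
#' @return A data.frame with one row per run.
#' @export
runtimeLogs <- function(nCells, k, cpus = 1L, tasksPerNode = 1L,
                        cpusPerTask = 1L, elapsedSeconds) {
  logs <- data.frame(nCells = nCells, k = k, cpus = cpus,
                     tasksPerNode = tasksPerNode,
                     cpusPerTask = cpusPerTask,
                     elapsedSeconds = elapsedSeconds)
  if (any(as.matrix(logs) <= 0))
    stop("all log fields must be positive")
  logs
}

#' Fit the run-time regressor
#'
#' Trains a random-forest regressor mapping dataset size, cluster count
#' and compute resources to elapsed clustering time, so that run times of
#' new datasets can be budgeted in advance.
#'
#' @param logs data.frame with columns `nCells`, `k`, `cpus`,
#'   `tasksPerNode`, `cpusPerTask`, `elapsedSeconds` (see
#'   [runtimeLogs()]); at least 10 rows.
#' @param seed integer seed; predictions are deterministic given the seed.
#' @param ntree number of trees (default 500).
#' @return A [RuntimeModel-class].
#' @export
fitRuntimeModel <- function(logs, seed = 1L, ntree = 500L) {
  missing <- setdiff(c(.runtimeFeatures, "elapsedSeconds"), names(logs))
  if (length(missing))
    stop("missing log columns: ", paste(missing, collapse = ", "))
  if (nrow(logs) < 10L)
    stop("at least 10 run logs are required, got ", nrow(logs))
  set.seed(as.integer(seed))
  # resource features that never vary in the collected logs carry no
  # signal but would stall tree splits whenever the per-split feature
  # sample draws only them; fit on the informative features
  varying <- .runtimeFeatures[vapply(
    logs[.runtimeFeatures], function(v) length(unique(v)) > 1L,
    logical(1))]
  if (!length(varying)) varying <- .runtimeFeatures[1L]
  fit <- randomForest::randomForest(
    x = logs[, varying, drop = FALSE],
    y = logs$elapsedSeconds, ntree = ntree,
    mtry = max(1L, ceiling(length(varying) * 2 / 3)))
  new("RuntimeModel", fit = fit, features = .runtimeFeatures,
      seed = as.integer(seed))
}

#' Predict run times
#'
#' @param model a [RuntimeModel-class].
#' @param logs data.frame containing the model's feature columns.
#' @return Numeric vector of predicted elapsed seconds.
#' @export
predictRuntime <- function(model, logs) {
  missing <- setdiff(model@features, names(logs))
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  as.numeric(stats::predict(model@fit,
                            logs[, model@features, drop = FALSE]))
}

#' Mean absolute error of run-time predictions
#'
#' @param model a [RuntimeModel-class].
#' @param logs data.frame with the feature columns and `elapsedSeconds`.
#' @return Mean of `|predicted - actual|`, in seconds; zero iff the model
#'   reproduces every log exactly.
#' @export
evaluateRuntimeModel <- function(model, logs) {
  if (!nrow(logs)) stop("no logs to evaluate")
  mean(abs(predictRuntime(model, logs) - logs$elapsedSeconds))
}
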