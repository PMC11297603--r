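# The progressive multitask stacked-forest learner. One probability forest
# per task per layer; layer 1 sees the raw fingerprint, every deeper layer
# sees the fingerprint concatenated with all tasks' class-1 scores from the
# layer below, so information moves between tasks through the score columns
# even when the tasks' chemical collections are disjoint.

#' Rank-based ROC AUC with midrank tie handling
#'
#' The Mann-Whitney form of the area under the ROC curve: the probability
#' that a random positive outscores a random negative, with half credit for
#' ties. Computed from midranks, so it matches exhaustive enumeration of
#' all positive-negative pairs exactly.
#'
#' @param predScores numeric score vector.
#' @param trueLabels 0/1 vector of the same length.
#' @return AUC in [0, 1].
#' @export
#' @examples
#' rocAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' rocAUC(c(0.5, 0.5, 0.5), c(1, 0, 1))          # 0.5
rocAUC <- function(predScores, trueLabels) {
  if (length(predScores) != length(trueLabels))
    stop("scores and labels differ in length")
  trueLabels <- as.integer(trueLabels)
  nPos <- sum(trueLabels == 1L)
  nNeg <- sum(trueLabels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: only one class present")
  r <- rank(predScores, ties.method = "average")
  (sum(r[trueLabels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Largest-remainder allocation of n items to fractions (sums to n exactly).
allocateCounts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign stratified train/validation/test tags to a task
#'
#' Splits the task's chemicals into train/validation/test at the given
#' fractions, separately within each label class (largest-remainder
#' rounding per class), so heavily imbalanced tasks keep minority chemicals
#' in every partition where the arithmetic allows. Deterministic for a
#' fixed seed.
#'
#' @param task a \code{\link{TaskDataset-class}}.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed for the within-class shuffles.
#' @return the task with split tags assigned.
#' @export
stratifiedSplit <- function(task, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(is(task, "TaskDataset"))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  y <- task@y
  if (length(unique(y)) < 2L)
    stop("task '", task@taskName, "': only one class present, cannot split")
  if (length(y) < 10L)
    stop("task '", task@taskName, "': need at least 10 chemicals")
  tags <- character(length(y))
  rng <- localRNG(seed)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[rng$sampleIdx(length(idx))]
    cnt <- allocateCounts(length(idx), fractions)
    tags[idx] <- rep(c("train", "validation", "test"), times = cnt)
  }
  if (length(unique(y[tags == "train"])) < 2L)
    stop("task '", task@taskName, "': train split lost a class")
  initialize(task, split = tags)
}

# Private RNG that never disturbs the caller's .Random.seed.
localRNG <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  withState <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(
    sampleIdx = function(n) withState(function() sample.int(n)),
    draw = function(f) withState(f)
  )
}

mtryOf <- function(params, p) max(1L, floor(log2(p)))

rfFit <- function(X, y, params) {
  ranger::ranger(x = X, y = factor(y, levels = c(0L, 1L)),
                 num.trees = params@nTrees,
                 mtry = mtryOf(params, ncol(X)),
                 probability = TRUE, seed = params@seed,
                 num.threads = 1L)
}

rfProb <- function(forest, X) {
  stats::predict(forest, data = X, num.threads = 1L)$predictions[, "1"]
}

# Stacked input matrix for one task's forest at a given layer.
stackedInput <- function(X, S, ownCol, includeOwnScore) {
  if (is.null(S)) return(X)
  if (includeOwnScore) cbind(X, S) else cbind(X, S[, -ownCol, drop = FALSE])
}

#' Train one layer of per-task forests
#'
#' Trains one probability forest per task on that task's training split
#' only. Without \code{prevScores} the input is the raw fingerprint (layer
#' 1); with \code{prevScores} the input is the fingerprint concatenated
#' with all tasks' previous-layer scores (width \code{m + T}, or
#' \code{m + T - 1} when the task's own score is excluded).
#'
#' @param tasks list of split \code{\link{TaskDataset-class}} objects.
#' @param prevScores \code{NULL}, or a list (parallel to \code{tasks}) of
#'   per-task score matrices covering every chemical of each task, columns
#'   in task order.
#' @param params \code{\link{forestParams}}.
#' @param includeOwnScore keep the task's own previous-layer score among
#'   its stacked inputs.
#' @return a layer: list with \code{forests} (one per task),
#'   \code{inputWidths}, and \code{isFirst}.
#' @export
trainLayer <- function(tasks, prevScores = NULL, params = forestParams(),
                       includeOwnScore = TRUE) {
  tn <- vapply(tasks, taskName, character(1))
  if (!is.null(prevScores)) {
    for (t in seq_along(tasks)) {
      if (nrow(prevScores[[t]]) != nrow(tasks[[t]]@X))
        stop("previous-layer scores do not cover every chemical of task '",
             tn[t], "'")
    }
  }
  forests <- vector("list", length(tasks))
  widths <- integer(length(tasks))
  for (t in seq_along(tasks)) {
    tr <- tasks[[t]]@split == "train"
    Xt <- stackedInput(tasks[[t]]@X,
                       if (is.null(prevScores)) NULL else prevScores[[t]],
                       t, includeOwnScore)
    if (length(unique(tasks[[t]]@y[tr])) < 2L)
      stop("task '", tn[t], "': both classes required in the train split")
    forests[[t]] <- rfFit(Xt[tr, , drop = FALSE], tasks[[t]]@y[tr], params)
    widths[t] <- ncol(Xt)
  }
  names(forests) <- tn
  list(forests = forests, inputWidths = widths, isFirst = is.null(prevScores))
}

# Score every row of every task with every forest of one layer.
# Returns a list (per task) of n_t x T matrices, columns = task order.
scoreLayerAll <- function(layer, tasks, prevScores, includeOwnScore) {
  tn <- names(layer$forests)
  lapply(seq_along(tasks), function(d) {
    Xd <- tasks[[d]]@X
    Sd <- if (is.null(prevScores)) NULL else prevScores[[d]]
    out <- matrix(0, nrow(Xd), length(tn), dimnames = list(NULL, tn))
    for (t in seq_along(tn)) {
      inp <- stackedInput(Xd, Sd, t, includeOwnScore)
      out[, t] <- rfProb(layer$forests[[t]], inp)
    }
    colnames(out) <- paste0("S_", tn)
    out
  })
}

#' Apply one layer's forests to a feature matrix
#'
#' Scores arbitrary chemicals with every forest of a layer; any chemical
#' can be scored by any task's model. For stacked layers \code{X} must
#' already carry the previous layer's score columns.
#'
#' @param layer a layer from \code{\link{trainLayer}}.
#' @param X feature matrix of the width the layer was trained on (for
#'   layers beyond the first: fingerprint plus previous-layer scores; when
#'   the layer was trained without own-task scores, pass the full
#'   fingerprint+score matrix and the per-task own column is dropped
#'   internally).
#' @param includeOwnScore must match the setting the layer was trained
#'   with.
#' @return \code{\link{ScoreMatrix-class}}-style numeric matrix, chemicals
#'   by tasks.
#' @export
scoreAll <- function(layer, X, includeOwnScore = TRUE) {
  tn <- names(layer$forests)
  T_ <- length(tn)
  if (layer$isFirst || includeOwnScore) {
    expect <- layer$inputWidths[1]
    if (ncol(X) != expect)
      stop("feature width ", ncol(X), " does not match layer width ", expect)
    out <- vapply(seq_len(T_), function(t) rfProb(layer$forests[[t]], X),
                  numeric(nrow(X)))
  } else {
    m <- layer$inputWidths[1] - (T_ - 1L)
    if (ncol(X) != m + T_)
      stop("feature width ", ncol(X), " does not match expected ", m + T_)
    out <- vapply(seq_len(T_), function(t) {
      rfProb(layer$forests[[t]], X[, -(m + t), drop = FALSE])
    }, numeric(nrow(X)))
  }
  out <- matrix(out, nrow = nrow(X), ncol = T_,
                dimnames = list(rownames(X), paste0("S_", tn)))
  out
}

#' Fit a progressive multitask stacked-forest model
#'
#' Builds layer 1 from raw fingerprints (equivalent to independent
#' single-task forests); then, iteratively, scores every chemical of every
#' task with the current layer and trains the next layer on the fingerprint
#' concatenated with those scores. Each layer's per-task AUC on the
#' validation split is averaged (tasks whose validation split holds a
#' single class are excluded with a warning); layers are added until a new
#' layer fails to strictly improve the best mean validation AUC, or
#' \code{maxLayers} is reached. The selected layer is the argmax of mean
#' validation AUC; the first non-improving layer is retained for
#' inspection but never selected.
#'
#' @param tasks list of split \code{\link{TaskDataset-class}} objects with
#'   identical feature width.
#' @param params \code{\link{forestParams}}.
#' @param maxLayers cap on the number of layers built.
#' @param includeOwnScore keep each task's own previous-layer score among
#'   its stacked inputs (the default; excluding it is available for
#'   ablation).
#' @param verbose print one line of mean validation AUC per layer.
#' @return an \code{\link{MTForestNetModel-class}}.
#' @export
mtForestNet <- function(tasks, params = forestParams(), maxLayers = 10L,
                        includeOwnScore = TRUE, verbose = FALSE) {
  stopifnot(length(tasks) >= 1L, maxLayers >= 1L)
  tn <- unname(vapply(tasks, taskName, character(1)))
  if (anyDuplicated(tn)) stop("task names must be unique")
  names(tasks) <- tn
  m <- unique(vapply(tasks, function(t) ncol(t@X), integer(1)))
  if (length(m) != 1L) stop("all tasks must share one feature width")
  for (t in tasks)
    if (any(t@split == "unsplit"))
      stop("task '", t@taskName, "' is unsplit; run stratifiedSplit() first")

  layers <- list(); aucs <- list(); meanAUC <- numeric(0); cache <- list()
  prev <- NULL
  bestMean <- -Inf
  for (k in seq_len(maxLayers)) {
    layer <- trainLayer(tasks, prev, params, includeOwnScore)
    S <- scoreLayerAll(layer, tasks, prev, includeOwnScore)
    aucK <- vapply(seq_along(tasks), function(t) {
      v <- tasks[[t]]@split == "validation"
      yv <- tasks[[t]]@y[v]
      if (length(unique(yv)) < 2L) return(NA_real_)
      rocAUC(S[[t]][v, t], yv)
    }, numeric(1))
    names(aucK) <- tn
    if (anyNA(aucK))
      warning("layer ", k, ": validation AUC undefined for task(s) ",
              paste(tn[is.na(aucK)], collapse = ", "),
              " (single-class validation split); excluded from the mean")
    mAUC <- mean(aucK, na.rm = TRUE)
    layers[[k]] <- layer; aucs[[k]] <- aucK; meanAUC[k] <- mAUC
    cache[[k]] <- S
    if (verbose)
      message(sprintf("[mtfn] layer %d mean validation AUC %.4f", k, mAUC))
    if (mAUC > bestMean) {
      bestMean <- mAUC
      prev <- S
    } else {
      if (verbose) message(sprintf(
        "[mtfn] converged: layer %d did not improve on %.4f", k, bestMean))
      break
    }
  }
  new("MTForestNetModel", taskOrder = tn, layers = layers,
      perLayerValidationAUC = aucs, meanValidationAUC = meanAUC,
      bestLayer = as.integer(which.max(meanAUC)), params = params,
      featureLength = as.integer(m),
      includeOwnScore = includeOwnScore, scoreCache = cache)
}

#' Predict per-task probabilities for new chemicals
#'
#' Propagates the fingerprint matrix through the stacked layers: layer 1
#' scores the raw fingerprints, each subsequent layer scores the
#' fingerprints concatenated with the previous layer's score matrix, up to
#' the requested layer (the selected best layer by default).
#'
#' @param object a fitted \code{\link{MTForestNetModel-class}}.
#' @param X fingerprint matrix of width \code{featureLength}; may have 0
#'   rows.
#' @param layer layer to read scores from (default \code{bestLayer}).
#' @return \code{\link{ScoreMatrix-class}} of class-1 probabilities,
#'   columns in task order.
#' @export
setMethod("predict", "MTForestNetModel", function(object, X,
                                                  layer = bestLayer(object)) {
  X <- as.matrix(X)
  if (ncol(X) != object@featureLength)
    stop("feature width ", ncol(X), " does not match model fingerprint width ",
         object@featureLength)
  layer <- as.integer(layer)
  if (layer < 1L || layer > length(object@layers)) stop("layer out of range")
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("chem", seq_len(nrow(X)))
  if (nrow(X) == 0L)
    return(scoreMatrix(character(0),
                       matrix(0, 0, length(object@taskOrder),
                              dimnames = list(NULL, paste0("S_", object@taskOrder))),
                       layer))
  colnames(X) <- paste0("F", seq_len(ncol(X)))
  S <- scoreAll(object@layers[[1L]], X, object@includeOwnScore)
  if (layer >= 2L) for (k in 2:layer)
    S <- scoreAll(object@layers[[k]], cbind(X, S), object@includeOwnScore)
  scoreMatrix(ids, S, layer)
})

#' Binary toxicity calls from a fitted model
#'
#' @param model fitted \code{\link{MTForestNetModel-class}}.
#' @param X fingerprint matrix.
#' @param threshold probability cut-off for a positive call.
#' @param layer layer to read scores from.
#' @return integer 0/1 matrix, chemicals by tasks.
#' @export
predictCalls <- function(model, X, threshold = 0.5,
                         layer = bestLayer(model)) {
  sm <- predict(model, X, layer = layer)
  calls <- (scores(sm) >= threshold) + 0L
  rownames(calls) <- chemIds(sm)
  calls
}

#' Evaluate a fitted model on a held-out split
#'
#' Computes each task's AUC on its own chemicals carrying the requested
#' split tag, using the selected layer's scores. When the supplied tasks
#' are the ones the model was fitted on (matched by chemical ids), the
#' score cache recorded during fitting is reused; otherwise scores are
#' recomputed by forward propagation. Tasks whose split holds a single
#' class get \code{NA} with a warning and are excluded from the mean.
#'
#' @param model fitted \code{\link{MTForestNetModel-class}}.
#' @param tasks the task list to evaluate.
#' @param split \code{"validation"} or \code{"test"}.
#' @param layer layer to evaluate (default \code{bestLayer}).
#' @return list: \code{perTaskAUC}, \code{meanAUC}, \code{nAbove0.8}
#'   (count of tasks with AUC > 0.8), \code{undefinedTasks}.
#' @export
evaluateModel <- function(model, tasks, split = c("test", "validation"),
                          layer = bestLayer(model)) {
  split <- match.arg(split)
  tn <- unname(vapply(tasks, taskName, character(1)))
  if (!identical(tn, unname(model@taskOrder)))
    stop("task list does not match the model's task order")
  cached <- length(model@scoreCache) >= layer &&
    all(vapply(seq_along(tasks), function(t)
      nrow(model@scoreCache[[layer]][[t]]) == nrow(tasks[[t]]@X), logical(1)))
  aucv <- vapply(seq_along(tasks), function(t) {
    rows <- tasks[[t]]@split == split
    yv <- tasks[[t]]@y[rows]
    if (length(unique(yv)) < 2L) return(NA_real_)
    s <- if (cached) model@scoreCache[[layer]][[t]][rows, t] else
      scores(predict(model, tasks[[t]]@X[rows, , drop = FALSE],
                     layer = layer))[, t]
    rocAUC(s, yv)
  }, numeric(1))
  names(aucv) <- tn
  if (anyNA(aucv))
    warning("AUC undefined (single-class ", split, " split) for task(s): ",
            paste(tn[is.na(aucv)], collapse = ", "))
  list(perTaskAUC = aucv, meanAUC = mean(aucv, na.rm = TRUE),
       nAbove0.8 = sum(aucv > 0.8, na.rm = TRUE),
       undefinedTasks = tn[is.na(aucv)])
}

#' Refit the model with one dataset group excluded
#'
#' Drops every task assigned to the excluded group, refits the full stacked
#' model on the remaining tasks, and reports mean test AUC and the fraction
#' of tasks above AUC 0.8 — the single-dataset-exclusion ablation.
#'
#' @param tasks list of split \code{\link{TaskDataset-class}} objects.
#' @param groupAssignment named character vector task name -> group name.
#' @param excludedGroup group to leave out (a declared group with no tasks
#'   reproduces the full model).
#' @param knownGroups the declared group names; defaults to the groups
#'   appearing in \code{groupAssignment}.
#' @param params,maxLayers,includeOwnScore passed to
#'   \code{\link{mtForestNet}}.
#' @return list: \code{model}, \code{evaluation} (test split),
#'   \code{excludedTasks}, \code{fractionAbove0.8}.
#' @export
ablateDataset <- function(tasks, groupAssignment, excludedGroup,
                          params = forestParams(), maxLayers = 10L,
                          includeOwnScore = TRUE,
                          knownGroups = unique(groupAssignment)) {
  tn <- vapply(tasks, taskName, character(1))
  if (!all(tn %in% names(groupAssignment)))
    stop("groupAssignment must cover every task")
  if (!excludedGroup %in% knownGroups)
    stop("unknown group: ", excludedGroup)
  drop <- tn[groupAssignment[tn] == excludedGroup]
  keep <- tasks[!tn %in% drop]
  if (length(keep) == 0L) stop("excluding group '", excludedGroup,
                               "' leaves no tasks")
  model <- mtForestNet(keep, params = params, maxLayers = maxLayers,
                       includeOwnScore = includeOwnScore)
  ev <- evaluateModel(model, keep, "test")
  nDef <- sum(!is.na(ev$perTaskAUC))
  list(model = model, evaluation = ev, excludedTasks = drop,
       fractionAbove0.8 = if (nDef) ev$nAbove0.8 / nDef else NA_real_)
}
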