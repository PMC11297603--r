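# Downstream use of the multitask model: append its binary per-task calls
# (ZF features) to a fingerprint matrix, select task-relevant call columns
# by floating backward elimination, and benchmark with repeated stratified
# train/test splits.

#' Augment fingerprints with predicted per-task toxicity calls
#'
#' Thresholds the multitask model's class-1 probabilities at
#' \code{callThreshold} and appends one binary column per task to the base
#' fingerprint matrix (1024 + T columns for the default fingerprint and T
#' tasks), forming the design matrix used by downstream classifiers.
#'
#' @param model fitted \code{\link{MTForestNetModel-class}}.
#' @param xBase fingerprint matrix of width \code{featureLength}.
#' @param callThreshold probability cut-off for a positive call.
#' @param y optional downstream binary labels.
#' @return an \code{\link{AugmentedDataset-class}}.
#' @export
augmentZF <- function(model, xBase, callThreshold = 0.5, y = integer(0)) {
  xBase <- as.matrix(xBase)
  if (ncol(xBase) != model@featureLength)
    stop("feature width ", ncol(xBase), " does not match model width ",
         model@featureLength)
  calls <- predictCalls(model, xBase, threshold = callThreshold)
  colnames(calls) <- paste0("ZF_", model@taskOrder)
  ids <- rownames(xBase)
  if (is.null(ids)) ids <- paste0("chem", seq_len(nrow(xBase)))
  augmentedDataset(ids, xBase, calls, y)
}

# Stratified k-fold assignment; errors if any fold would lose a class.
stratifiedFolds <- function(y, k, seed) {
  rng <- localRNG(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[rng$sampleIdx(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  for (f in seq_len(k))
    if (length(unique(y[fold != f])) < 2L || length(unique(y[fold == f])) < 2L)
      stop("degenerate fold: fold ", f, " is single-class; ",
           "reduce kFolds or rebalance")
  fold
}

# Mean over folds of held-out AUC for one column subset, given fixed folds.
cvAUCForColumns <- function(X, y, cols, folds, params) {
  k <- max(folds)
  Xs <- X[, cols, drop = FALSE]
  mean(vapply(seq_len(k), function(f) {
    tr <- folds != f
    fit <- rfFit(Xs[tr, , drop = FALSE], y[tr], params)
    rocAUC(rfProb(fit, Xs[!tr, , drop = FALSE]), y[!tr])
  }, numeric(1)))
}

#' Sequential backward feature selection with conditional inclusion
#'
#' Floating backward search over the candidate columns with the fixed
#' columns always retained: starting from the full candidate set, the
#' candidate whose removal gives the highest k-fold cross-validated AUC is
#' removed; after each removal, previously removed candidates are re-added
#' (one at a time) whenever re-adding strictly improves the current CV AUC
#' and does not revisit a subset already scored. The search stops after
#' \code{patience} consecutive removal rounds that fail to improve the
#' best CV AUC seen, or when the candidates are exhausted, and returns the
#' best subset encountered (ties broken toward the smaller set, then
#' lexicographically). Fold assignment is fixed once per call, so all
#' subsets are scored on identical folds; subset evaluations are memoized.
#'
#' @param X design matrix.
#' @param y 0/1 labels.
#' @param candidateColumns column names or indices searched over.
#' @param fixedColumns column names or indices always retained (may be
#'   empty).
#' @param kFolds folds for the CV criterion.
#' @param seed seed for the fold assignment.
#' @param params \code{\link{forestParams}} used for every subset fit.
#' @param patience consecutive non-improving removal rounds tolerated
#'   before the search stops.
#' @return list: \code{selected} (candidate columns of the best subset,
#'   original order), \code{cvAUC}, \code{fullSetCvAUC}, \code{trace}
#'   (data.frame of scored subsets).
#' @export
sbfsConditional <- function(X, y, candidateColumns, fixedColumns = integer(0),
                            kFolds = 10L, seed = 1L,
                            params = forestParams(), patience = 2L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  asNames <- function(cols) if (is.character(cols)) cols else colnames(X)[cols]
  cand <- asNames(candidateColumns)
  fixed <- asNames(fixedColumns)
  if (length(cand) == 0L) stop("candidateColumns must be non-empty")
  y <- as.integer(y)
  folds <- stratifiedFolds(y, kFolds, seed)

  memo <- new.env(parent = emptyenv())
  evals <- 0L
  scoreOf <- function(set) {
    key <- paste(sort(set), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- cvAUCForColumns(X, y, c(fixed, set), folds, params)
    memo[[key]] <- s
    evals <<- evals + 1L
    s
  }
  cur <- cand
  curS <- scoreOf(cur)
  bestSet <- cur; bestS <- curS
  fullS <- curS
  # a tie only displaces the incumbent if the set is smaller, then
  # lexicographically first; the best *score* drives the patience counter
  updateBest <- function(set, s) {
    if (s > bestS) { bestSet <<- set; bestS <<- s; return(invisible()) }
    if (s < bestS) return(invisible())
    a <- paste(sort(set), collapse = "|")
    b <- paste(sort(bestSet), collapse = "|")
    if (length(set) < length(bestSet) ||
        (length(set) == length(bestSet) && a < b)) bestSet <<- set
    invisible()
  }
  stale <- 0L
  trace <- list(data.frame(size = length(cur), cvAUC = curS,
                           action = "start", stringsAsFactors = FALSE))
  while (length(cur) > 1L && stale < patience) {
    bestBefore <- bestS
    # backward step: best single removal
    remS <- vapply(cur, function(r) scoreOf(setdiff(cur, r)), numeric(1))
    drop <- cur[which.max(remS)]
    cur <- setdiff(cur, drop)
    curS <- max(remS)
    trace[[length(trace) + 1L]] <- data.frame(size = length(cur), cvAUC = curS,
                                              action = paste0("-", drop),
                                              stringsAsFactors = FALSE)
    updateBest(cur, curS)
    # conditional inclusion: re-add while strictly improving the current set
    repeat {
      out <- setdiff(cand, cur)
      if (length(out) == 0L) break
      addS <- vapply(out, function(a) scoreOf(c(cur, a)), numeric(1))
      if (max(addS) <= curS) break
      add <- out[which.max(addS)]
      cur <- cand[cand %in% c(cur, add)]   # keep original candidate order
      curS <- max(addS)
      trace[[length(trace) + 1L]] <- data.frame(size = length(cur),
                                                cvAUC = curS,
                                                action = paste0("+", add),
                                                stringsAsFactors = FALSE)
      updateBest(cur, curS)
    }
    stale <- if (bestS > bestBefore) 0L else stale + 1L
  }
  list(selected = cand[cand %in% bestSet], cvAUC = bestS,
       fullSetCvAUC = fullS, trace = do.call(rbind, trace),
       nEvaluations = evals)
}

runSeedOf <- function(masterSeed, run) {
  as.integer((as.numeric(masterSeed) * 1009 + run) %% 2147483647)
}

#' Repeated stratified train/test evaluation of a downstream classifier
#'
#' For each run: a stratified split into (1 - \code{testFraction}) training
#' and \code{testFraction} test chemicals; optionally the predicted-call
#' (ZF) columns are appended to the fingerprint; optionally the ZF columns
#' are filtered by \code{\link{sbfsConditional}} using the training rows
#' only; a random forest with the package's default parameters is trained
#' on the training rows and scored by AUC on the held-out rows. Per-run
#' seeds derive from the master seed by the fixed affine scheme
#' \code{(seed * 1009 + run) mod (2^31 - 1)}, so runs are independent but
#' the whole experiment is reproducible.
#'
#' @param dataset labeled \code{\link{AugmentedDataset-class}}.
#' @param runs number of repeated splits.
#' @param testFraction held-out fraction per run.
#' @param useZF append the ZF call columns.
#' @param useSelection run SBFS over the ZF columns (training rows only).
#' @param seed master seed.
#' @param params \code{\link{forestParams}} for the per-run forests (and
#'   SBFS subset fits).
#' @param kFolds,patience passed to \code{\link{sbfsConditional}}.
#' @return list: \code{meanAUC}, \code{varAUC}, \code{perRunAUC},
#'   \code{selectionFrequency} (per ZF column, in [0, 1]; \code{NULL}
#'   unless selection ran).
#' @export
repeatedEvaluation <- function(dataset, runs = 100L, testFraction = 0.2,
                               useZF = TRUE, useSelection = FALSE,
                               seed = 1L, params = forestParams(),
                               kFolds = 10L, patience = 2L) {
  stopifnot(is(dataset, "AugmentedDataset"))
  y <- dataset@y
  if (length(y) == 0L) stop("dataset carries no labels")
  if (length(unique(y)) < 2L) stop("both classes required")
  zfNames <- colnames(dataset@xZF)
  baseNames <- colnames(dataset@xBase)
  Xall <- cbind(dataset@xBase, dataset@xZF)
  perRun <- numeric(runs)
  selCount <- stats::setNames(numeric(length(zfNames)), zfNames)
  selRan <- FALSE
  for (r in seq_len(runs)) {
    rs <- runSeedOf(seed, r)
    rng <- localRNG(rs)
    tag <- character(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[rng$sampleIdx(length(idx))]
      nTest <- max(1L, round(testFraction * length(idx)))
      tag[idx] <- rep(c("test", "train"),
                      c(nTest, length(idx) - nTest))
    }
    tr <- tag == "train"
    cols <- baseNames
    if (useZF) {
      zf <- zfNames
      if (useSelection) {
        sel <- sbfsConditional(Xall[tr, , drop = FALSE], y[tr],
                               candidateColumns = zfNames,
                               fixedColumns = baseNames,
                               kFolds = kFolds, seed = rs, params = params,
                               patience = patience)
        zf <- sel$selected
        selCount[zf] <- selCount[zf] + 1
        selRan <- TRUE
      }
      cols <- c(baseNames, zf)
    }
    fit <- rfFit(Xall[tr, cols, drop = FALSE], y[tr], params)
    perRun[r] <- rocAUC(rfProb(fit, Xall[!tr, cols, drop = FALSE]), y[!tr])
  }
  list(meanAUC = mean(perRun), varAUC = stats::var(perRun),
       perRunAUC = perRun,
       selectionFrequency = if (selRan) selCount / runs else NULL)
}
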