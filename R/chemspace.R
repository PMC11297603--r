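# Chemical-space diagnostics: how related are two datasets (shared
# chemicals, structural similarity), how correlated are task labels, and
# where do the chemicals fall in fingerprint principal-component space.

#' Tanimoto similarity of two binary fingerprints
#'
#' \code{|A intersect B| / |A union B|} over set bits. Defined as 0 when
#' both fingerprints are all-zero.
#'
#' @param fpA,fpB binary vectors of equal length.
#' @return similarity in [0, 1].
#' @export
#' @examples
#' tanimoto(c(0, 1, 1, 1, 0), c(0, 0, 1, 1, 1))  # 2/4
tanimoto <- function(fpA, fpB) {
  if (length(fpA) != length(fpB))
    stop("fingerprint length mismatch: ", length(fpA), " vs ", length(fpB))
  a <- as.logical(fpA); b <- as.logical(fpB)
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

# All pairwise Tanimoto similarities between rows of two binary matrices,
# via bit-count algebra: |A&B| = X Y', |A|B| = rowsum + colsum - X Y'.
crossTanimoto <- function(X, Y) {
  X <- matrix(as.numeric(X != 0), nrow = nrow(X))
  Y <- matrix(as.numeric(Y != 0), nrow = nrow(Y))
  inter <- X %*% t(Y)
  uni <- outer(rowSums(X), rowSums(Y), `+`) - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  out
}

#' Highest percentage of common chemicals between two dataset groups
#'
#' For every pair of subsets (one from each group) computes
#' \code{100 * |shared ids| / |union of ids|}; the highest value over all
#' subset pairs is returned, summarizing how strongly the two datasets'
#' chemical collections overlap.
#'
#' @param A,B \code{\link{DatasetGroup-class}} objects.
#' @return percentage in [0, 100].
#' @export
commonChemicalPercentage <- function(A, B) {
  stopifnot(is(A, "DatasetGroup"), is(B, "DatasetGroup"))
  best <- 0
  for (sa in A@subsets) for (sb in B@subsets) {
    u <- length(union(sa$ids, sb$ids))
    v <- if (u == 0L) 0 else 100 * length(intersect(sa$ids, sb$ids)) / u
    if (v > best) best <- v
  }
  best
}

#' Average Tanimoto similarity between two dataset groups
#'
#' For each of the n x m subset pairs, the mean Tanimoto similarity over all
#' cross pairs (one chemical from each subset) is computed; the unweighted
#' mean of these subset-pair means, times 100, is returned. Chemicals
#' present in both subsets contribute their self-similarity of 1, so
#' heavily overlapping datasets score near 100.
#'
#' @param A,B \code{\link{DatasetGroup-class}} objects whose subsets carry
#'   fingerprints.
#' @param pooled if \code{TRUE}, average over all cross pairs pooled
#'   together instead of averaging subset-pair means.
#' @return percentage in [0, 100].
#' @export
averageSimilarity <- function(A, B, pooled = FALSE) {
  stopifnot(is(A, "DatasetGroup"), is(B, "DatasetGroup"))
  means <- c(); weights <- c()
  for (sa in A@subsets) for (sb in B@subsets) {
    if (is.null(sa$fingerprints) || is.null(sb$fingerprints))
      stop("missing fingerprints in subset of group '",
           if (is.null(sa$fingerprints)) A@name else B@name, "'")
    sim <- crossTanimoto(sa$fingerprints, sb$fingerprints)
    means <- c(means, mean(sim))
    weights <- c(weights, length(sim))
  }
  if (pooled) 100 * sum(means * weights) / sum(weights) else 100 * mean(means)
}

#' Summarize inter-task label correlations into strength bins
#'
#' For every unordered pair of tasks, the Pearson correlation of their
#' binary labels over chemicals labeled in both tasks is computed and its
#' absolute value binned: low (|r| < 0.3), medium (0.3 <= |r| < 0.5), high
#' (0.5 <= |r| < 0.7), very high (0.7 <= |r|). Pairs sharing fewer than
#' \code{minShared} chemicals, or with zero label variance in either task
#' on the shared chemicals, are counted as uncategorized.
#'
#' @param taskLabelList named list; each element a named 0/1 vector
#'   (chemical id -> label) for one task.
#' @param minShared minimum shared labeled chemicals for a pair to be
#'   categorized (>= 3; two points always give |r| = 1).
#' @return list with \code{counts} (named integer vector over the four
#'   bins), \code{uncategorized}, \code{minShared} and \code{pairs} (a
#'   data.frame of per-pair r values, \code{NA} when uncategorized).
#' @export
taskCorrelationSummary <- function(taskLabelList, minShared = 3L) {
  if (minShared < 3L) stop("minShared must be >= 3")
  tn <- names(taskLabelList)
  if (is.null(tn)) stop("taskLabelList must be named")
  bins <- c(low = 0L, medium = 0L, high = 0L, very_high = 0L)
  unc <- 0L
  rows <- list()
  if (length(tn) >= 2L) {
    for (i in seq_len(length(tn) - 1L)) for (j in seq(i + 1L, length(tn))) {
      a <- taskLabelList[[i]]; b <- taskLabelList[[j]]
      shared <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
      r <- NA_real_
      if (length(shared) >= minShared) {
        x <- as.numeric(a[shared]); y <- as.numeric(b[shared])
        if (stats::var(x) > 0 && stats::var(y) > 0)
          r <- stats::cor(x, y)
      }
      if (is.na(r)) {
        unc <- unc + 1L
      } else {
        ar <- abs(r)
        bin <- if (ar < 0.3) "low" else if (ar < 0.5) "medium" else
          if (ar < 0.7) "high" else "very_high"
        bins[bin] <- bins[bin] + 1L
      }
      rows[[length(rows) + 1L]] <-
        data.frame(task_a = tn[i], task_b = tn[j],
                   n_shared = length(shared), r = r,
                   stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(task_a = character(0), task_b = character(0),
               n_shared = integer(0), r = numeric(0))
  list(counts = bins, uncategorized = unc, minShared = as.integer(minShared),
       pairs = pairs)
}

#' Project fingerprints onto principal components
#'
#' Mean-centered PCA (no scaling) of a binary fingerprint matrix, the
#' standard view for comparing chemical spaces. Explained-variance
#' fractions are reported over all components, so they sum to 1.
#'
#' @param fingerprints numeric matrix, chemicals by bits.
#' @param nComponents number of leading components to return.
#' @return list with \code{coordinates} (chemicals x \code{nComponents}),
#'   \code{explainedVariance} (fractions for the returned components) and
#'   \code{allExplainedVariance} (fractions for every component).
#' @export
pcaProjection <- function(fingerprints, nComponents = 2L) {
  fingerprints <- as.matrix(fingerprints)
  if (nrow(fingerprints) < nComponents + 1L)
    stop("need at least ", nComponents + 1L, " fingerprints for ",
         nComponents, " components")
  p <- stats::prcomp(fingerprints, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  frac <- ev / sum(ev)
  k <- min(nComponents, ncol(p$x))
  list(coordinates = p$x[, seq_len(k), drop = FALSE],
       explainedVariance = frac[seq_len(k)],
       allExplainedVariance = frac)
}

#' Pairwise chemical-space report for several dataset groups
#'
#' Convenience wrapper computing the full pairwise matrices of
#' \code{\link{commonChemicalPercentage}} and
#' \code{\link{averageSimilarity}} for a list of groups.
#'
#' @param groups list of \code{\link{DatasetGroup-class}} objects.
#' @return list of two named matrices, \code{commonPercent} and
#'   \code{averageSimilarity}.
#' @export
chemspaceReport <- function(groups) {
  nm <- vapply(groups, function(g) g@name, character(1))
  k <- length(groups)
  cp <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  as_ <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    cp[i, j] <- commonChemicalPercentage(groups[[i]], groups[[j]])
    as_[i, j] <- averageSimilarity(groups[[i]], groups[[j]])
  }
  list(commonPercent = cp, averageSimilarity = as_)
}
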