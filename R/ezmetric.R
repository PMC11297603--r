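# EZ Metric: weighted-sum overall-toxicity score over binary endpoint
# calls at 24 and 120 hours post fertilization, plus the comparison of
# predicted against experimental scores.

#' EZ Metric overall-toxicity score
#'
#' The weighted sum of binary endpoint calls under nonnegative endpoint
#' weights: \code{sum(w_e * call_e)} over non-missing endpoints. Endpoints
#' without data are skipped by default (an endpoint not measured simply
#' contributes nothing); \code{missingPolicy = "error"} makes missing calls
#' fatal instead.
#'
#' @param calls named numeric vector of 0/1/\code{NA} endpoint calls for
#'   one chemical, or a chemicals-by-endpoints matrix (rownames chemical
#'   ids) for many.
#' @param weights an \code{\link{ezWeights}} object covering every called
#'   endpoint.
#' @param missingPolicy \code{"skip"} or \code{"error"}.
#' @return a single score, or a named vector of scores for matrix input.
#' @export
#' @examples
#' w <- ezWeights(c(a = 2, b = 1, c = 0.5))
#' ezScore(c(a = 1, b = 0, c = NA), w)  # 2
ezScore <- function(calls, weights, missingPolicy = c("skip", "error")) {
  missingPolicy <- match.arg(missingPolicy)
  stopifnot(is(weights, "EZWeights"))
  if (is.matrix(calls)) {
    out <- apply(calls, 1L, ezScore, weights = weights,
                 missingPolicy = missingPolicy)
    return(out)
  }
  en <- names(calls)
  if (is.null(en)) stop("calls must be named by endpoint")
  unknown <- setdiff(en, names(weights@weights))
  if (length(unknown))
    stop("unknown endpoint(s): ", paste(unknown, collapse = ", "))
  if (anyNA(calls) && missingPolicy == "error")
    stop("missing call(s) for endpoint(s): ",
         paste(en[is.na(calls)], collapse = ", "))
  ok <- !is.na(calls)
  if (!all(calls[ok] %in% c(0, 1))) stop("calls must be 0, 1 or NA")
  sum(weights@weights[en[ok]] * calls[ok])
}

#' Pearson correlation with validity checks
#'
#' Sample Pearson correlation for vectors of length at least 3 with
#' nonzero variance on both sides (the correlation is undefined
#' otherwise).
#'
#' @param x,y numeric vectors of equal length.
#' @return correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y)
}

#' Compare predicted and experimental EZ Metric scores
#'
#' Scores each chemical from both its predicted and its experimental
#' endpoint calls and summarizes the agreement: the Pearson correlation of
#' the two score vectors and the bias \code{mean(predicted -
#' experimental)}, whose sign reports whether the predictions over- or
#' under-call overall toxicity.
#'
#' @param predictedCalls,experimentalCalls chemicals-by-endpoints matrices
#'   of 0/1/\code{NA} calls with chemical ids as rownames; the two chemical
#'   sets must coincide.
#' @param weights an \code{\link{ezWeights}} object.
#' @param missingPolicy passed to \code{\link{ezScore}}.
#' @return list: \code{scorePairs} (data.frame chem_id, predicted,
#'   experimental), \code{pearsonR}, \code{bias}.
#' @export
compareEZ <- function(predictedCalls, experimentalCalls, weights,
                      missingPolicy = "skip") {
  idP <- rownames(predictedCalls); idE <- rownames(experimentalCalls)
  if (is.null(idP) || is.null(idE))
    stop("call matrices must carry chemical ids as rownames")
  extra <- c(setdiff(idP, idE), setdiff(idE, idP))
  if (length(extra))
    stop("chemical sets differ; unmatched: ",
         paste(utils::head(extra, 10L), collapse = ", "))
  experimentalCalls <- experimentalCalls[idP, , drop = FALSE]
  p <- ezScore(predictedCalls, weights, missingPolicy)
  e <- ezScore(experimentalCalls, weights, missingPolicy)
  list(scorePairs = data.frame(chem_id = idP, predicted = unname(p),
                               experimental = unname(e),
                               stringsAsFactors = FALSE),
       pearsonR = pearson(p, e),
       bias = mean(p - e))
}

#' Read EZ Metric weights from a YAML file
#'
#' Expected layout: a top-level \code{endpoints} map of
#' \code{name: \{weight: w, group: 24hpf|120hpf\}} entries, or a flat
#' \code{name: weight} map (all tagged 120hpf).
#'
#' @param path YAML file.
#' @return an \code{\link{ezWeights}} object.
#' @export
readEZWeights <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$endpoints)) cfg <- cfg$endpoints
  if (is.list(cfg[[1]])) {
    w <- vapply(cfg, function(e) as.numeric(e$weight), numeric(1))
    g <- vapply(cfg, function(e)
      if (is.null(e$group)) "120hpf" else as.character(e$group), character(1))
    ezWeights(stats::setNames(w, names(cfg)), stats::setNames(g, names(cfg)))
  } else {
    ezWeights(stats::setNames(vapply(cfg, as.numeric, numeric(1)), names(cfg)))
  }
}
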