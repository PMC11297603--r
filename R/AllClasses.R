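#' @import methods
NULL

#' Random-forest hyperparameters for all layers
#'
#' Holds the forest configuration used by every classifier in a stacked
#' multitask model: number of trees, the rule mapping feature count to
#' \code{mtry}, and the forest seed. The defaults (500 trees,
#' \code{floor(log2(p))} candidate features per split, seed 8) are the
#' configuration used throughout the package; \code{mtry} is always taken
#' from the width of the training matrix actually in use, so stacked layers
#' with appended score columns get a slightly larger \code{mtry} than the
#' first layer.
#'
#' @slot nTrees number of trees per forest.
#' @slot mtryRule rule for candidate features per split; only
#'   \code{"log2"} (\code{floor(log2(p))}) is supported.
#' @slot seed integer seed passed to the forest learner.
#' @exportClass ForestParams
setClass("ForestParams",
  representation(nTrees = "integer", mtryRule = "character", seed = "integer"),
  prototype(nTrees = 500L, mtryRule = "log2", seed = 8L)
)

setValidity("ForestParams", function(object) {
  if (length(object@nTrees) != 1L || object@nTrees < 1L)
    return("nTrees must be a single positive integer")
  if (!identical(object@mtryRule, "log2"))
    return("mtryRule must be 'log2'")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' @describeIn ForestParams-class Constructor.
#' @param nTrees,mtryRule,seed see slots.
#' @return A \code{ForestParams} object.
#' @export
#' @examples
#' forestParams()
#' forestParams(nTrees = 50, seed = 1)
forestParams <- function(nTrees = 500L, mtryRule = "log2", seed = 8L) {
  new("ForestParams", nTrees = as.integer(nTrees), mtryRule = mtryRule,
      seed = as.integer(seed))
}

#' One binary classification task over a fingerprint matrix
#'
#' A named learning task: an ordered set of chemicals, their binary feature
#' matrix, binary labels, and a per-chemical split tag. Freshly generated or
#' imported tasks carry the tag \code{"unsplit"}; \code{\link{stratifiedSplit}}
#' assigns \code{train}/\code{validation}/\code{test}.
#'
#' @slot taskName task identifier (unique within a task list).
#' @slot chemIds chemical identifiers, one per row of \code{X}.
#' @slot X numeric matrix, chemicals by features, entries in \{0,1\}.
#' @slot y integer vector of labels in \{0,1\}.
#' @slot split character vector in
#'   \{\code{train}, \code{validation}, \code{test}, \code{unsplit}\}.
#' @slot group dataset-group name the task belongs to (may be \code{NA}).
#' @exportClass TaskDataset
setClass("TaskDataset",
  representation(taskName = "character", chemIds = "character",
                 X = "matrix", y = "integer", split = "character",
                 group = "character")
)

setValidity("TaskDataset", function(object) {
  n <- nrow(object@X)
  if (length(object@chemIds) != n) return("chemIds length must match nrow(X)")
  if (anyDuplicated(object@chemIds)) return("chemIds must be unique")
  if (length(object@y) != n) return("y length must match nrow(X)")
  if (length(object@split) != n) return("split length must match nrow(X)")
  if (!all(object@y %in% c(0L, 1L))) return("y must be 0/1")
  ok <- c("train", "validation", "test", "unsplit")
  if (!all(object@split %in% ok))
    return("split tags must be train/validation/test/unsplit")
  TRUE
})

#' @describeIn TaskDataset-class Constructor.
#' @param taskName,chemIds,X,y,split,group see slots.
#' @return A \code{TaskDataset}.
#' @export
taskDataset <- function(taskName, chemIds, X, y,
                        split = rep("unsplit", nrow(X)), group = NA_character_) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  new("TaskDataset", taskName = as.character(taskName),
      chemIds = as.character(chemIds), X = X, y = as.integer(y),
      split = as.character(split), group = as.character(group))
}

#' Per-layer class-probability scores for a set of chemicals
#'
#' The chemicals-by-tasks matrix of class-1 probabilities emitted by one
#' layer of a stacked multitask model. Column order is the model's fixed
#' task order.
#'
#' @slot chemIds chemical identifiers, one per row.
#' @slot scores numeric matrix in [0,1], chemicals by tasks.
#' @slot layerIndex which layer produced the scores.
#' @exportClass ScoreMatrix
setClass("ScoreMatrix",
  representation(chemIds = "character", scores = "matrix",
                 layerIndex = "integer")
)

setValidity("ScoreMatrix", function(object) {
  if (nrow(object@scores) != length(object@chemIds))
    return("chemIds length must match nrow(scores)")
  s <- object@scores
  if (length(s) && (min(s) < 0 || max(s) > 1))
    return("scores must lie in [0,1]")
  TRUE
})

scoreMatrix <- function(chemIds, scores, layerIndex) {
  new("ScoreMatrix", chemIds = as.character(chemIds),
      scores = as.matrix(scores), layerIndex = as.integer(layerIndex))
}

#' A trained progressive multitask stacked-forest model
#'
#' An ordered list of layers (each layer one probability forest per task),
#' the per-layer validation AUCs used for layer selection, and the index of
#' the selected best layer. Layer 1 forests see the raw fingerprint
#' (\code{featureLength} columns); deeper layers see the fingerprint
#' concatenated with all tasks' previous-layer scores.
#'
#' @slot taskOrder fixed task order defining score-column order.
#' @slot layers list of layers; each layer is a named list of forests.
#' @slot perLayerValidationAUC list of per-task validation AUC vectors.
#' @slot meanValidationAUC mean validation AUC per layer.
#' @slot bestLayer index of the layer with the highest mean validation AUC.
#' @slot params the \code{\link{ForestParams-class}} used.
#' @slot featureLength width of the raw fingerprint.
#' @slot includeOwnScore whether a task's own previous-layer score is part
#'   of its stacked input.
#' @slot scoreCache per-layer, per-task score matrices for the chemicals the
#'   model was fitted on (used by \code{\link{evaluateModel}}).
#' @exportClass MTForestNetModel
setClass("MTForestNetModel",
  representation(taskOrder = "character", layers = "list",
                 perLayerValidationAUC = "list",
                 meanValidationAUC = "numeric", bestLayer = "integer",
                 params = "ForestParams", featureLength = "integer",
                 includeOwnScore = "logical", scoreCache = "list")
)

setValidity("MTForestNetModel", function(object) {
  k <- length(object@layers)
  if (k < 1L) return("model must have at least one layer")
  if (object@bestLayer < 1L || object@bestLayer > k)
    return("bestLayer out of range")
  if (length(object@meanValidationAUC) != k)
    return("one mean validation AUC per layer required")
  if (object@meanValidationAUC[object@bestLayer] <
      object@meanValidationAUC[1L] - 1e-12)
    return("bestLayer cannot be worse than layer 1")
  TRUE
})

#' Endpoint weights for the EZ Metric overall-toxicity score
#'
#' Nonnegative weights over named toxicity endpoints, each tagged with its
#' developmental timepoint group (24 or 120 hours post fertilization). The
#' EZ Metric is the weighted sum of binary endpoint calls under these
#' weights; weight values are supplied by the user (e.g. from a YAML file),
#' not fixed by the package.
#'
#' @slot weights named nonnegative numeric vector, one entry per endpoint.
#' @slot group named character vector over the same endpoints, values in
#'   \{\code{"24hpf"}, \code{"120hpf"}\}.
#' @exportClass EZWeights
setClass("EZWeights",
  representation(weights = "numeric", group = "character")
)

setValidity("EZWeights", function(object) {
  w <- object@weights
  if (is.null(names(w)) || any(!nzchar(names(w))))
    return("weights must be named by endpoint")
  if (anyDuplicated(names(w))) return("endpoint names must be unique")
  if (any(w < 0)) return("weights must be nonnegative")
  if (!identical(sort(names(w)), sort(names(object@group))))
    return("group must tag exactly the weighted endpoints")
  if (!all(object@group %in% c("24hpf", "120hpf")))
    return("group values must be '24hpf' or '120hpf'")
  TRUE
})

#' @describeIn EZWeights-class Constructor.
#' @param weights named nonnegative numeric vector.
#' @param group named character vector of timepoint tags
#'   (\code{"24hpf"}/\code{"120hpf"}); defaults to \code{"120hpf"} for all.
#' @return An \code{EZWeights} object.
#' @export
#' @examples
#' ezWeights(c(MORT = 2, AXIS = 1), c(MORT = "24hpf", AXIS = "120hpf"))
ezWeights <- function(weights, group = NULL) {
  if (is.null(group)) {
    group <- rep("120hpf", length(weights))
    names(group) <- names(weights)
  }
  new("EZWeights",
      weights = stats::setNames(as.numeric(weights), names(weights)),
      group = group[names(weights)])
}

#' A named group of chemical subsets with fingerprints
#'
#' Represents one dataset as an ordered list of named subsets; each subset
#' is a set of chemical identifiers with a fingerprint per member. Pairwise
#' dataset comparisons (common-chemical percentage, average Tanimoto
#' similarity) iterate over the cross product of the two groups' subsets.
#'
#' @slot name group name.
#' @slot subsets named list; each element a list with \code{ids}
#'   (unique character vector) and \code{fingerprints} (binary matrix with
#'   rownames \code{ids}).
#' @exportClass DatasetGroup
setClass("DatasetGroup",
  representation(name = "character", subsets = "list")
)

setValidity("DatasetGroup", function(object) {
  if (length(object@subsets) == 0L) return("group must have >= 1 subset")
  for (nm in names(object@subsets)) {
    s <- object@subsets[[nm]]
    if (length(s$ids) == 0L) return(sprintf("subset '%s' is empty", nm))
    if (anyDuplicated(s$ids))
      return(sprintf("subset '%s' has duplicate chemical ids", nm))
    if (!is.null(s$fingerprints)) {
      if (nrow(s$fingerprints) != length(s$ids))
        return(sprintf("subset '%s': fingerprint rows != ids", nm))
    }
  }
  TRUE
})

#' @describeIn DatasetGroup-class Constructor.
#' @param name group name.
#' @param subsets named list of \code{list(ids=, fingerprints=)} elements;
#'   \code{fingerprints} may be omitted for id-only comparisons.
#' @return A \code{DatasetGroup}.
#' @export
datasetGroup <- function(name, subsets) {
  if (is.null(names(subsets)))
    names(subsets) <- paste0("subset", seq_along(subsets))
  subsets <- lapply(subsets, function(s) {
    if (is.null(s$ids)) stop("each subset needs an 'ids' field")
    s$ids <- as.character(s$ids)
    if (!is.null(s$fingerprints)) {
      s$fingerprints <- as.matrix(s$fingerprints)
      rownames(s$fingerprints) <- s$ids
    }
    s
  })
  new("DatasetGroup", name = as.character(name), subsets = subsets)
}

#' Fingerprint matrix augmented with predicted toxicity calls
#'
#' Pairs a chemicals-by-fingerprint base matrix with the binary toxicity
#' calls predicted by a multitask model (one column per task), optionally
#' with labels for a downstream endpoint. The combined design matrix has
#' width \code{ncol(xBase) + ncol(xZF)}.
#'
#' @slot chemIds chemical identifiers.
#' @slot xBase base fingerprint matrix.
#' @slot xZF binary matrix of per-task predicted calls.
#' @slot y downstream binary labels (may be length 0 when unlabeled).
#' @exportClass AugmentedDataset
setClass("AugmentedDataset",
  representation(chemIds = "character", xBase = "matrix", xZF = "matrix",
                 y = "integer")
)

setValidity("AugmentedDataset", function(object) {
  if (nrow(object@xBase) != length(object@chemIds))
    return("xBase rows must match chemIds")
  if (nrow(object@xZF) != length(object@chemIds))
    return("xZF rows must match chemIds")
  if (length(object@xZF) && !all(object@xZF %in% c(0, 1)))
    return("xZF entries must be 0/1")
  if (length(object@y) && length(object@y) != length(object@chemIds))
    return("y must be empty or match chemIds")
  TRUE
})

#' @describeIn AugmentedDataset-class Constructor.
#' @param chemIds,xBase,xZF,y see slots.
#' @return An \code{AugmentedDataset}.
#' @export
augmentedDataset <- function(chemIds, xBase, xZF, y = integer(0)) {
  new("AugmentedDataset", chemIds = as.character(chemIds),
      xBase = as.matrix(xBase), xZF = as.matrix(xZF), y = as.integer(y))
}
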