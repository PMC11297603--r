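#' @rdname TaskDataset-class
#' @param object,x a package object.
#' @export
setGeneric("taskName", function(x) standardGeneric("taskName"))
#' @rdname TaskDataset-class
#' @export
setGeneric("chemIds", function(x) standardGeneric("chemIds"))
#' @rdname TaskDataset-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname TaskDataset-class
#' @export
setGeneric("taskLabels", function(x) standardGeneric("taskLabels"))
#' @rdname TaskDataset-class
#' @export
setGeneric("splitTags", function(x) standardGeneric("splitTags"))
#' @rdname ScoreMatrix-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname ScoreMatrix-class
#' @export
setGeneric("layerIndex", function(x) standardGeneric("layerIndex"))
#' @rdname MTForestNetModel-class
#' @export
setGeneric("taskOrder", function(x) standardGeneric("taskOrder"))
#' @rdname MTForestNetModel-class
#' @export
setGeneric("bestLayer", function(x) standardGeneric("bestLayer"))
#' @rdname MTForestNetModel-class
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname MTForestNetModel-class
#' @export
setGeneric("validationAUC", function(x) standardGeneric("validationAUC"))
#' @rdname MTForestNetModel-class
#' @export
setGeneric("forestParamsOf", function(x) standardGeneric("forestParamsOf"))

setMethod("taskName", "TaskDataset", function(x) x@taskName)
setMethod("chemIds", "TaskDataset", function(x) x@chemIds)
setMethod("features", "TaskDataset", function(x) x@X)
setMethod("taskLabels", "TaskDataset", function(x) x@y)
setMethod("splitTags", "TaskDataset", function(x) x@split)
setMethod("chemIds", "ScoreMatrix", function(x) x@chemIds)
setMethod("scores", "ScoreMatrix", function(x) x@scores)
setMethod("layerIndex", "ScoreMatrix", function(x) x@layerIndex)
setMethod("taskOrder", "MTForestNetModel", function(x) x@taskOrder)
setMethod("bestLayer", "MTForestNetModel", function(x) x@bestLayer)
setMethod("nLayers", "MTForestNetModel", function(x) length(x@layers))
setMethod("validationAUC", "MTForestNetModel",
          function(x) x@perLayerValidationAUC)
setMethod("forestParamsOf", "MTForestNetModel", function(x) x@params)
setMethod("chemIds", "AugmentedDataset", function(x) x@chemIds)

setMethod("show", "TaskDataset", function(object) {
  cat(sprintf("TaskDataset '%s': %d chemicals x %d features\n",
              object@taskName, nrow(object@X), ncol(object@X)))
  cat(sprintf("  positives: %d (%.1f%%)\n", sum(object@y),
              100 * mean(object@y)))
  tab <- table(factor(object@split,
                      levels = c("train", "validation", "test", "unsplit")))
  cat("  split:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
})

setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d chemicals x %d tasks (layer %d)\n",
              nrow(object@scores), ncol(object@scores), object@layerIndex))
})

setMethod("show", "MTForestNetModel", function(object) {
  cat(sprintf("MTForestNetModel: %d tasks, %d layers (best layer %d)\n",
              length(object@taskOrder), length(object@layers),
              object@bestLayer))
  cat(sprintf("  fingerprint width %d; forests: %d trees, mtry=%s, seed %d\n",
              object@featureLength, object@params@nTrees,
              object@params@mtryRule, object@params@seed))
  cat("  mean validation AUC by layer:",
      paste(sprintf("%.4f", object@meanValidationAUC), collapse = ", "), "\n")
})

setMethod("show", "ForestParams", function(object) {
  cat(sprintf("ForestParams: %d trees, mtry rule '%s', seed %d\n",
              object@nTrees, object@mtryRule, object@seed))
})

setMethod("show", "EZWeights", function(object) {
  cat(sprintf("EZWeights: %d endpoints (%d at 24hpf, %d at 120hpf), total weight %.3f\n",
              length(object@weights), sum(object@group == "24hpf"),
              sum(object@group == "120hpf"), sum(object@weights)))
})

setMethod("show", "DatasetGroup", function(object) {
  sizes <- vapply(object@subsets, function(s) length(s$ids), integer(1))
  cat(sprintf("DatasetGroup '%s': %d subset(s), sizes %s\n", object@name,
              length(object@subsets), paste(sizes, collapse = ", ")))
})

setMethod("show", "AugmentedDataset", function(object) {
  cat(sprintf("AugmentedDataset: %d chemicals, %d base + %d predicted-call features%s\n",
              length(object@chemIds), ncol(object@xBase), ncol(object@xZF),
              if (length(object@y)) " (labeled)" else ""))
})
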