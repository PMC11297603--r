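# Versioned on-disk model layout: one serialized forest per (layer, task)
# plus a plain-text JSON manifest carrying everything needed to rebuild the
# model object and verify compatibility. load(save(model)) reproduces
# predictions bit-identically.

MODEL_FORMAT_VERSION <- "1"

#' Persist a fitted model to a directory
#'
#' Writes \code{manifest.json} (task order, forest parameters, per-layer
#' validation AUCs, selected layer, fingerprint width, format version) and
#' one RDS file per (layer, task) forest. The score cache is not persisted;
#' a reloaded model recomputes scores by forward propagation.
#'
#' @param model fitted \code{\link{MTForestNetModel-class}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
saveModel <- function(model, dir) {
  stopifnot(is(model, "MTForestNetModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format_version = MODEL_FORMAT_VERSION,
    package_version = as.character(utils::packageVersion("MTForestNet")),
    task_order = model@taskOrder,
    n_layers = length(model@layers),
    best_layer = model@bestLayer,
    feature_length = model@featureLength,
    include_own_score = model@includeOwnScore,
    params = list(n_trees = model@params@nTrees,
                  mtry_rule = model@params@mtryRule,
                  seed = model@params@seed),
    mean_validation_auc = model@meanValidationAUC,
    per_layer_validation_auc = lapply(model@perLayerValidationAUC, unname),
    input_widths = lapply(model@layers, `[[`, "inputWidths")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (k in seq_along(model@layers))
    for (t in seq_along(model@taskOrder))
      saveRDS(model@layers[[k]]$forests[[t]],
              file.path(dir, sprintf("layer%02d_task%03d.rds", k, t)))
  invisible(dir)
}

#' Load a persisted model
#'
#' @param dir directory written by \code{\link{saveModel}}.
#' @return an \code{\link{MTForestNetModel-class}} whose predictions are
#'   bit-identical to the saved model's.
#' @export
loadModel <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("not a model directory (no manifest.json): ", dir)
  manifest <- tryCatch(jsonlite::read_json(mf, simplifyVector = TRUE),
                       error = function(e)
                         stop("corrupted model manifest: ", conditionMessage(e)))
  need <- c("format_version", "task_order", "n_layers", "best_layer",
            "feature_length", "params")
  if (!all(need %in% names(manifest)))
    stop("corrupted model manifest: missing field(s) ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  if (!identical(as.character(manifest$format_version), MODEL_FORMAT_VERSION))
    stop("unsupported model format version: ", manifest$format_version)
  tn <- manifest$task_order
  asRowList <- function(x, n) {
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ])
    else if (is.list(x)) x
    else if (n == 1L) list(x)
    else stop("corrupted model manifest: malformed per-layer field")
  }
  plAUC <- asRowList(manifest$per_layer_validation_auc, manifest$n_layers)
  plWidth <- asRowList(manifest$input_widths, manifest$n_layers)
  layers <- vector("list", manifest$n_layers)
  for (k in seq_len(manifest$n_layers)) {
    forests <- vector("list", length(tn))
    for (t in seq_along(tn)) {
      f <- file.path(dir, sprintf("layer%02d_task%03d.rds", k, t))
      if (!file.exists(f)) stop("model directory incomplete: missing ", f)
      forests[[t]] <- readRDS(f)
    }
    names(forests) <- tn
    layers[[k]] <- list(forests = forests,
                        inputWidths = rep_len(as.integer(plWidth[[k]]),
                                              length(tn)),
                        isFirst = k == 1L)
  }
  aucs <- lapply(plAUC, function(a) stats::setNames(as.numeric(a), tn))
  new("MTForestNetModel", taskOrder = tn, layers = layers,
      perLayerValidationAUC = aucs,
      meanValidationAUC = as.numeric(manifest$mean_validation_auc),
      bestLayer = as.integer(manifest$best_layer),
      params = forestParams(manifest$params$n_trees,
                            manifest$params$mtry_rule,
                            manifest$params$seed),
      featureLength = as.integer(manifest$feature_length),
      includeOwnScore = isTRUE(manifest$include_own_score),
      scoreCache = list())
}
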