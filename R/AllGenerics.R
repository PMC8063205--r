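#' Feature names of a container
#' @param x a [TrajectoryTable-class], [DenseCurveSet-class] or
#'   [MFPCAResult-class].
#' @return character vector of feature names.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname featureNames
#' @export
setMethod("featureNames", "TrajectoryTable", function(x)
  setdiff(names(x@data), .tt_meta_cols))

#' @rdname featureNames
#' @export
setMethod("featureNames", "DenseCurveSet", function(x) dimnames(x@curves)[[3L]])

#' @rdname featureNames
#' @export
setMethod("featureNames", "MFPCAResult", function(x) x@features)

#' VOI identifiers
#' @param x a container with per-VOI rows.
#' @return character vector of unique VOI ids, in table order.
#' @export
setGeneric("voiIds", function(x) standardGeneric("voiIds"))

#' @rdname voiIds
#' @export
setMethod("voiIds", "TrajectoryTable", function(x) unique(x@data$voi_id))

#' @rdname voiIds
#' @export
setMethod("voiIds", "DenseCurveSet", function(x) x@meta$voi_id)

#' @rdname voiIds
#' @export
setMethod("voiIds", "PredictionSet", function(x) x@data$voi_id)

#' Per-VOI metadata (voi_id, patient_id, label)
#' @param x a [TrajectoryTable-class] or [DenseCurveSet-class].
#' @return data.frame with one row per VOI.
#' @export
setGeneric("voiInfo", function(x) standardGeneric("voiInfo"))

#' @rdname voiInfo
#' @export
setMethod("voiInfo", "TrajectoryTable", function(x) {
  d <- unique(x@data[, c("voi_id", "patient_id", "label")])
  rownames(d) <- NULL
  d
})

#' @rdname voiInfo
#' @export
setMethod("voiInfo", "DenseCurveSet", function(x) x@meta)

#' Observed months of a trajectory table
#' @param x a [TrajectoryTable-class].
#' @return sorted unique observation months.
#' @export
setGeneric("obsMonths", function(x) standardGeneric("obsMonths"))

#' @rdname obsMonths
#' @export
setMethod("obsMonths", "TrajectoryTable", function(x)
  sort(unique(x@data$timepoint_month)))

#' Component scores
#' @param x a [UFPCAResult-class] or [MFPCAResult-class].
#' @param retainedOnly keep only the retained components.
#' @return numeric matrix of scores, rows = curves/VOIs.
#' @export
setGeneric("componentScores", function(x, retainedOnly = TRUE)
  standardGeneric("componentScores"))

#' @rdname componentScores
#' @export
setMethod("componentScores", "UFPCAResult", function(x, retainedOnly = TRUE) {
  if (retainedOnly) x@scores[, seq_len(x@retained), drop = FALSE] else x@scores
})

#' @rdname componentScores
#' @export
setMethod("componentScores", "MFPCAResult", function(x, retainedOnly = TRUE) {
  if (retainedOnly) x@scores[, seq_len(x@retained), drop = FALSE] else x@scores
})

#' Predicted Control-class probabilities
#' @param x a [PredictionSet-class].
#' @return named numeric vector (names are VOI ids).
#' @export
setGeneric("probControl", function(x) standardGeneric("probControl"))

#' @rdname probControl
#' @export
setMethod("probControl", "PredictionSet", function(x)
  stats::setNames(x@data$prob_control, x@data$voi_id))

#' @rdname probControl
#' @param object,... standard show/coercion arguments.
#' @export
setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nPatients, "patients,",
      object@nOrnVois, "ORN /", object@nControlVois, "Control VOIs,",
      object@nFeatures, "features\n")
  cat("  signal:", object@signalMode, "(effect", object@effectSize,
      ", noise sd", object@noiseSd, ")\n")
  cat("  months:", paste(object@obsMonths, collapse = ", "),
      "| seed:", object@seed, "\n")
})

#' @export
setMethod("show", "TrajectoryTable", function(object) {
  info <- voiInfo(object)
  cat("TrajectoryTable:", nrow(info), "VOIs (",
      sum(info$label == "ORN"), "ORN /", sum(info$label == "Control"),
      "Control ) x", length(obsMonths(object)), "months,",
      length(featureNames(object)), "features\n")
})

#' @export
setMethod("show", "VoxelVolume", function(object) {
  cat("VoxelVolume:", paste(dim(object@values), collapse = " x "),
      "voxels, spacing", paste(object@spacing, collapse = " x "), "mm\n")
})

#' @export
setMethod("show", "UFPCAResult", function(object) {
  cat("UFPCAResult:", ncol(object@phi), "components on",
      length(object@grid), "grid points;", object@retained, "retained",
      sprintf("(PVE %.3f)\n", sum(object@pve[seq_len(object@retained)])))
})

#' @export
setMethod("show", "MFPCAResult", function(object) {
  cat("MFPCAResult:", length(object@features), "features,",
      length(object@values), "multivariate components;",
      object@retained, "retained",
      sprintf("(PVE %.3f)\n", sum(object@pve[seq_len(object@retained)])))
})

#' @export
setMethod("show", "PredictionSet", function(object) {
  cat("PredictionSet [", object@representation, "]: ",
      nrow(object@data), " VOIs, mean heldout count ",
      round(mean(object@data$n_heldout), 1), "\n", sep = "")
})

#' @export
setMethod("show", "ROCReport", function(object) {
  cat(sprintf("ROCReport: AUC %.3f", object@auc))
  if (!all(is.na(object@ci)))
    cat(sprintf(" (95%% CI %.3f-%.3f, %s)", object@ci[1L], object@ci[2L],
                object@ciMethod))
  cat(";", nrow(object@points), "thresholds\n")
})

#' Coerce a TrajectoryTable to data.frame
#' @param x a [TrajectoryTable-class].
#' @param ... ignored.
#' @return the underlying data.frame.
#' @export
as.data.frame.TrajectoryTable <- function(x, ...) x@data
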