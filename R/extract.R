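#' Default texture-extraction configuration
#'
#' @param targetSpacing resampling target in mm (1 x 1 mm pixels, 3 mm
#'   slices).
#' @param nLevels gray-level discretization (equal-width bins).
#' @param modes texture matrix modes to compute.
#' @param nidNeighborhoods NGTDM window sizes.
#' @param resample whether to resample before extraction.
#' @return named list of settings, recorded as provenance in outputs.
#' @export
extractionConfig <- function(targetSpacing = c(1, 1, 3), nLevels = 32L,
                             modes = c("3D", "2.5D"),
                             nidNeighborhoods = c(3L, 5L, 7L),
                             resample = TRUE) {
  list(targetSpacing = targetSpacing, nLevels = as.integer(nLevels),
       modes = modes, nidNeighborhoods = as.integer(nidNeighborhoods),
       resample = resample)
}

#' Full radiomic feature vector for one VOI at one time point
#'
#' Resamples (trilinear volume / nearest-neighbour mask), discretizes
#' in-mask intensities and computes the first-order family plus the GLCM,
#' GLRL and NGTDM families in the configured modes and neighbourhood
#' sizes, in a deterministic column order. Features that are undefined on
#' the given region (e.g. an NGTDM window larger than the mask) are
#' emitted as `NA` (flagged-missing) rather than propagated.
#'
#' @param volume a [VoxelVolume-class].
#' @param mask a [VOIMask-class].
#' @param config from [extractionConfig()].
#' @return named numeric vector; names encode family, mode and parameters.
#' @export
computeFeatureVector <- function(volume, mask, config = extractionConfig()) {
  stopifnot(is(volume, "VoxelVolume"), is(mask, "VOIMask"))
  if (config$resample) {
    srcSpacing <- volume@spacing
    volume <- resampleTrilinear(volume, config$targetSpacing)
    mask <- resampleMaskNearest(mask, srcSpacing, config$targetSpacing)
  }
  if (sum(mask@indicator) < 27L)
    stop("mask has fewer than 27 voxels after resampling")
  lev <- discretizeLevels(volume, mask, config$nLevels)

  out <- numeric(0)
  safely <- function(expr, template) {
    v <- tryCatch(expr, error = function(e) {
      stats::setNames(rep(NA_real_, length(template)), template)
    })
    v[template]
  }
  fo <- safely(firstOrderFeatures(volume, mask, config$nLevels),
               c("mean", "sd", "skewness", "kurtosis", "entropy",
                 "local_entropy_median", "voxel_volume"))
  out <- c(out, stats::setNames(fo, paste0("fo_", names(fo))))

  glcmNames <- c("contrast", "correlation", "dissimilarity", "cluster_shade",
                 "inverse_difference_moment_normalized",
                 "information_measure_correlation_1")
  glrlNames <- c("short_run_emphasis", "long_run_emphasis",
                 "gray_level_nonuniformity", "run_length_nonuniformity",
                 "run_percentage")
  ngtdmNames <- c("coarseness", "contrast", "busyness", "complexity",
                  "texture_strength")
  for (mode in config$modes) {
    tag <- if (mode == "3D") "3d" else "2.5d"
    g <- safely(glcmFeatures(computeGLCM(lev, mode = mode,
                                         nLevels = config$nLevels)), glcmNames)
    out <- c(out, stats::setNames(g, paste0("glcm_", tag, "_", names(g))))
    r <- safely(glrlFeatures(lev, mode = mode, nLevels = config$nLevels),
                glrlNames)
    out <- c(out, stats::setNames(r, paste0("glrl_", tag, "_", names(r))))
  }
  for (mode in config$modes) {
    tag <- if (mode == "3D") "3d" else "2.5d"
    for (k in config$nidNeighborhoods) {
      v <- safely(ngtdmFeatures(lev, neighborhood = k, mode = mode), ngtdmNames)
      out <- c(out, stats::setNames(v, sprintf("ngtdm_%s_k%d_%s", tag, k,
                                               names(v))))
    }
  }
  out
}

#' Extract a longitudinal feature table from volumes and masks
#'
#' Runs [computeFeatureVector()] for every VOI at every configured month.
#' A VOI missing any required month is dropped entirely with a warning
#' (longitudinal analyses need complete trajectories).
#'
#' @param vois list of VOI entries; each entry is a list with `voi_id`,
#'   `patient_id`, `label` and `months`, a named list mapping month (as
#'   character) to `list(volume = , mask = )`.
#' @param config from [extractionConfig()].
#' @param months required months; defaults to the union observed across
#'   VOIs.
#' @return a [TrajectoryTable-class].
#' @export
extractFeatureTable <- function(vois, config = extractionConfig(),
                                months = NULL) {
  if (is.null(months))
    months <- sort(unique(as.numeric(unlist(lapply(vois, function(v)
      names(v$months))))))
  rows <- list()
  for (v in vois) {
    have <- as.numeric(names(v$months))
    if (!all(months %in% have)) {
      warning("VOI ", v$voi_id, " missing month(s) ",
              paste(setdiff(months, have), collapse = ", "),
              "; excluded from the table", call. = FALSE)
      next
    }
    for (m in months) {
      entry <- v$months[[as.character(m)]]
      fv <- computeFeatureVector(entry$volume, entry$mask, config)
      rows[[length(rows) + 1L]] <- data.frame(
        voi_id = v$voi_id, patient_id = v$patient_id, label = v$label,
        timepoint_month = m, t(fv), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no complete VOIs to extract")
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  trajectoryTable(d)
}

#' Read a trajectory table from CSV
#' @param path CSV with columns `voi_id,patient_id,label,timepoint_month`
#'   then features.
#' @return a [TrajectoryTable-class].
#' @export
readTrajectoryTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  trajectoryTable(d)
}

#' Write a trajectory table to CSV
#' @param table a [TrajectoryTable-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeTrajectoryTable <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
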