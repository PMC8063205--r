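#' @import methods
NULL

#' Synthetic cohort specification
#'
#' A `CohortSpec` describes a synthetic longitudinal radiomics cohort:
#' how many patients and volumes of interest (VOIs) to generate, the
#' block-correlation structure of the feature panel, where the
#' ORN-vs-Control discriminative signal lives (at baseline, in the net
#' change, or purely in the trajectory shape), and the noise level.
#' The defaults reproduce the study geometry the package is designed
#' around: 21 patients contributing 22 ORN and 21 paired Control VOIs
#' observed at months 0, 2 and 6 after radiotherapy.
#'
#' @slot nPatients number of patients.
#' @slot nOrnVois number of ORN VOIs (may exceed `nPatients`; a patient can
#'   contribute two lesions).
#' @slot nControlVois number of Control VOIs; every Control VOI is paired to
#'   a patient that also has an ORN VOI.
#' @slot nFeatures number of radiomic features in the panel.
#' @slot correlationBlocks list of `c(size, rho)` pairs describing
#'   equicorrelated feature blocks; sizes must sum to at most `nFeatures`
#'   (left-over features are uncorrelated).
#' @slot signalMode one of `"none"`, `"baseline"`, `"delta"`, `"shape"`.
#' @slot effectSize standardized mean separation injected per `signalMode`.
#' @slot noiseSd per-timepoint observation noise, on the standardized
#'   feature scale.
#' @slot obsMonths ordered observation months, first element 0.
#' @slot withinPatientRho correlation between the latent feature values of
#'   the paired ORN and Control VOIs of one patient (the paired same-dose
#'   design shares anatomy, so the default is substantial).
#' @slot netChangeSd standard deviation of the latent month-0 to month-6
#'   net change.
#' @slot baselineLevel common feature baseline level, in units of the
#'   latent (unit) feature sd. Radiomic features live on positive scales
#'   with coefficients of variation well below 1, and relative-change
#'   (delta) representations are only meaningful around a nonzero
#'   baseline; the default of 5 corresponds to a 20% coefficient of
#'   variation.
#' @slot seed integer RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec", representation(
  nPatients = "integer",
  nOrnVois = "integer",
  nControlVois = "integer",
  nFeatures = "integer",
  correlationBlocks = "list",
  signalMode = "character",
  effectSize = "numeric",
  noiseSd = "numeric",
  obsMonths = "numeric",
  withinPatientRho = "numeric",
  netChangeSd = "numeric",
  baselineLevel = "numeric",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
  if (object@nOrnVois < object@nPatients)
    msg <- c(msg, "nOrnVois must be >= nPatients (every patient has an ORN VOI)")
  if (object@nControlVois > object@nPatients)
    msg <- c(msg, "nControlVois must be <= nPatients (one paired Control per patient)")
  if (!object@signalMode %in% c("none", "baseline", "delta", "shape"))
    msg <- c(msg, "signalMode must be one of none/baseline/delta/shape")
  if (length(object@obsMonths) < 2L || object@obsMonths[1L] != 0 ||
      any(diff(object@obsMonths) <= 0))
    msg <- c(msg, "obsMonths must be strictly increasing and start at 0")
  for (b in object@correlationBlocks) {
    if (length(b) != 2L || b[1L] < 1 || b[2L] < 0 || b[2L] >= 1)
      msg <- c(msg, "each correlation block must be c(size >= 1, rho in [0,1))")
  }
  if (sum(vapply(object@correlationBlocks, `[`, numeric(1), 1L)) > object@nFeatures)
    msg <- c(msg, "correlation block sizes exceed nFeatures")
  if (object@withinPatientRho < 0 || object@withinPatientRho >= 1)
    msg <- c(msg, "withinPatientRho must be in [0, 1)")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' @param nPatients,nOrnVois,nControlVois,nFeatures cohort sizes.
#' @param correlationBlocks list of `c(size, rho)` pairs.
#' @param signalMode `"none"`, `"baseline"`, `"delta"` or `"shape"`.
#' @param effectSize,noiseSd signal and noise magnitudes (standardized scale).
#' @param obsMonths observation months.
#' @param withinPatientRho latent ORN/Control within-patient correlation.
#' @param netChangeSd sd of the latent net change over the follow-up.
#' @param baselineLevel common nonzero feature baseline level (latent-sd
#'   units).
#' @param seed integer seed.
#' @return a validated [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(signalMode = "shape", seed = 1L)
#' @export
cohortSpec <- function(nPatients = 21L, nOrnVois = 22L, nControlVois = 21L,
                       nFeatures = 16L,
                       correlationBlocks = list(c(4, 0.4), c(4, 0.4),
                                                c(4, 0.4), c(4, 0.4)),
                       signalMode = "shape", effectSize = 1.5, noiseSd = 0.2,
                       obsMonths = c(0, 2, 6), withinPatientRho = 0.5,
                       netChangeSd = 0.5, baselineLevel = 5, seed = 1L) {
  new("CohortSpec",
      nPatients = as.integer(nPatients), nOrnVois = as.integer(nOrnVois),
      nControlVois = as.integer(nControlVois), nFeatures = as.integer(nFeatures),
      correlationBlocks = correlationBlocks, signalMode = signalMode,
      effectSize = effectSize, noiseSd = noiseSd, obsMonths = as.numeric(obsMonths),
      withinPatientRho = withinPatientRho, netChangeSd = netChangeSd,
      baselineLevel = baselineLevel, seed = as.integer(seed))
}

#' Textured phantom specification
#'
#' Describes a deterministic textured phantom volume with two spherical
#' VOIs carrying (possibly different) band-limited sinusoidal textures on a
#' shared base level, used as a fully known fixture for the texture-feature
#' extractors.
#'
#' @slot gridShape voxels per axis (x, y, z).
#' @slot voxelSpacing voxel spacing in mm (x, y, z).
#' @slot textureA,textureB numeric `c(base, amplitude, period)`; period in
#'   voxels.
#' @slot maskRadiusMM VOI sphere radius in mm.
#' @slot noiseSd additive white-noise sd.
#' @slot seed integer seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec", representation(
  gridShape = "integer",
  voxelSpacing = "numeric",
  textureA = "numeric",
  textureB = "numeric",
  maskRadiusMM = "numeric",
  noiseSd = "numeric",
  seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 3L))
    msg <- c(msg, "gridShape must be 3 axes of >= 3 voxels")
  if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
    msg <- c(msg, "voxelSpacing must be 3 positive values (mm)")
  for (tx in list(object@textureA, object@textureB))
    if (length(tx) != 3L || tx[3L] <= 0)
      msg <- c(msg, "textures must be c(base, amplitude, period > 0)")
  if (object@maskRadiusMM <= 0) msg <- c(msg, "maskRadiusMM must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param gridShape,voxelSpacing,textureA,textureB,maskRadiusMM,noiseSd,seed
#'   see [PhantomSpec-class].
#' @return a validated [PhantomSpec-class] object.
#' @export
phantomSpec <- function(gridShape = c(48L, 24L, 16L),
                        voxelSpacing = c(1, 1, 3),
                        textureA = c(100, 20, 4),
                        textureB = c(100, 40, 8),
                        maskRadiusMM = 7, noiseSd = 2, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSpacing = as.numeric(voxelSpacing),
      textureA = as.numeric(textureA), textureB = as.numeric(textureB),
      maskRadiusMM = maskRadiusMM, noiseSd = noiseSd, seed = as.integer(seed))
}

#' 3D scalar volume with anisotropic voxel spacing
#'
#' @slot values 3D numeric array of intensities.
#' @slot spacing voxel spacing in mm along (x, y, z).
#' @exportClass VoxelVolume
setClass("VoxelVolume", representation(values = "array", spacing = "numeric"))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L) msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (any(!is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelVolume
#' @param values 3D numeric array.
#' @param spacing voxel spacing in mm, length 3.
#' @return a [VoxelVolume-class].
#' @export
voxelVolume <- function(values, spacing = c(1, 1, 1)) {
  new("VoxelVolume", values = values, spacing = as.numeric(spacing))
}

#' Binary volume-of-interest mask
#'
#' @slot indicator 3D logical array aligned with its [VoxelVolume-class].
#' @exportClass VOIMask
setClass("VOIMask", representation(indicator = "array"))

setValidity("VOIMask", function(object) {
  if (length(dim(object@indicator)) != 3L) return("indicator must be a 3D array")
  if (!is.logical(object@indicator)) return("indicator must be logical")
  TRUE
})

#' Construct a VOIMask
#' @param indicator 3D logical (or 0/1) array.
#' @return a [VOIMask-class].
#' @export
voiMask <- function(indicator) {
  storage.mode(indicator) <- "logical"
  new("VOIMask", indicator = indicator)
}

#' Long-format longitudinal feature table
#'
#' One row per (VOI, observed month), wide by feature. The first four
#' columns are `voi_id`, `patient_id`, `label` (ORN/Control) and
#' `timepoint_month`; all remaining columns are radiomic features.
#'
#' @slot data the underlying data.frame.
#' @exportClass TrajectoryTable
setClass("TrajectoryTable", representation(data = "data.frame"))

.tt_meta_cols <- c("voi_id", "patient_id", "label", "timepoint_month")

setValidity("TrajectoryTable", function(object) {
  d <- object@data
  msg <- character()
  if (!all(.tt_meta_cols %in% names(d)))
    msg <- c(msg, sprintf("missing required columns: %s",
                          paste(setdiff(.tt_meta_cols, names(d)), collapse = ", ")))
  else {
    if (!all(d$label %in% c("ORN", "Control")))
      msg <- c(msg, "labels must be 'ORN' or 'Control'")
    if (anyDuplicated(d[, c("voi_id", "timepoint_month")]))
      msg <- c(msg, "duplicate (voi_id, timepoint_month) rows")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TrajectoryTable
#' @param data data.frame with columns `voi_id`, `patient_id`, `label`,
#'   `timepoint_month` and one column per feature.
#' @return a [TrajectoryTable-class].
#' @export
trajectoryTable <- function(data) new("TrajectoryTable", data = data)

#' Dense per-VOI curves on a common monthly grid
#'
#' @slot grid months at which the curves are sampled.
#' @slot weights quadrature weights over the grid (trapezoidal by default).
#' @slot curves numeric array `[voi, grid point, feature]`.
#' @slot meta data.frame with `voi_id`, `patient_id`, `label` per VOI.
#' @exportClass DenseCurveSet
setClass("DenseCurveSet", representation(
  grid = "numeric", weights = "numeric", curves = "array", meta = "data.frame"))

setValidity("DenseCurveSet", function(object) {
  msg <- character()
  if (any(diff(object@grid) <= 0)) msg <- c(msg, "grid must be strictly increasing")
  if (length(object@weights) != length(object@grid))
    msg <- c(msg, "weights must match grid length")
  d <- dim(object@curves)
  if (length(d) != 3L || d[2L] != length(object@grid) || d[1L] != nrow(object@meta))
    msg <- c(msg, "curves must be [voi, grid, feature] matching meta and grid")
  if (length(msg)) msg else TRUE
})

#' Univariate functional PCA decomposition
#'
#' @slot grid,weights the quadrature grid.
#' @slot mu pointwise mean curve.
#' @slot phi eigenfunctions, one column per component, orthonormal under the
#'   quadrature inner product.
#' @slot lambda eigenvalues, non-increasing.
#' @slot scores per-curve component scores (rows = curves).
#' @slot pve proportion of variance explained per component.
#' @slot retained number of components kept at the configured PVE level.
#' @exportClass UFPCAResult
setClass("UFPCAResult", representation(
  grid = "numeric", weights = "numeric", mu = "numeric", phi = "matrix",
  lambda = "numeric", scores = "matrix", pve = "numeric", retained = "integer"))

#' Multivariate functional PCA decomposition
#'
#' Joint decomposition of several features' curves through the
#' eigen-structure of their stacked univariate scores.
#'
#' @slot features feature names, in stacking order.
#' @slot grid,weights the quadrature grid.
#' @slot ufpca list of per-feature [UFPCAResult-class] objects.
#' @slot vectors orthonormal stacked-score eigenvectors (columns).
#' @slot values multivariate eigenvalues, non-increasing.
#' @slot scores per-VOI multivariate scores (rows = VOIs).
#' @slot eigenfunctions list (per feature) of matrices `[grid, component]`
#'   holding the feature blocks of the multivariate eigenfunctions.
#' @slot pve proportion of variance explained per multivariate component.
#' @slot retained number of multivariate components kept.
#' @slot voiIds VOI identifiers for the score rows.
#' @exportClass MFPCAResult
setClass("MFPCAResult", representation(
  features = "character", grid = "numeric", weights = "numeric",
  ufpca = "list", vectors = "matrix", values = "numeric", scores = "matrix",
  eigenfunctions = "list", pve = "numeric", retained = "integer",
  voiIds = "character"))

#' Out-of-sample prediction set
#'
#' Per-VOI mean held-out probability of the Control class under repeated
#' random-subsampling (Monte-Carlo) cross-validation.
#'
#' @slot data data.frame with `voi_id`, `patient_id`, `label`,
#'   `prob_control`, `n_heldout`.
#' @slot representation which design matrix produced it (baseline, delta2,
#'   delta6, trajectory, ensemble).
#' @exportClass PredictionSet
setClass("PredictionSet", representation(
  data = "data.frame", representation = "character"))

setValidity("PredictionSet", function(object) {
  d <- object@data
  req <- c("voi_id", "patient_id", "label", "prob_control", "n_heldout")
  if (!all(req %in% names(d))) return("missing prediction columns")
  if (any(d$prob_control < 0 | d$prob_control > 1)) return("probabilities outside [0,1]")
  if (any(d$n_heldout < 1)) return("every VOI must be held out at least once")
  TRUE
})

#' ROC analysis report
#'
#' @slot points data.frame of `threshold`, `sensitivity`, `specificity` and
#'   Youden `J` per candidate threshold (ORN is the detection-positive class,
#'   called when `prob_control` falls below the threshold).
#' @slot auc area under the ROC curve (trapezoidal).
#' @slot ci 95% confidence interval for the AUC, or `c(NA, NA)` if not
#'   computed.
#' @slot ciMethod `"delong"`, `"bootstrap"` or `"none"`.
#' @exportClass ROCReport
setClass("ROCReport", representation(
  points = "data.frame", auc = "numeric", ci = "numeric", ciMethod = "character"))

setValidity("ROCReport", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "AUC outside [0,1]")
  if (!all(is.na(object@ci)) &&
      (object@ci[1L] > object@auc + 1e-12 || object@ci[2L] < object@auc - 1e-12))
    msg <- c(msg, "CI must contain the AUC")
  if (length(msg)) msg else TRUE
})
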