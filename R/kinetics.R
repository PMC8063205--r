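#' Scale features to unit variance of the stacked observations
#'
#' Feature scales differ by orders of magnitude (mm^3 volumes vs entropy
#' bits); dividing each feature column by the standard deviation of its
#' stacked (all VOIs, all months) observations stops any one feature from
#' dominating the functional covariance. The transform is recorded so it
#' is reversible.
#'
#' @param table a [TrajectoryTable-class].
#' @return the scaled table, with a `"featureScales"` attribute on the
#'   underlying data.frame.
#' @export
standardizeFeatures <- function(table) {
  d <- as.data.frame(table)
  feats <- featureNames(table)
  scales <- vapply(feats, function(f) stats::sd(d[[f]]), numeric(1))
  if (any(scales == 0)) stop("constant feature column(s): ",
                             paste(feats[scales == 0], collapse = ", "))
  for (f in feats) d[[f]] <- d[[f]] / scales[f]
  out <- trajectoryTable(d)
  attr(out@data, "featureScales") <- scales
  out
}

#' Cubic spline completion of sparse trajectories
#'
#' Fits a natural cubic spline through each VOI x feature trajectory's
#' observed (month, value) points and evaluates it at the dense monthly
#' grid, turning 3-point trajectories into dense curves. Pure
#' interpolation: the grid must lie inside the observed month range, and
#' the curves pass exactly through the observations.
#'
#' @param table a [TrajectoryTable-class].
#' @param grid evaluation months (default integer months 0..6).
#' @return a [DenseCurveSet-class] with trapezoidal quadrature weights.
#' @export
splineComplete <- function(table, grid = 0:6) {
  d <- as.data.frame(table)
  months <- obsMonths(table)
  if (min(grid) < min(months) || max(grid) > max(months))
    stop("grid extends beyond the observed months; spline completion does not extrapolate")
  feats <- featureNames(table)
  info <- voiInfo(table)
  n <- nrow(info)
  curves <- array(NA_real_, c(n, length(grid), length(feats)),
                  dimnames = list(info$voi_id, NULL, feats))
  for (i in seq_len(n)) {
    rowsI <- d[d$voi_id == info$voi_id[i], , drop = FALSE]
    rowsI <- rowsI[order(rowsI$timepoint_month), , drop = FALSE]
    if (!identical(as.numeric(rowsI$timepoint_month), as.numeric(months)))
      stop("VOI ", info$voi_id[i], " is missing observed months")
    for (f in feats)
      curves[i, , f] <- stats::spline(rowsI$timepoint_month, rowsI[[f]],
                                      xout = grid, method = "natural")$y
  }
  new("DenseCurveSet", grid = as.numeric(grid),
      weights = trapezoidWeights(grid), curves = curves, meta = info)
}

#' Univariate functional principal component analysis
#'
#' Centers the curves by the pointwise mean, forms the empirical covariance
#' and solves the quadrature-weighted eigenproblem (symmetrised as
#' W^(1/2) C W^(1/2), eigenvectors back-transformed by W^(-1/2)), yielding
#' eigenfunctions orthonormal under the quadrature inner product. Scores
#' are quadrature integrals of the centered curves against the
#' eigenfunctions. Each eigenfunction's sign is fixed so its quadrature
#' integral (or, when that is near zero, its first grid value) is
#' positive, making the decomposition deterministic.
#'
#' @param curves numeric matrix, one curve per row, on a common grid.
#' @param grid sampling grid (months).
#' @param weights quadrature weights; trapezoidal by default.
#' @param pve proportion of variance explained to retain (default 0.99).
#' @return a [UFPCAResult-class].
#' @export
ufpca <- function(curves, grid = NULL, weights = NULL, pve = 0.99) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 2L) stop("need at least 2 curves")
  if (is.null(grid)) grid <- seq_len(ncol(curves)) - 1
  if (is.null(weights)) weights <- trapezoidWeights(grid)
  stopifnot(length(grid) == ncol(curves), length(weights) == length(grid))

  mu <- colMeans(curves)
  Xc <- sweep(curves, 2L, mu)
  C <- crossprod(Xc) / (n - 1)
  sw <- sqrt(weights)
  A <- (sw * t(sw * C))          # W^{1/2} C W^{1/2} (symmetric)
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  if (sum(lambda) <= 0) stop("zero total variance; curves are identical")
  phi <- eig$vectors / sw        # back-transform

  for (m in seq_len(ncol(phi))) {
    s <- sum(weights * phi[, m])
    flip <- if (abs(s) > 1e-8) sign(s) else sign(phi[1L, m] + (phi[1L, m] == 0))
    phi[, m] <- phi[, m] * flip
  }
  scores <- Xc %*% (weights * phi)
  pveVec <- lambda / sum(lambda)
  retained <- which(cumsum(pveVec) >= pve - 1e-12)[1L]
  new("UFPCAResult", grid = as.numeric(grid), weights = weights, mu = mu,
      phi = phi, lambda = lambda, scores = scores, pve = pveVec,
      retained = as.integer(retained))
}

#' Multivariate functional principal component analysis
#'
#' Joint decomposition of several features' trajectories. The retained
#' univariate scores of all features are stacked into a VOI x (sum M_j)
#' matrix; its sample covariance is eigendecomposed to give the
#' multivariate eigenvalues, orthonormal stacked-score eigenvectors and
#' per-VOI multivariate scores. The feature blocks of each eigenvector,
#' combined with the corresponding univariate eigenfunctions, give the
#' multivariate eigenfunction components, so correlated features share
#' components instead of being encoded independently. Eigenvector signs
#' are fixed so the largest-magnitude loading is positive.
#'
#' @param ufpcaList named list of per-feature [UFPCAResult-class] objects
#'   fitted on the same VOIs (same row order).
#' @param voiIds VOI identifiers for the score rows.
#' @param M number of multivariate components to retain; overrides `pve`.
#' @param pve retention level on cumulative proportion of variance
#'   explained (default 0.9).
#' @return an [MFPCAResult-class].
#' @export
mfpca <- function(ufpcaList, voiIds = NULL, M = NULL, pve = 0.9) {
  stopifnot(length(ufpcaList) >= 1L)
  ns <- vapply(ufpcaList, function(u) nrow(u@scores), integer(1))
  if (length(unique(ns)) != 1L) stop("all features must share the VOI set")
  n <- ns[1L]
  Mj <- vapply(ufpcaList, function(u) u@retained, integer(1))
  if (sum(Mj) == 0L) stop("no retained univariate components to stack")
  Xi <- do.call(cbind, lapply(ufpcaList, componentScores))
  C <- crossprod(scale(Xi, center = TRUE, scale = FALSE)) / (n - 1)
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  nu <- pmax(eig$values, 0)
  vec <- eig$vectors
  for (m in seq_len(ncol(vec))) {
    top <- which.max(abs(vec[, m]))
    if (vec[top, m] < 0) vec[, m] <- -vec[, m]
  }
  scores <- Xi %*% vec

  feats <- names(ufpcaList)
  if (is.null(feats)) feats <- paste0("feature", seq_along(ufpcaList))
  blockEnd <- cumsum(Mj)
  blockStart <- blockEnd - Mj + 1L
  eigenfuns <- lapply(seq_along(ufpcaList), function(j) {
    u <- ufpcaList[[j]]
    u@phi[, seq_len(Mj[j]), drop = FALSE] %*%
      vec[blockStart[j]:blockEnd[j], , drop = FALSE]
  })
  names(eigenfuns) <- feats

  pveVec <- nu / sum(nu)
  retained <- if (!is.null(M)) min(as.integer(M), length(nu)) else
    which(cumsum(pveVec) >= pve - 1e-12)[1L]
  if (is.null(voiIds)) voiIds <- as.character(seq_len(n))
  new("MFPCAResult", features = feats, grid = ufpcaList[[1L]]@grid,
      weights = ufpcaList[[1L]]@weights, ufpca = ufpcaList, vectors = vec,
      values = nu, scores = scores, eigenfunctions = eigenfuns,
      pve = pveVec, retained = as.integer(retained), voiIds = voiIds)
}

#' Reconstruct dense curves from a truncated MFPCA decomposition
#'
#' @param mf an [MFPCAResult-class].
#' @param M number of multivariate components to use (defaults to the
#'   retained number; 0 gives the mean curves).
#' @param meta optional per-VOI metadata data.frame (voi_id, patient_id,
#'   label).
#' @return a [DenseCurveSet-class] of reconstructed curves.
#' @export
reconstructCurves <- function(mf, M = mf@retained, meta = NULL) {
  stopifnot(M <= length(mf@values))
  n <- nrow(mf@scores)
  Tg <- length(mf@grid)
  p <- length(mf@features)
  curves <- array(0, c(n, Tg, p), dimnames = list(mf@voiIds, NULL, mf@features))
  for (j in seq_len(p)) {
    mu <- mf@ufpca[[j]]@mu
    rec <- matrix(mu, n, Tg, byrow = TRUE)
    if (M > 0)
      rec <- rec + mf@scores[, seq_len(M), drop = FALSE] %*%
        t(mf@eigenfunctions[[j]][, seq_len(M), drop = FALSE])
    curves[, , j] <- rec
  }
  if (is.null(meta))
    meta <- data.frame(voi_id = mf@voiIds, patient_id = NA_character_,
                       label = NA_character_, stringsAsFactors = FALSE)
  new("DenseCurveSet", grid = mf@grid, weights = mf@weights, curves = curves,
      meta = meta)
}

#' Trajectory encoding of a longitudinal feature table
#'
#' Convenience wrapper for the kinetics stage: standardize features, spline
#' complete to the monthly grid, fit per-feature UFPCA, then combine by
#' MFPCA.
#'
#' @param table a [TrajectoryTable-class].
#' @param grid dense monthly grid.
#' @param uPve univariate retention level.
#' @param mPve multivariate retention level.
#' @param M optional fixed number of multivariate components.
#' @param standardize scale features to unit stacked variance first.
#' @return list with `curves` (the [DenseCurveSet-class]), `ufpca` (list),
#'   `mfpca` (the [MFPCAResult-class]) and `scales`.
#' @export
trajectoryKinetics <- function(table, grid = 0:6, uPve = 0.99, mPve = 0.9,
                               M = NULL, standardize = TRUE) {
  scales <- NULL
  if (standardize) {
    table <- standardizeFeatures(table)
    scales <- attr(table@data, "featureScales")
  }
  curves <- splineComplete(table, grid)
  feats <- featureNames(curves)
  uf <- lapply(feats, function(f)
    ufpca(curves@curves[, , f], grid = curves@grid,
          weights = curves@weights, pve = uPve))
  names(uf) <- feats
  mf <- mfpca(uf, voiIds = curves@meta$voi_id, M = M, pve = mPve)
  list(curves = curves, ufpca = uf, mfpca = mf, scales = scales)
}
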