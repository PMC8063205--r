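#' Generate a synthetic longitudinal radiomics cohort
#'
#' Draws a feature-trajectory table with known ground truth. Each VOI's
#' features follow a multivariate Gaussian with the block correlation
#' structure of the specification; the paired ORN and Control VOIs of a
#' patient share a latent component (controlled by `withinPatientRho`),
#' mirroring the same-patient, same-dose Control design. The
#' class-discriminative signal is injected according to `signalMode`:
#'
#' * `baseline`: the ORN mean is shifted at month 0 and the shift is carried
#'   additively to all later months, so net changes are uninformative.
#' * `delta`: identical month-0 distributions; the ORN net change over the
#'   follow-up is shifted (ramping linearly in time).
#' * `shape`: identical month-0 AND identical net-change distributions, but
#'   ORN paths detour at the interior month(s) (non-monotone) while Control
#'   paths rise or fall monotonically — a scenario that neither a baseline
#'   model nor a delta model can detect, only the trajectory shape.
#' * `none`: the two classes are identical in law.
#'
#' @param spec a [CohortSpec-class].
#' @return list with elements `table` (a [TrajectoryTable-class]) and
#'   `truth` (labels, patient assignments and the injected signal
#'   parameters).
#' @examples
#' cohort <- generateTrajectoryCohort(cohortSpec(seed = 7L))
#' cohort$table
#' @export
generateTrajectoryCohort <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  p <- spec@nFeatures
  months <- spec@obsMonths
  tmax <- max(months)

  Sigma <- blockCorrelationMatrix(p, spec@correlationBlocks)
  L <- tryCatch(chol(Sigma), error = function(e)
    stop("implied correlation matrix is not positive definite"))

  patients <- sprintf("P%02d", seq_len(spec@nPatients))
  ornPatient <- c(patients,
                  if (spec@nOrnVois > spec@nPatients)
                    sample(patients, spec@nOrnVois - spec@nPatients))
  ctlPatient <- if (spec@nControlVois == spec@nPatients) patients
                else sample(patients, spec@nControlVois)
  voiPatient <- c(ornPatient, ctlPatient)
  voiLabel <- c(rep("ORN", spec@nOrnVois), rep("Control", spec@nControlVois))
  voiId <- c(sprintf("ORN%02d", seq_len(spec@nOrnVois)),
             sprintf("CTL%02d", seq_len(spec@nControlVois)))
  nVoi <- length(voiId)

  rmvn <- function(n) matrix(stats::rnorm(n * p), n, p) %*% L
  rho <- spec@withinPatientRho
  uBase <- rmvn(spec@nPatients); rownames(uBase) <- patients
  uChange <- rmvn(spec@nPatients); rownames(uChange) <- patients
  vBase <- rmvn(nVoi)
  vChange <- rmvn(nVoi)
  z <- sqrt(rho) * uBase[voiPatient, , drop = FALSE] + sqrt(1 - rho) * vBase
  g <- spec@netChangeSd *
    (sqrt(rho) * uChange[voiPatient, , drop = FALSE] + sqrt(1 - rho) * vChange)

  # class shift profile per month, applied to ORN VOIs on every feature
  shift <- vapply(months, function(t) switch(spec@signalMode,
    none = 0,
    baseline = spec@effectSize,
    delta = spec@effectSize * t / tmax,
    shape = if (t > 0 && t < tmax) spec@effectSize else 0), numeric(1))

  rows <- vector("list", length(months))
  for (k in seq_along(months)) {
    t <- months[k]
    x <- spec@baselineLevel + z + g * (t / tmax)
    x[voiLabel == "ORN", ] <- x[voiLabel == "ORN", , drop = FALSE] + shift[k]
    x <- x + matrix(stats::rnorm(nVoi * p, sd = spec@noiseSd), nVoi, p)
    colnames(x) <- sprintf("f%03d", seq_len(p))
    rows[[k]] <- data.frame(voi_id = voiId, patient_id = voiPatient,
                            label = voiLabel, timepoint_month = t,
                            x, stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, rows)
  d <- d[order(d$voi_id, d$timepoint_month), ]
  rownames(d) <- NULL

  truth <- list(voi_id = voiId, patient_id = voiPatient, label = voiLabel,
                signal_mode = spec@signalMode, effect_size = spec@effectSize,
                noise_sd = spec@noiseSd, shift_by_month = stats::setNames(shift,
                  as.character(months)),
                signal_features = sprintf("f%03d", seq_len(p)),
                seed = spec@seed)
  list(table = trajectoryTable(d), truth = truth)
}

# Block-diagonal equicorrelation matrix; features beyond the blocks are
# uncorrelated.
blockCorrelationMatrix <- function(p, blocks) {
  Sigma <- diag(p)
  at <- 1L
  for (b in blocks) {
    size <- as.integer(b[1L]); r <- b[2L]
    idx <- at:(at + size - 1L)
    Sigma[idx, idx] <- r
    diag(Sigma)[idx] <- 1
    at <- at + size
  }
  Sigma
}

#' Generate curves from a known orthonormal basis
#'
#' Fixture generator for functional-PCA recovery tests: draws curves
#' `mean + sum_m score_m * phi_m + noise` with independent Gaussian scores
#' of the requested variances, and returns the true scores alongside.
#'
#' @param eigenfunctions matrix `[grid point, component]`, orthonormal under
#'   the trapezoidal quadrature implied by `grid` (checked to 1e-6).
#' @param eigenvalues component score variances, one per column.
#' @param n number of curves.
#' @param noiseSd iid observation noise sd added pointwise.
#' @param seed integer seed.
#' @param grid strictly increasing sampling grid (defines the quadrature).
#' @param mean optional mean curve (defaults to 0).
#' @return list with `curves` (n x grid matrix), `scores` (n x M true
#'   scores), `grid` and `weights`.
#' @export
generateCurvesFromBasis <- function(eigenfunctions, eigenvalues, n,
                                    noiseSd = 0, seed = 1L, grid = NULL,
                                    mean = NULL) {
  phi <- as.matrix(eigenfunctions)
  if (is.null(grid)) grid <- seq_len(nrow(phi)) - 1
  stopifnot(length(grid) == nrow(phi),
            length(eigenvalues) == ncol(phi))
  w <- trapezoidWeights(grid)
  gram <- t(phi) %*% (w * phi)
  if (max(abs(gram - diag(ncol(phi)))) > 1e-6)
    stop("eigenfunctions are not orthonormal under the grid quadrature")
  if (is.null(mean)) mean <- numeric(length(grid))
  set.seed(seed)
  scores <- matrix(stats::rnorm(n * ncol(phi)), n) %*%
    diag(sqrt(eigenvalues), ncol(phi))
  curves <- matrix(mean, n, length(grid), byrow = TRUE) + scores %*% t(phi)
  if (noiseSd > 0)
    curves <- curves + matrix(stats::rnorm(length(curves), sd = noiseSd),
                              nrow(curves))
  list(curves = curves, scores = scores, grid = grid, weights = w)
}
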