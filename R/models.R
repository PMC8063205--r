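#' Random-forest Monte-Carlo cross-validation settings
#'
#' @param nTrees trees per forest (500, matching the study setting).
#' @param mtry split-candidate count; `NULL` means the conventional
#'   `floor(sqrt(p))` rule (a literal all-p reading can be requested
#'   explicitly).
#' @param nRepeats number of random train/test splits; enough that every
#'   VOI is held out many times.
#' @param testFraction fraction of patients (or VOIs) held out per repeat.
#' @param grouped split by patient so the paired ORN/Control VOIs of one
#'   patient never straddle the train/test boundary.
#' @param seed integer seed driving the split schedule and forests.
#' @return a `ModelSpec` settings list.
#' @export
modelSpec <- function(nTrees = 500L, mtry = NULL, nRepeats = 200L,
                      testFraction = 1 / 3, grouped = TRUE, seed = 1L) {
  stopifnot(testFraction > 0, testFraction < 1, nTrees >= 1L)
  structure(list(nTrees = as.integer(nTrees), mtry = mtry,
                 nRepeats = as.integer(nRepeats),
                 testFraction = testFraction, grouped = isTRUE(grouped),
                 seed = as.integer(seed)), class = "ModelSpec")
}

#' Build the design matrix for one representation
#'
#' `baseline` uses the month-0 feature values; `delta2` and `delta6` use
#' the relative change (x_t - x_0) / max(|x_0|, eps) to the 2- and 6-month
#' follow-up (eps = 1e-8 of the feature's month-0 scale guards against
#' division by zero); `trajectory` uses the retained MFPCA scores. The
#' ensemble has no design matrix — it averages two models' predictions
#' downstream.
#'
#' @param table a [TrajectoryTable-class].
#' @param representation one of `"baseline"`, `"delta2"`, `"delta6"`,
#'   `"trajectory"`.
#' @param kinetics result of [trajectoryKinetics()] (required for
#'   `"trajectory"`).
#' @return numeric VOI x feature matrix with VOI ids as rownames.
#' @export
buildRepresentation <- function(table, representation = c("baseline",
                                "delta2", "delta6", "trajectory"),
                                kinetics = NULL) {
  representation <- match.arg(representation)
  if (representation == "trajectory") {
    if (is.null(kinetics)) stop("trajectory representation needs the kinetics stage")
    sc <- componentScores(kinetics$mfpca)
    rownames(sc) <- kinetics$mfpca@voiIds
    colnames(sc) <- paste0("rho_", seq_len(ncol(sc)))
    return(sc)
  }
  months <- obsMonths(table)
  x0 <- monthMatrix(table, months[1L])
  if (representation == "baseline") return(x0)
  tUse <- if (representation == "delta2") months[2L] else months[length(months)]
  xt <- monthMatrix(table, tUse)
  scale <- apply(abs(x0), 2L, max)
  eps <- pmax(1e-8 * scale, .Machine$double.eps)
  denom <- pmax(abs(x0), rep(eps, each = nrow(x0)))
  (xt - x0) / denom
}

# Label-stratified, optionally patient-grouped split schedule: a list of
# logical held-out indicators, one per repeat. Splits with a single-class
# train or test partition are redrawn (bounded retries).
makeSplitSchedule <- function(labels, groups, nRepeats, testFraction,
                              grouped, seed) {
  set.seed(deriveSeed(seed, "splits"))
  n <- length(labels)
  out <- vector("list", nRepeats)
  for (r in seq_len(nRepeats)) {
    for (try in seq_len(100L)) {
      if (grouped) {
        gs <- unique(groups)
        nTest <- max(1L, round(testFraction * length(gs)))
        testG <- sample(gs, nTest)
        test <- groups %in% testG
      } else {
        test <- rep(FALSE, n)
        for (cl in unique(labels)) {
          idx <- which(labels == cl)
          test[sample(idx, max(1L, round(testFraction * length(idx))))] <- TRUE
        }
      }
      if (length(unique(labels[test])) == 2L &&
          length(unique(labels[!test])) == 2L) break
      if (try == 100L) stop("could not draw a two-class train/test split")
    }
    out[[r]] <- test
  }
  out
}

#' Monte-Carlo cross-validated random forest predictions
#'
#' For each repeat, draws a held-out set (patient-grouped by default, so
#' paired VOIs never leak across the split), fits a random forest on the
#' remaining VOIs and records the held-out Control-class probabilities.
#' The final probability per VOI is the mean over the repeats in which it
#' was held out. Deterministic given the spec seed.
#'
#' @param X design matrix (VOI x feature, VOI ids as rownames).
#' @param labels `"ORN"`/`"Control"` per row.
#' @param groups patient id per row.
#' @param spec a [modelSpec()].
#' @param splits optional precomputed split schedule (list of logical
#'   held-out indicators) so several representations share the same random
#'   splits; defaults to a schedule derived from the spec seed.
#' @param representation tag recorded on the result.
#' @return a [PredictionSet-class]; the split schedule is attached as the
#'   `"splits"` attribute for auditability.
#' @export
mcCvRandomForest <- function(X, labels, groups, spec = modelSpec(),
                             splits = NULL, representation = "custom") {
  X <- as.matrix(X)
  n <- nrow(X)
  labels <- factor(labels, levels = c("Control", "ORN"))
  if (nlevels(droplevels(labels)) < 2L) stop("need both classes")
  if (spec$grouped && min(table(unique(data.frame(groups, labels))$labels)) < 2L)
    stop("need at least 2 patients per class for grouped splitting")
  if (is.null(splits))
    splits <- makeSplitSchedule(labels, groups, spec$nRepeats,
                                spec$testFraction, spec$grouped, spec$seed)
  mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(ncol(X)))) else
    min(as.integer(spec$mtry), ncol(X))

  probSum <- numeric(n)
  heldout <- integer(n)
  set.seed(deriveSeed(spec$seed, "forest"))
  for (r in seq_along(splits)) {
    test <- splits[[r]]
    rf <- randomForest::randomForest(
      x = X[!test, , drop = FALSE], y = droplevels(labels[!test]),
      ntree = spec$nTrees, mtry = mtry)
    pr <- stats::predict(rf, X[test, , drop = FALSE], type = "prob")
    probSum[test] <- probSum[test] + pr[, "Control"]
    heldout[test] <- heldout[test] + 1L
  }
  if (any(heldout == 0L))
    stop("some VOIs were never held out; increase nRepeats")
  out <- new("PredictionSet",
             data = data.frame(voi_id = rownames(X), patient_id = groups,
                               label = as.character(labels),
                               prob_control = probSum / heldout,
                               n_heldout = heldout, stringsAsFactors = FALSE),
             representation = representation)
  attr(out@data, "splits") <- splits
  out
}

#' Average two prediction sets into an ensemble
#'
#' @param a,b two [PredictionSet-class] objects over the same VOIs.
#' @return a [PredictionSet-class] with the per-VOI unweighted mean of the
#'   two Control probabilities.
#' @export
ensembleAverage <- function(a, b) {
  da <- a@data; db <- b@data
  if (!setequal(da$voi_id, db$voi_id)) stop("mismatched VOI sets")
  db <- db[match(da$voi_id, db$voi_id), ]
  new("PredictionSet",
      data = data.frame(voi_id = da$voi_id, patient_id = da$patient_id,
                        label = da$label,
                        prob_control = (da$prob_control + db$prob_control) / 2,
                        n_heldout = pmin(da$n_heldout, db$n_heldout),
                        stringsAsFactors = FALSE),
      representation = "ensemble")
}

#' Run the five-model comparison suite
#'
#' Full analysis pipeline on a longitudinal feature table: correlation
#' filtering and screening, trajectory kinetics (spline completion, UFPCA,
#' MFPCA), then baseline / delta2 / delta6 / trajectory random forests
#' under one shared patient-grouped split schedule (so comparisons are
#' paired), and the baseline + trajectory ensemble.
#'
#' @param table a [TrajectoryTable-class].
#' @param corrThreshold mean-correlation filter bound.
#' @param grid dense monthly grid for kinetics.
#' @param uPve,mPve,M kinetics retention settings (see
#'   [trajectoryKinetics()]).
#' @param spec a [modelSpec()] shared by all representations.
#' @return list with `predictions` (named list of [PredictionSet-class]:
#'   baseline, delta2, delta6, trajectory, ensemble), `screening`,
#'   `kinetics`, `splits` and `settings`.
#' @export
runModelSuite <- function(table, corrThreshold = 0.5, grid = 0:6,
                          uPve = 0.99, mPve = 0.9, M = NULL,
                          spec = modelSpec()) {
  table <- dropIncompleteVois(table)
  scr <- screenFeatures(table, threshold = corrThreshold,
                        month = obsMonths(table)[1L])
  d <- as.data.frame(table)
  sub <- trajectoryTable(d[, c(.tt_meta_cols, scr$retained)])
  kin <- trajectoryKinetics(sub, grid = grid, uPve = uPve, mPve = mPve, M = M)

  info <- voiInfo(sub)
  splits <- makeSplitSchedule(info$label, info$patient_id, spec$nRepeats,
                              spec$testFraction, spec$grouped, spec$seed)
  reps <- c("baseline", "delta2", "delta6", "trajectory")
  preds <- lapply(reps, function(rp) {
    X <- buildRepresentation(sub, rp, kinetics = kin)
    X <- X[match(info$voi_id, rownames(X)), , drop = FALSE]
    mcCvRandomForest(X, info$label, info$patient_id, spec, splits = splits,
                     representation = rp)
  })
  names(preds) <- reps
  preds$ensemble <- ensembleAverage(preds$baseline, preds$trajectory)

  list(predictions = preds, screening = scr, kinetics = kin, splits = splits,
       settings = list(corrThreshold = corrThreshold, grid = grid,
                       uPve = uPve, mPve = mPve, M = M, spec = unclass(spec)))
}
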