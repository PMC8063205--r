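.predLabels <- function(predictions, labels) {
  if (is(predictions, "PredictionSet")) {
    list(prob = predictions@data$prob_control, label = predictions@data$label)
  } else list(prob = as.numeric(predictions), label = as.character(labels))
}

#' ROC curve and AUC of a prediction set
#'
#' ORN is the detection-positive class, called when the Control-class
#' probability falls below the threshold. Candidate thresholds are the
#' midpoints between sorted distinct probabilities plus the two infinities;
#' the AUC is the trapezoidal area, which equals the tie-corrected
#' two-sample U-statistic U/(n1 n2).
#'
#' @param predictions a [PredictionSet-class], or numeric Control
#'   probabilities.
#' @param labels `"ORN"`/`"Control"` per element (taken from the prediction
#'   set when omitted).
#' @return an [ROCReport-class] (without a confidence interval; see
#'   [aucCI()]).
#' @export
rocAndAuc <- function(predictions, labels = NULL) {
  pl <- .predLabels(predictions, labels)
  prob <- pl$prob; lab <- pl$label
  if (length(unique(lab)) < 2L) stop("both classes must be present")
  u <- sort(unique(prob))
  thr <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  isOrn <- lab == "ORN"
  pts <- data.frame(threshold = thr,
                    sensitivity = vapply(thr, function(t) mean(prob[isOrn] < t),
                                         numeric(1)),
                    specificity = vapply(thr, function(t) mean(prob[!isOrn] >= t),
                                         numeric(1)))
  pts$J <- pts$sensitivity + pts$specificity - 1
  fpr <- 1 - pts$specificity
  ord <- order(fpr, pts$sensitivity)
  auc <- sum(diff(fpr[ord]) *
               (pts$sensitivity[ord][-1L] + pts$sensitivity[ord][-nrow(pts)]) / 2)
  new("ROCReport", points = pts, auc = auc, ci = c(NA_real_, NA_real_),
      ciMethod = "none")
}

#' 95% confidence interval for the AUC
#'
#' DeLong's nonparametric variance method by default (truncated to
#' `[0, 1]`), or a seeded class-stratified percentile bootstrap. If the
#' DeLong variance is degenerate the bootstrap is used with a warning.
#'
#' @param predictions,labels as in [rocAndAuc()].
#' @param method `"delong"` or `"bootstrap"`.
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return numeric `c(low, high)`.
#' @export
aucCI <- function(predictions, labels = NULL,
                  method = c("delong", "bootstrap"), nBoot = 2000L,
                  seed = 1L) {
  method <- match.arg(method)
  pl <- .predLabels(predictions, labels)
  prob <- pl$prob; lab <- pl$label
  if (method == "delong") {
    ci <- tryCatch(suppressWarnings({
      r <- pROC::roc(response = lab, predictor = prob,
                     levels = c("Control", "ORN"), direction = ">",
                     quiet = TRUE)
      as.numeric(pROC::ci.auc(r, method = "delong"))[c(1L, 3L)]
    }), error = function(e) c(NA_real_, NA_real_))
    if (all(is.finite(ci)) && ci[2L] > ci[1L]) return(pmin(pmax(ci, 0), 1))
    warning("degenerate DeLong variance; falling back to bootstrap")
  }
  set.seed(deriveSeed(seed, "aucboot"))
  iOrn <- which(lab == "ORN"); iCtl <- which(lab == "Control")
  isOrn <- lab == "ORN"
  stat <- vapply(seq_len(nBoot), function(b) {
    idx <- c(sample(iOrn, replace = TRUE), sample(iCtl, replace = TRUE))
    fastAUC(prob[idx], isOrn[idx])
  }, numeric(1))
  unname(stats::quantile(stat, c(0.025, 0.975)))
}

# Tie-corrected rank AUC: P(prob_ORN < prob_Control) + 0.5 P(tie), equal to
# the trapezoidal ROC area. Used where many AUCs are needed (bootstrap).
fastAUC <- function(prob, isOrn) {
  nO <- sum(isOrn); nC <- sum(!isOrn)
  r <- rank(prob)
  (sum(r[!isOrn]) - nC * (nC + 1) / 2) / (nO * nC)
}

#' Youden-optimal operating point
#'
#' Maximizes J = sensitivity + specificity - 1 over the ROC points; ties
#' are broken toward higher sensitivity, then lower threshold, so the
#' choice is deterministic.
#'
#' @param roc an [ROCReport-class].
#' @return list with `threshold`, `sensitivity`, `specificity`, `J`.
#' @export
youdenOptimal <- function(roc) {
  pts <- roc@points
  ord <- order(-pts$J, -pts$sensitivity, pts$threshold)
  best <- pts[ord[1L], ]
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity, J = best$J)
}

#' Classify VOIs at a probability cutoff
#'
#' A region with Control probability strictly below the cutoff is called
#' ORN; at or above the cutoff it is called Control (the boundary goes to
#' Control, reading the cutoff as the value above which a region is
#' predicted Control).
#'
#' @param predictions a [PredictionSet-class] or numeric probabilities.
#' @param tau cutoff in `[0, 1]`.
#' @param labels true labels (taken from the prediction set when omitted).
#' @return list with `predicted` (per-VOI class), `confusion` (2 x 2 count
#'   matrix, rows = truth) and `percentCorrect` (per-class percent
#'   correctly classified).
#' @export
classifyAtThreshold <- function(predictions, tau, labels = NULL) {
  stopifnot(tau >= 0, tau <= 1)
  pl <- .predLabels(predictions, labels)
  predicted <- ifelse(pl$prob < tau, "ORN", "Control")
  conf <- table(factor(pl$label, levels = c("ORN", "Control")),
                factor(predicted, levels = c("ORN", "Control")))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("truth", "predicted")
  pct <- 100 * diag(conf) / rowSums(conf)
  list(predicted = stats::setNames(predicted,
         if (is(predictions, "PredictionSet")) predictions@data$voi_id else NULL),
       confusion = conf, percentCorrect = pct)
}

#' Full evaluation report for one prediction set
#'
#' @param predictions a [PredictionSet-class].
#' @param ciMethod `"delong"` or `"bootstrap"`.
#' @param tau cutoff for the confusion matrix; defaults to the
#'   Youden-optimal threshold.
#' @param seed bootstrap seed.
#' @return list with `roc` (an [ROCReport-class] including the CI),
#'   `youden`, `tau` and `classification`.
#' @export
evaluatePredictions <- function(predictions, ciMethod = "delong", tau = NULL,
                                seed = 1L) {
  roc <- rocAndAuc(predictions)
  ci <- aucCI(predictions, method = ciMethod, seed = seed)
  roc@ci <- pmin(pmax(c(min(ci[1L], roc@auc), max(ci[2L], roc@auc)), 0), 1)
  roc@ciMethod <- ciMethod
  yo <- youdenOptimal(roc)
  if (is.null(tau)) tau <- min(max(yo$threshold, 0), 1)
  list(roc = roc, youden = yo, tau = tau,
       classification = classifyAtThreshold(predictions, tau))
}

#' Comparison table across model representations
#'
#' @param suite result of [runModelSuite()].
#' @param ciMethod `"delong"` or `"bootstrap"`.
#' @param seed bootstrap seed.
#' @return data.frame with one row per representation: AUC, CI bounds and
#'   the Youden operating point.
#' @export
comparisonTable <- function(suite, ciMethod = "delong", seed = 1L) {
  rows <- lapply(names(suite$predictions), function(nm) {
    ev <- evaluatePredictions(suite$predictions[[nm]], ciMethod = ciMethod,
                              seed = seed)
    data.frame(representation = nm, auc = ev$roc@auc,
               ci_low = ev$roc@ci[1L], ci_high = ev$roc@ci[2L],
               youden_threshold = ev$youden$threshold,
               sensitivity = ev$youden$sensitivity,
               specificity = ev$youden$specificity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$auc), ]
}
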