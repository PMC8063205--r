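#' Spearman correlation matrix of features at one month
#'
#' @param table a [TrajectoryTable-class] (or plain feature matrix).
#' @param month which observed month to use (the pre-treatment time point
#'   by default).
#' @return feature x feature Spearman correlation matrix (average ranks for
#'   ties).
#' @export
spearmanMatrix <- function(table, month = 0) {
  m <- if (is(table, "TrajectoryTable")) monthMatrix(table, month) else
    as.matrix(table)
  if (nrow(m) < 3L) stop("need at least 3 VOIs for correlation filtering")
  constant <- apply(m, 2L, function(x) max(x) == min(x))
  if (any(constant))
    stop("constant feature column(s): ",
         paste(colnames(m)[constant], collapse = ", "),
         "; drop them before correlation filtering")
  stats::cor(m, method = "spearman")
}

#' Iterative mean-correlation feature filter
#'
#' Removes multicollinear features: while any feature's mean absolute
#' off-diagonal correlation with the currently retained features exceeds
#' the threshold, the feature with the largest such mean is removed (ties
#' broken by earliest column order) and the means are recomputed. The
#' procedure is deterministic and idempotent.
#'
#' @param corr square symmetric correlation matrix.
#' @param threshold mean absolute correlation bound in (0, 1); 0.5 balances
#'   multicollinearity reduction against retained variation.
#' @return character vector of retained feature names (or indices when the
#'   matrix has no dimnames).
#' @export
meanCorrelationFilter <- function(corr, threshold = 0.5) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr),
            threshold > 0, threshold < 1)
  nm <- colnames(corr)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(corr)))
  keep <- seq_len(ncol(corr))
  repeat {
    if (length(keep) == 1L) break
    sub <- abs(corr[keep, keep, drop = FALSE])
    means <- (colSums(sub) - 1) / (length(keep) - 1L)
    if (max(means) <= threshold) break
    worst <- which.max(means)   # which.max takes the earliest on ties
    keep <- keep[-worst]
    if (!length(keep)) stop("all features removed; raise the threshold")
  }
  nm[keep]
}

#' Mann-Whitney screening of features between ORN and Control
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per feature at one
#' month, with the direction of the mean difference mean(ORN) -
#' mean(Control). The exact null distribution is used when both group
#' sizes are at most 10 and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. Raw p-values are
#' reported; a Benjamini-Hochberg column is available behind a flag.
#'
#' @param table a [TrajectoryTable-class], or a numeric feature matrix.
#' @param month month at which to screen (ignored for a matrix).
#' @param labels factor/character of `"ORN"`/`"Control"` per row; derived
#'   from the table when omitted.
#' @param alpha significance level for the `significant` flag.
#' @param adjust add a Benjamini-Hochberg adjusted p-value column.
#' @return data.frame with columns `feature`, `U`, `p`, `direction`
#'   (`Positive`/`Negative`, `NA` when the means are equal), `significant`
#'   and optionally `p_bh`.
#' @export
mannWhitneyScreen <- function(table, month = 0, labels = NULL, alpha = 0.05,
                              adjust = FALSE) {
  if (is(table, "TrajectoryTable")) {
    m <- monthMatrix(table, month)
    info <- voiInfo(table)
    labels <- info$label[match(rownames(m), info$voi_id)]
  } else m <- as.matrix(table)
  stopifnot(!is.null(labels), all(labels %in% c("ORN", "Control")))
  orn <- labels == "ORN"
  if (!any(orn) || all(orn)) stop("both groups must be non-empty")

  res <- lapply(colnames(m), function(f) {
    x <- m[orn, f]; y <- m[!orn, f]
    exact <- length(x) <= 10L && length(y) <= 10L &&
      !anyDuplicated(c(x, y))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    md <- mean(x) - mean(y)
    data.frame(feature = f, U = unname(wt$statistic), p = wt$p.value,
               direction = if (md > 0) "Positive" else if (md < 0) "Negative"
                           else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- out$p < alpha
  if (adjust) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Run the pre-selection stage: correlation filter then screening
#'
#' @param table a [TrajectoryTable-class].
#' @param threshold mean-correlation bound for [meanCorrelationFilter()].
#' @param month filtering/screening month (pre-treatment by default; the
#'   retained list is then applied to all months).
#' @param alpha screening significance level.
#' @return list with `retained` (feature names), `screening` (the
#'   [mannWhitneyScreen()] table on the retained features) and `dropped`
#'   (features removed for undefined values or by the filter).
#' @export
screenFeatures <- function(table, threshold = 0.5, month = 0, alpha = 0.05) {
  d <- as.data.frame(table)
  feats <- featureNames(table)
  # keep only features defined for every VOI at every month (flagged-missing
  # and constant columns are unusable downstream)
  usable <- feats[vapply(feats, function(f) all(is.finite(d[[f]])), logical(1))]
  m0 <- monthMatrix(table, month)[, usable, drop = FALSE]
  nonconst <- usable[apply(m0, 2L, function(x) max(x) > min(x))]
  corr <- spearmanMatrix(m0[, nonconst, drop = FALSE], month)
  retained <- meanCorrelationFilter(corr, threshold)
  sub <- trajectoryTable(d[, c(.tt_meta_cols, retained)])
  list(retained = retained,
       screening = mannWhitneyScreen(sub, month = month, alpha = alpha),
       dropped = setdiff(feats, retained))
}
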