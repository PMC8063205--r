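#' Trapezoidal quadrature weights for a grid
#' @param grid strictly increasing numeric vector.
#' @return weights such that `sum(w * f(grid))` approximates the integral.
#' @export
trapezoidWeights <- function(grid) {
  stopifnot(length(grid) >= 2L, all(diff(grid) > 0))
  h <- diff(grid)
  w <- numeric(length(grid))
  w[1L] <- h[1L] / 2
  w[length(grid)] <- h[length(h)] / 2
  if (length(grid) > 2L)
    w[2:(length(grid) - 1L)] <- (h[-length(h)] + h[-1L]) / 2
  w
}

# Deterministic per-stage seed derivation: a small hash of the stage name
# folded into the global seed, kept inside the 32-bit integer range.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 9973L
  as.integer((as.numeric(seed) * 131L + h) %% .Machine$integer.max)
}

# Standardized group separation (pooled-sd Cohen's d) of x between labels.
standardizedSeparation <- function(x, label) {
  a <- x[label == "ORN"]; b <- x[label == "Control"]
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Drop VOIs with incomplete trajectories
#'
#' Longitudinal analyses need every VOI at every observed month; VOIs
#' missing any month (e.g. no 6-month follow-up scan) are excluded with a
#' warning.
#'
#' @param table a [TrajectoryTable-class].
#' @return the table restricted to complete VOIs.
#' @export
dropIncompleteVois <- function(table) {
  d <- as.data.frame(table)
  months <- obsMonths(table)
  counts <- base::table(d$voi_id)
  bad <- names(counts)[counts < length(months)]
  if (length(bad)) {
    warning("VOI(s) missing observed month(s), excluded: ",
            paste(bad, collapse = ", "), call. = FALSE)
    d <- d[!d$voi_id %in% bad, , drop = FALSE]
  }
  trajectoryTable(d)
}

# Wide month slice of a trajectory table: VOI x feature matrix at one month.
monthMatrix <- function(table, month) {
  d <- as.data.frame(table)
  d <- d[d$timepoint_month == month, , drop = FALSE]
  if (!nrow(d)) stop("no rows at month ", month)
  d <- d[match(voiIds(table), d$voi_id), , drop = FALSE]
  m <- as.matrix(d[, featureNames(table), drop = FALSE])
  rownames(m) <- d$voi_id
  m
}
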