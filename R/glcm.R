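#' Gray-level co-occurrence matrix
#'
#' Accumulates co-occurring discretized gray-level pairs at distance one
#' over all unique spatial directions — 13 offsets (26-connected
#' neighbourhood) in 3D mode, or the 4 in-plane offsets (8-connected)
#' accumulated slice by slice in 2.5D mode — counting a pair only when both
#' voxels are in-mask. Counts are symmetrised and normalised to sum 1, so
#' directional calculations are merged into one matrix.
#'
#' @param labelled integer level array from [discretizeLevels()] (`NA`
#'   outside the mask).
#' @param mask optional [VOIMask-class]/logical array restricting pairs
#'   (defaults to the non-`NA` voxels of `labelled`).
#' @param mode `"3D"` or `"2.5D"`.
#' @param nLevels matrix size; defaults to the `nLevels` attribute of
#'   `labelled`.
#' @return normalised symmetric `nLevels x nLevels` matrix.
#' @export
computeGLCM <- function(labelled, mask = NULL, mode = c("3D", "2.5D"),
                        nLevels = attr(labelled, "nLevels")) {
  mode <- match.arg(mode)
  if (is.null(nLevels)) nLevels <- max(labelled, na.rm = TRUE)
  lev <- labelled
  if (!is.null(mask)) {
    ind <- if (is(mask, "VOIMask")) mask@indicator else mask
    lev[!ind] <- NA_integer_
  }
  L <- as.integer(nLevels)
  dims <- dim(lev)
  counts <- matrix(0, L, L)
  for (r in seq_len(nrow(glcmOffsets(mode)))) {
    off <- glcmOffsets(mode)[r, ]
    rg <- offsetRanges(dims, off)
    if (!all(lengths(rg))) next
    a <- lev[rg[[1L]], rg[[2L]], rg[[3L]], drop = FALSE]
    b <- lev[rg[[1L]] + off[1L], rg[[2L]] + off[2L], rg[[3L]] + off[3L],
             drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate((a[ok] - 1L) * L + b[ok], nbins = L * L)
    counts <- counts + matrix(tab, L, L, byrow = TRUE)
  }
  counts <- counts + t(counts)          # symmetric accumulation
  if (sum(counts) == 0) stop("no valid voxel pairs for GLCM")
  counts / sum(counts)
}

#' Haralick-family features of a normalised GLCM
#'
#' Computes contrast, correlation, dissimilarity, cluster shade, inverse
#' difference moment normalised (IDMN) and the first information measure of
#' correlation (IMC1, base-2 entropies, with the 0*log(0) := 0 convention).
#' Features that are undefined on the given matrix (zero marginal variance
#' for correlation, zero marginal entropy for IMC1) are returned as `NA`
#' and listed in the `"undefined"` attribute.
#'
#' @param P normalised symmetric co-occurrence matrix.
#' @return named numeric vector of the six features.
#' @export
glcmFeatures <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P),
            abs(sum(P) - 1) < 1e-8)
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(seq_len(L) * px)
  muy <- sum(seq_len(L) * py)
  sdx <- sqrt(sum((seq_len(L) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(L) - muy)^2 * py))

  contrast <- sum(P * (i - j)^2)
  dissimilarity <- sum(P * abs(i - j))
  correlation <- if (sdx * sdy > 0)
    sum(P * (i - mux) * (j - muy)) / (sdx * sdy) else NA_real_
  clusterShade <- sum(P * (i + j - mux - muy)^3)
  idmn <- sum(P / (1 + (i - j)^2 / L^2))

  xlogx <- function(p) ifelse(p > 0, p * log2(p), 0)
  HX <- -sum(xlogx(px))
  HY <- -sum(xlogx(py))
  HXY <- -sum(xlogx(P))
  pxy <- outer(px, py)
  HXY1 <- -sum(P[pxy > 0] * log2(pxy[pxy > 0]))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else NA_real_

  out <- c(contrast = contrast, correlation = correlation,
           dissimilarity = dissimilarity, cluster_shade = clusterShade,
           inverse_difference_moment_normalized = idmn,
           information_measure_correlation_1 = imc1)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}
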