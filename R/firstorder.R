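#' First-order intensity features
#'
#' Moments over in-mask intensities, histogram entropy on the discretized
#' levels (base 2), the median local entropy over 3 x 3 x 1 in-plane
#' neighbourhoods of the discretized volume, and the physical VOI volume
#' (in-mask voxel count times the voxel volume in mm^3). Skewness and
#' kurtosis use the population moment definitions m3/m2^(3/2) and m4/m2^2
#' and are `NA`-flagged on constant regions.
#'
#' @param volume a [VoxelVolume-class].
#' @param mask a [VOIMask-class] (or logical array).
#' @param nLevels gray levels for the histogram/local entropies.
#' @return named numeric vector: `mean`, `sd`, `skewness`, `kurtosis`,
#'   `entropy`, `local_entropy_median`, `voxel_volume`.
#' @export
firstOrderFeatures <- function(volume, mask, nLevels = 32L) {
  stopifnot(is(volume, "VoxelVolume"))
  ind <- if (is(mask, "VOIMask")) mask@indicator else mask
  if (!any(ind)) stop("mask is empty")
  x <- volume@values[ind]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  sdv <- stats::sd(x)
  skew <- if (m2 > 0) mean((x - m)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((x - m)^4) / m2^2 else NA_real_

  lev <- discretizeLevels(volume, ind, nLevels)
  histEntropy <- levelEntropy(lev[ind])
  locEnt <- localEntropies(lev)
  vvol <- n * prod(volume@spacing)

  out <- c(mean = m, sd = sdv, skewness = skew, kurtosis = kurt,
           entropy = histEntropy,
           local_entropy_median = stats::median(locEnt),
           voxel_volume = vvol)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

# Shannon entropy (base 2) of an integer level vector.
levelEntropy <- function(levels) {
  p <- tabulate(levels)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# Per in-mask voxel: entropy of the discretized 3x3x1 in-plane window
# (window voxels restricted to the grid and the mask, center included).
localEntropies <- function(lev) {
  dims <- dim(lev)
  coords <- which(!is.na(lev), arr.ind = TRUE)
  vapply(seq_len(nrow(coords)), function(r) {
    co <- coords[r, ]
    xs <- max(1L, co[1L] - 1L):min(dims[1L], co[1L] + 1L)
    ys <- max(1L, co[2L] - 1L):min(dims[2L], co[2L] + 1L)
    win <- lev[xs, ys, co[3L]]
    levelEntropy(win[!is.na(win)])
  }, numeric(1))
}
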