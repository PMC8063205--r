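#' Neighborhood gray-tone difference features
#'
#' Amadasun-King-style features from the neighborhood gray-tone difference
#' vector. For neighbourhood size k, each voxel's window is the k x k x k
#' cube (3D) or k x k in-plane square (2.5D) excluding the center; only
#' voxels whose full window lies inside the mask contribute. With n_i the
#' number of contributing voxels at level i, p_i = n_i / N and
#' s_i = sum over those voxels of |i - mean(window levels)|, the features
#' are coarseness, contrast, busyness, complexity and texture strength
#' (strength uses the raw counts n_i and is 0 by convention when all s_i
#' vanish, i.e. on a constant region).
#'
#' @param labelled integer level array from [discretizeLevels()].
#' @param mask optional mask.
#' @param neighborhood window size, one of 3, 5, 7.
#' @param mode `"3D"` (cubic window) or `"2.5D"` (in-plane window).
#' @return named numeric vector of the five features (`NA` with an
#'   `"undefined"` attribute where a feature has no value, e.g. coarseness
#'   of a constant region).
#' @export
ngtdmFeatures <- function(labelled, mask = NULL, neighborhood = 3L,
                          mode = c("3D", "2.5D")) {
  mode <- match.arg(mode)
  stopifnot(neighborhood %in% c(3L, 5L, 7L))
  lev <- labelled
  if (!is.null(mask)) {
    ind <- if (is(mask, "VOIMask")) mask@indicator else mask
    lev[!ind] <- NA_integer_
  }
  L <- attr(labelled, "nLevels")
  if (is.null(L)) L <- max(lev, na.rm = TRUE)
  dims <- dim(lev)
  k <- as.integer(neighborhood)
  half <- (k - 1L) %/% 2L
  dzs <- if (mode == "3D") -half:half else 0L
  offs <- expand.grid(dx = -half:half, dy = -half:half, dz = dzs)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  nw <- nrow(offs)

  inMask <- !is.na(lev)
  lev0 <- lev; lev0[!inMask] <- 0L
  neighborCount <- array(0L, dims)
  neighborSum <- array(0, dims)
  shiftAdd <- function(acc, src, off) {
    rg <- offsetRanges(dims, off)
    if (!all(lengths(rg))) return(acc)
    dst <- acc
    dst[rg[[1L]], rg[[2L]], rg[[3L]]] <-
      dst[rg[[1L]], rg[[2L]], rg[[3L]], drop = FALSE] +
      src[rg[[1L]] + off[1L], rg[[2L]] + off[2L], rg[[3L]] + off[3L],
          drop = FALSE]
    dst
  }
  for (r in seq_len(nw)) {
    off <- as.integer(offs[r, ])
    neighborCount <- shiftAdd(neighborCount, inMask + 0L, off)
    neighborSum <- shiftAdd(neighborSum, lev0, off)
  }
  contributes <- inMask & neighborCount == nw
  if (!any(contributes))
    stop("no voxel has a complete in-mask window for neighborhood ", k)

  iLev <- lev[contributes]
  dev <- abs(iLev - neighborSum[contributes] / nw)
  n <- tabulate(iLev, nbins = L)
  s <- vapply(seq_len(L), function(i) sum(dev[iLev == i]), numeric(1))
  N <- sum(n)
  p <- n / N
  present <- p > 0
  Ng <- sum(present)
  lv <- seq_len(L)

  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else NA_real_

  ij2 <- outer(lv, lv, function(a, b) (a - b)^2)
  pp <- outer(p, p)
  contrastVal <- if (Ng >= 2)
    (sum(pp * ij2) / (Ng * (Ng - 1))) * (sum(s) / N) else 0

  ipi <- lv * p
  busyDen <- sum(abs(outer(ipi[present], ipi[present], `-`)))
  busyness <- if (busyDen > 0) ps / busyDen else 0

  complexity <- 0
  if (Ng >= 2) {
    pi_ <- p[present]; si_ <- s[present]; li_ <- lv[present]
    num <- outer(pi_ * si_, pi_ * si_, function(a, b) a + b)
    den <- outer(pi_, pi_, `+`)
    complexity <- sum(abs(outer(li_, li_, `-`)) * num / den) / N
  }

  ssum <- sum(s)
  strength <- if (ssum > 0) {
    ni_ <- n[present]; li_ <- lv[present]
    sum(outer(ni_, ni_, `+`) * outer(li_, li_, function(a, b) (a - b)^2)) / ssum
  } else 0

  out <- c(coarseness = coarseness, contrast = contrastVal,
           busyness = busyness, complexity = complexity,
           texture_strength = strength)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}
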