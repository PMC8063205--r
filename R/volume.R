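#' Trilinear resampling to a target voxel spacing
#'
#' Resamples a volume onto a new grid covering the same physical extent,
#' interpolating trilinearly between the eight nearest input voxel centers
#' (values outside the input center lattice are clamped to the border).
#' The default target, 1 x 1 mm in-plane and 3 mm slice thickness,
#' standardises voxel size before texture calculation.
#'
#' @param volume a [VoxelVolume-class].
#' @param targetSpacing target spacing in mm, length 3.
#' @return a resampled [VoxelVolume-class].
#' @export
resampleTrilinear <- function(volume, targetSpacing = c(1, 1, 3)) {
  stopifnot(is(volume, "VoxelVolume"), all(targetSpacing > 0))
  dims <- dim(volume@values)
  if (any(dims < 2L)) stop("cannot resample a degenerate (single-voxel) axis")
  sIn <- volume@spacing
  nNew <- pmax(1L, as.integer(round(dims * sIn / targetSpacing)))

  axisIndex <- function(ax) {
    centers <- (seq_len(nNew[ax]) - 0.5) * targetSpacing[ax]
    pos <- centers / sIn[ax] + 0.5            # fractional input index
    pos <- pmin(pmax(pos, 1), dims[ax])       # clamp to the center lattice
    i0 <- pmin(floor(pos), dims[ax] - 1L)
    list(i0 = as.integer(i0), frac = pos - i0)
  }
  ix <- axisIndex(1L); iy <- axisIndex(2L); iz <- axisIndex(3L)

  out <- array(0, nNew)
  V <- volume@values
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    wx <- if (a) ix$frac else 1 - ix$frac
    wy <- if (b) iy$frac else 1 - iy$frac
    wz <- if (c) iz$frac else 1 - iz$frac
    corner <- V[ix$i0 + a, iy$i0 + b, iz$i0 + c, drop = FALSE]
    w <- outer(outer(wx, wy), wz)
    out <- out + array(corner, nNew) * w
  }
  voxelVolume(out, targetSpacing)
}

#' Nearest-neighbour resampling of a binary mask
#'
#' Companion to [resampleTrilinear()]: the mask is carried to the same
#' target grid by nearest-center lookup so it stays binary.
#'
#' @param mask a [VOIMask-class].
#' @param sourceSpacing spacing of the grid the mask lives on, in mm.
#' @param targetSpacing target spacing in mm, length 3.
#' @return a resampled [VOIMask-class].
#' @export
resampleMaskNearest <- function(mask, sourceSpacing, targetSpacing = c(1, 1, 3)) {
  stopifnot(is(mask, "VOIMask"))
  dims <- dim(mask@indicator)
  nNew <- pmax(1L, as.integer(round(dims * sourceSpacing / targetSpacing)))
  nn <- function(ax) {
    centers <- (seq_len(nNew[ax]) - 0.5) * targetSpacing[ax]
    pos <- centers / sourceSpacing[ax] + 0.5
    as.integer(pmin(pmax(round(pos), 1), dims[ax]))
  }
  voiMask(mask@indicator[nn(1L), nn(2L), nn(3L), drop = FALSE])
}

#' Discretize in-mask intensities into equal-width gray levels
#'
#' Bins the intensities inside the mask into `nLevels` equal-width bins
#' between the in-mask minimum and maximum; a constant region maps entirely
#' to level 1 (flagged via the `"constant"` attribute). Voxels outside the
#' mask are `NA`.
#'
#' @param volume a [VoxelVolume-class] or 3D numeric array.
#' @param mask a [VOIMask-class] or 3D logical array.
#' @param nLevels number of gray levels (>= 2).
#' @return integer array of levels (`NA` outside the mask) with attributes
#'   `nLevels` and `constant`.
#' @export
discretizeLevels <- function(volume, mask, nLevels = 32L) {
  vals <- if (is(volume, "VoxelVolume")) volume@values else volume
  ind <- if (is(mask, "VOIMask")) mask@indicator else as.array(mask == TRUE)
  stopifnot(identical(dim(vals), dim(ind)), nLevels >= 2L)
  if (!any(ind)) stop("mask is empty")
  x <- vals[ind]
  lo <- min(x); hi <- max(x)
  lev <- array(NA_integer_, dim(vals))
  if (hi == lo) {
    lev[ind] <- 1L
    constant <- TRUE
  } else {
    lev[ind] <- pmin(as.integer(floor((x - lo) / (hi - lo) * nLevels)) + 1L,
                     as.integer(nLevels))
    constant <- FALSE
  }
  attr(lev, "nLevels") <- as.integer(nLevels)
  attr(lev, "constant") <- constant
  lev
}

# Direction sets: unique displacement vectors at distance 1 (symmetric pairs
# counted once). 13 offsets span the 26-connected 3D neighbourhood; the 4
# in-plane offsets span the 8-connected 2D neighbourhood.
glcmOffsets <- function(mode = c("3D", "2.5D")) {
  mode <- match.arg(mode)
  if (mode == "3D") {
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    offs <- offs[offs$dz == 1 | (offs$dz == 0 & offs$dy == 1) |
                   (offs$dz == 0 & offs$dy == 0 & offs$dx == 1), ]
  } else {
    offs <- data.frame(dx = c(1, -1, 0, 1), dy = c(0, 1, 1, 1), dz = 0)
  }
  as.matrix(offs)
}

# In-grid index ranges on both ends of an offset shift.
offsetRanges <- function(dims, off) {
  lapply(seq_len(3L), function(ax) {
    lo <- max(1L, 1L - off[ax]); hi <- min(dims[ax], dims[ax] - off[ax])
    if (lo > hi) integer() else lo:hi
  })
}
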