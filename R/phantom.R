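#' Generate a textured phantom volume with two spherical VOIs
#'
#' Builds a deterministic 3D volume whose two spherical regions carry
#' band-limited sinusoidal textures (base level + contrast amplitude at a
#' known spatial period) plus optional white noise, as a fully known
#' fixture for the texture-feature extractors.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `volume` (a [VoxelVolume-class]) and `maskA`, `maskB`
#'   (two disjoint [VOIMask-class] spheres).
#' @examples
#' ph <- generateTexturedPhantom(phantomSpec(seed = 3L))
#' ph$volume
#' @export
generateTexturedPhantom <- function(spec) {
  validObject(spec)
  set.seed(spec@seed)
  dims <- spec@gridShape
  sp <- spec@voxelSpacing

  # physical voxel-center coordinates
  cx <- (seq_len(dims[1L]) - 0.5) * sp[1L]
  cy <- (seq_len(dims[2L]) - 0.5) * sp[2L]
  cz <- (seq_len(dims[3L]) - 0.5) * sp[3L]
  centerA <- c(max(cx) * 0.27, mean(cy), mean(cz))
  centerB <- c(max(cx) * 0.73, mean(cy), mean(cz))

  sphere <- function(center) {
    dx2 <- (cx - center[1L])^2
    dy2 <- (cy - center[2L])^2
    dz2 <- (cz - center[3L])^2
    arr <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    arr <= spec@maskRadiusMM^2
  }
  maskA <- sphere(centerA)
  maskB <- sphere(centerB)
  inside <- function(m) {
    any(m) && !any(m[c(1L, dims[1L]), , ]) && !any(m[, c(1L, dims[2L]), ]) &&
      !any(m[, , c(1L, dims[3L])])
  }
  if (!inside(maskA) || !inside(maskB))
    stop("VOI masks are not fully inside the grid; enlarge the grid or shrink the radius")
  if (any(maskA & maskB)) stop("mask collision: the two VOIs overlap")

  texField <- function(tx) {
    base <- tx[1L]; amp <- tx[2L]; period <- tx[3L]
    ii <- sin(2 * pi * seq_len(dims[1L]) / period)
    jj <- sin(2 * pi * seq_len(dims[2L]) / period)
    kk <- sin(2 * pi * seq_len(dims[3L]) / period)
    base + amp * outer(outer(ii, jj), kk)
  }
  vol <- array(mean(c(spec@textureA[1L], spec@textureB[1L])), dims)
  fa <- texField(spec@textureA); fb <- texField(spec@textureB)
  vol[maskA] <- fa[maskA]
  vol[maskB] <- fb[maskB]
  if (spec@noiseSd > 0)
    vol <- vol + array(stats::rnorm(prod(dims), sd = spec@noiseSd), dims)

  list(volume = voxelVolume(vol, sp), maskA = voiMask(maskA),
       maskB = voiMask(maskB))
}

#' Write a phantom to NIfTI files
#'
#' @param phantom result of [generateTexturedPhantom()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written (volume, maskA, maskB).
#' @export
writePhantomNifti <- function(phantom, dir, prefix = "phantom") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- phantom$volume@spacing
  paths <- file.path(dir, paste0(prefix, c("", "_maskA", "_maskB"), ".nii.gz"))
  imgs <- list(phantom$volume@values,
               phantom$maskA@indicator + 0,
               phantom$maskB@indicator + 0)
  for (i in seq_along(imgs)) {
    arr <- imgs[[i]]
    attr(arr, "pixdim") <- sp
    img <- RNifti::asNifti(arr, datatype = if (i == 1L) "double" else "uint8")
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read a volume and masks from NIfTI files
#'
#' @param volumePath NIfTI scalar volume.
#' @param maskPaths character vector of NIfTI mask paths (non-zero = inside).
#' @return list with `volume` (a [VoxelVolume-class]) and `masks` (list of
#'   [VOIMask-class]).
#' @export
readVolumeNifti <- function(volumePath, maskPaths = character()) {
  img <- RNifti::readNifti(volumePath)
  sp <- RNifti::pixdim(img)[seq_len(3L)]
  vol <- voxelVolume(array(as.numeric(img), dim(img)[seq_len(3L)]), sp)
  masks <- lapply(maskPaths, function(p) {
    m <- RNifti::readNifti(p)
    if (!identical(dim(m)[seq_len(3L)], dim(vol@values)))
      stop("mask grid does not match the volume: ", p)
    voiMask(array(as.numeric(m) != 0, dim(vol@values)))
  })
  list(volume = vol, masks = masks)
}
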