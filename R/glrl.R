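#' Gray-level run-length matrix
#'
#' Accumulates maximal runs of equal discretized gray level along each
#' direction of the GLCM direction set (13 unique directions in 3D, the 4
#' in-plane directions in 2.5D), truncating runs at the mask boundary, and
#' sums the per-direction matrices into one matrix before feature
#' computation.
#'
#' @param labelled integer level array from [discretizeLevels()].
#' @param mask optional mask restricting runs.
#' @param mode `"3D"` or `"2.5D"`.
#' @param directions optional integer matrix of direction vectors (rows) to
#'   override the default set, e.g. a single direction for didactic runs.
#' @param nLevels number of gray levels.
#' @return list with `matrix` (levels x run length counts), `nRuns`,
#'   `nVoxels` (in-mask voxel count) and `nDirections`.
#' @export
computeGLRL <- function(labelled, mask = NULL, mode = c("3D", "2.5D"),
                        directions = NULL,
                        nLevels = attr(labelled, "nLevels")) {
  mode <- match.arg(mode)
  lev <- labelled
  if (!is.null(mask)) {
    ind <- if (is(mask, "VOIMask")) mask@indicator else mask
    lev[!ind] <- NA_integer_
  }
  if (is.null(nLevels)) nLevels <- max(lev, na.rm = TRUE)
  L <- as.integer(nLevels)
  dims <- dim(lev)
  if (is.null(directions)) directions <- glcmOffsets(mode)
  nVox <- sum(!is.na(lev))
  if (nVox == 0) stop("empty run set: mask has no voxels")

  maxLen <- max(dims)
  R <- matrix(0, L, maxLen)
  inGrid <- function(co) co[, 1L] >= 1L & co[, 1L] <= dims[1L] &
    co[, 2L] >= 1L & co[, 2L] <= dims[2L] & co[, 3L] >= 1L & co[, 3L] <= dims[3L]
  at <- function(co) lev[cbind(co[, 1L], co[, 2L], co[, 3L])]

  coordsAll <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(directions))) {
    d <- directions[r, ]
    prev <- sweep(coordsAll, 2L, d)
    pin <- inGrid(prev)
    prevLev <- rep(NA_integer_, nrow(coordsAll))
    prevLev[pin] <- at(prev[pin, , drop = FALSE])
    isStart <- !pin | is.na(prevLev) | prevLev != at(coordsAll)
    pos <- coordsAll[isStart, , drop = FALSE]
    runLev <- at(pos)
    runLen <- rep(1L, nrow(pos))
    active <- seq_len(nrow(pos))
    while (length(active)) {
      nxt <- sweep(pos[active, , drop = FALSE], 2L, d, `+`)
      ok <- inGrid(nxt)
      nxtLev <- rep(NA_integer_, length(active))
      nxtLev[ok] <- at(nxt[ok, , drop = FALSE])
      cont <- ok & !is.na(nxtLev) & nxtLev == runLev[active]
      pos[active[cont], ] <- nxt[cont, , drop = FALSE]
      runLen[active[cont]] <- runLen[active[cont]] + 1L
      active <- active[cont]
    }
    tab <- tabulate((runLev - 1L) * maxLen + runLen, nbins = L * maxLen)
    R <- R + matrix(tab, L, maxLen, byrow = TRUE)
  }
  list(matrix = R, nRuns = sum(R), nVoxels = nVox,
       nDirections = nrow(directions))
}

#' Run-length features (Galloway definitions)
#'
#' Short-run emphasis, long-run emphasis, gray-level nonuniformity,
#' run-length nonuniformity and run percentage computed from the
#' direction-merged run-length matrix. Run percentage is the number of runs
#' divided by the number of in-mask voxels times the number of directions,
#' so a single direction on a constant line of length n gives 1/n.
#'
#' @param labelled,mask,mode,directions,nLevels passed to [computeGLRL()].
#' @return named numeric vector of the five features.
#' @export
glrlFeatures <- function(labelled, mask = NULL, mode = c("3D", "2.5D"),
                         directions = NULL,
                         nLevels = attr(labelled, "nLevels")) {
  g <- computeGLRL(labelled, mask, match.arg(mode), directions, nLevels)
  R <- g$matrix
  Nr <- g$nRuns
  if (Nr == 0) stop("empty run set")
  l <- seq_len(ncol(R))
  rl <- colSums(R)    # runs per length
  rg <- rowSums(R)    # runs per gray level
  c(short_run_emphasis = sum(rl / l^2) / Nr,
    long_run_emphasis = sum(rl * l^2) / Nr,
    gray_level_nonuniformity = sum(rg^2) / Nr,
    run_length_nonuniformity = sum(rl^2) / Nr,
    run_percentage = Nr / (g$nVoxels * g$nDirections))
}
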