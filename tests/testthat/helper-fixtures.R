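# Shared fixture builders (all generated in code at test time).

randomLabelledVolume <- function(seed, maxDims = c(6, 6, 3), nLevels = 4,
                                 maskFrac = 1) {
  set.seed(seed)
  dims <- c(sample(3:maxDims[1], 1), sample(3:maxDims[2], 1),
            sample(2:maxDims[3], 1))
  lev <- array(sample.int(nLevels, prod(dims), replace = TRUE), dims)
  if (maskFrac < 1) {
    drop <- runif(prod(dims)) > maskFrac
    lev[drop] <- NA_integer_
    if (all(is.na(lev))) lev[1] <- 1L
  }
  attr(lev, "nLevels") <- as.integer(nLevels)
  lev
}

# Orthonormal 2-component basis on the month grid 0..6 under trapezoidal
# quadrature, built by Gram-Schmidt from two smooth shapes.
monthBasis2 <- function(grid = 0:6) {
  w <- radkinetics::trapezoidWeights(grid)
  b1 <- rep(1, length(grid))
  b2 <- grid - mean(grid)
  ip <- function(a, b) sum(w * a * b)
  b1 <- b1 / sqrt(ip(b1, b1))
  b2 <- b2 - ip(b2, b1) * b1
  b2 <- b2 / sqrt(ip(b2, b2))
  cbind(b1, b2)
}

smallShapeCohort <- function(n = 50L, seed = 1L, mode = "shape",
                             effect = 1.5) {
  radkinetics::generateTrajectoryCohort(radkinetics::cohortSpec(
    nPatients = n, nOrnVois = n, nControlVois = n,
    signalMode = mode, effectSize = effect, noiseSd = 0.2, seed = seed))
}

quickModelSpec <- function(seed = 1L, nRepeats = 20L, nTrees = 150L) {
  radkinetics::modelSpec(nTrees = nTrees, nRepeats = nRepeats, seed = seed)
}
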