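test_that("trilinear resampling is exact on identity and affine fields", {
  set.seed(1)
  v <- voxelVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)), c(1, 1, 3))
  expect_equal(resampleTrilinear(v, c(1, 1, 3))@values, v@values)
  # linear ramp along x is reproduced exactly when downsampling x2
  ramp <- voxelVolume(array(rep(1:8, 8 * 4), c(8, 8, 4)), c(1, 1, 1))
  out <- resampleTrilinear(ramp, c(2, 2, 2))
  # output centers at x = 1, 3, 5, 7 mm -> fractional input index 1.5..7.5
  expect_equal(out@values[, 1, 1], c(1.5, 3.5, 5.5, 7.5))
  expect_error(resampleTrilinear(
    voxelVolume(array(1, c(1, 4, 4)), c(1, 1, 1)), c(2, 2, 2)), "degenerate")
})

test_that("trilinear resampling matches corner-weight arithmetic at probes", {
  set.seed(42)
  V <- array(rnorm(8 * 8 * 8, 100, 15), c(8, 8, 8))
  v <- voxelVolume(V, c(1, 1, 1))
  out <- resampleTrilinear(v, c(2, 2, 2))
  probes <- rbind(c(1, 1, 1), c(2, 3, 1), c(4, 4, 4), c(3, 1, 2), c(2, 2, 3))
  for (r in seq_len(nrow(probes))) {
    idx <- probes[r, ]
    expect_equal(out@values[idx[1], idx[2], idx[3]],
                 oracleTrilinearAt(V, c(1, 1, 1), c(2, 2, 2), idx),
                 tolerance = 1e-12)
  }
})

test_that("equal-width discretization follows the bin arithmetic", {
  vals <- array(0, c(16, 16, 1)); vals[] <- 0:255
  m <- array(TRUE, dim(vals))
  lev <- discretizeLevels(vals, m, 8)
  expect_equal(lev[vals == 0][1], 1L)
  expect_equal(lev[vals == 255][1], 8L)
  expect_equal(lev[vals == 96][1], 4L)
  # constant region maps to level 1 and is flagged
  flat <- discretizeLevels(array(7, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 4)
  expect_true(all(flat == 1L))
  expect_true(attr(flat, "constant"))
  lv2 <- discretizeLevels(array(1:4, c(4, 1, 1)), array(TRUE, c(4, 1, 1)), 2)
  expect_equal(as.integer(lv2), c(1L, 1L, 2L, 2L))
})

test_that("GLCM handles constant and checkerboard patterns exactly", {
  flat <- discretizeLevels(array(5, c(3, 3, 3)), array(TRUE, c(3, 3, 3)), 2)
  P <- computeGLCM(flat, mode = "3D")
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)
  # 4x4 two-level checkerboard, single horizontal offset
  cb <- array(NA_integer_, c(4, 4, 1))
  cb[, , 1] <- (outer(1:4, 1:4, `+`) %% 2L) + 1L
  attr(cb, "nLevels") <- 2L
  # single horizontal offset: enumerate the 24 ordered pairs
  Pone <- oracleGLCM(cb, 2, list(c(1, 0, 0)))
  expect_equal(Pone, matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(glcmFeatures(Pone)[["contrast"]], 1)
  expect_equal(glcmFeatures(Pone)[["dissimilarity"]], 1)
  expect_equal(glcmFeatures(Pone)[["correlation"]], -1)
})

test_that("GLCM is normalised, symmetric and matches the pair-count oracle", {
  for (s in c(3, 9, 27)) {
    lev <- randomLabelledVolume(s, maskFrac = 0.85)
    for (mode in c("3D", "2.5D")) {
      offs <- if (mode == "3D") oracleOffsets3D() else oracleOffsets2D()
      P <- computeGLCM(lev, mode = mode)
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P), tolerance = 1e-12)
      expect_equal(P, oracleGLCM(lev, attr(lev, "nLevels"), offs),
                   tolerance = 1e-12)
    }
  }
})

test_that("GLCM features on a single-entry matrix vanish", {
  P <- matrix(0, 3, 3); P[1, 1] <- 1
  f <- glcmFeatures(P)
  expect_equal(unname(f[c("contrast", "dissimilarity", "cluster_shade")]),
               c(0, 0, 0))
  expect_true(all(c("correlation", "information_measure_correlation_1") %in%
                    attr(f, "undefined")))
})

test_that("run-length features agree with hand-counted runs", {
  # constant 1x1x8 line, one direction: a single run of length 8
  line <- array(1L, c(8, 1, 1)); attr(line, "nLevels") <- 2L
  g <- computeGLRL(line, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(g$nRuns, 1)
  expect_equal(g$matrix[1, 8], 1)
  f <- glrlFeatures(line, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(f[["run_percentage"]], 1 / 8)
  # strictly alternating line: 8 runs of length 1, SRE = 1
  alt <- array(rep(c(1L, 2L), 4), c(8, 1, 1)); attr(alt, "nLevels") <- 2L
  fa <- glrlFeatures(alt, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(fa[["short_run_emphasis"]], 1)
  expect_equal(fa[["run_percentage"]], 1)
})

test_that("run-length matrix conserves runs and matches the walking oracle", {
  for (s in c(5, 15)) {
    lev <- randomLabelledVolume(s, maskFrac = 0.9)
    g <- computeGLRL(lev, mode = "3D")
    expect_equal(sum(g$matrix), g$nRuns)
    expect_equal(glrlFeatures(lev, mode = "3D"),
                 oracleGLRLFeatures(lev, attr(lev, "nLevels"),
                                    oracleOffsets3D()),
                 tolerance = 1e-12)
  }
})

test_that("NGTDM features match the per-voxel window oracle", {
  # fixed 5x5 single-slice two-level pattern
  pat <- array(NA_integer_, c(5, 5, 1))
  pat[, , 1] <- matrix(c(1, 2, 1, 2, 1,
                         2, 1, 2, 1, 2,
                         1, 2, 2, 2, 1,
                         2, 1, 2, 1, 2,
                         1, 2, 1, 2, 1), 5, byrow = TRUE)
  attr(pat, "nLevels") <- 2L
  expect_equal(ngtdmFeatures(pat, neighborhood = 3, mode = "2.5D"),
               oracleNGTDM(pat, 2, 3, "2.5D"), tolerance = 1e-12,
               ignore_attr = TRUE)
  # constant region: zero contrast and strength by convention
  flat <- discretizeLevels(array(3, c(5, 5, 5)), array(TRUE, c(5, 5, 5)), 4)
  ff <- ngtdmFeatures(flat, neighborhood = 3)
  expect_equal(unname(ff[c("contrast", "texture_strength")]), c(0, 0))
  expect_true("coarseness" %in% attr(ff, "undefined"))
  # window larger than the region
  set.seed(2)
  lev5 <- array(sample.int(4, 125, replace = TRUE), c(5, 5, 5))
  attr(lev5, "nLevels") <- 4L
  expect_error(ngtdmFeatures(lev5, neighborhood = 7), "complete in-mask window")
})

test_that("first-order features match moments and the local-entropy oracle", {
  flat <- voxelVolume(array(4.5, c(4, 4, 3)), c(1, 1, 1))
  m <- voiMask(array(TRUE, c(4, 4, 3)))
  f <- firstOrderFeatures(flat, m)
  expect_equal(unname(f[c("mean", "sd", "local_entropy_median")]),
               c(4.5, 0, 0))
  expect_equal(unname(f["voxel_volume"]), 48)
  v2 <- voxelVolume(array(c(1, 2, 3, 4), c(4, 1, 1)), c(1, 1, 1))
  expect_equal(unname(
    firstOrderFeatures(v2, voiMask(array(TRUE, c(4, 1, 1))))["mean"]), 2.5)
  set.seed(8)
  vol <- voxelVolume(array(rnorm(6 * 6 * 3), c(6, 6, 3)), c(1, 1, 3))
  msk <- voiMask(array(TRUE, c(6, 6, 3)))
  lev <- discretizeLevels(vol, msk, 8)
  expect_equal(unname(firstOrderFeatures(vol, msk, 8)["local_entropy_median"]),
               oracleLocalEntropyMedian(lev))
})

test_that("direction-merged 3D features are invariant to 90-degree rotation", {
  set.seed(13)
  lev <- array(sample.int(4, 125, replace = TRUE), c(5, 5, 5))
  attr(lev, "nLevels") <- 4L
  rot <- aperm(lev[, 5:1, ], c(2, 1, 3))     # 90 deg about z
  attr(rot, "nLevels") <- 4L
  expect_equal(glcmFeatures(computeGLCM(lev, mode = "3D")),
               glcmFeatures(computeGLCM(rot, mode = "3D")), tolerance = 1e-9)
  expect_equal(glrlFeatures(lev, mode = "3D"), glrlFeatures(rot, mode = "3D"),
               tolerance = 1e-9)
  expect_equal(ngtdmFeatures(lev, neighborhood = 3),
               ngtdmFeatures(rot, neighborhood = 3), tolerance = 1e-9)
})

test_that("feature extraction assembles trajectories and drops missing VOIs", {
  mkvoi <- function(id, months, seed) {
    set.seed(seed)
    ms <- lapply(months, function(m) {
      list(volume = voxelVolume(array(rnorm(6 * 6 * 4, 100, 10), c(6, 6, 4)),
                                c(1, 1, 3)),
           mask = voiMask(array(TRUE, c(6, 6, 4))))
    })
    names(ms) <- as.character(months)
    list(voi_id = id, patient_id = paste0("P", id), label = "ORN",
         months = ms)
  }
  cfg <- extractionConfig(resample = FALSE, modes = "3D",
                          nidNeighborhoods = 3L)
  tab <- extractFeatureTable(list(mkvoi("a", c(0, 2, 6), 1)), cfg)
  expect_equal(nrow(as.data.frame(tab)), 3L)
  expect_warning(
    tab2 <- extractFeatureTable(list(mkvoi("a", c(0, 2, 6), 1),
                                     mkvoi("b", c(0, 2), 2)), cfg,
                                months = c(0, 2, 6)),
    "missing month")
  expect_equal(voiIds(tab2), "a")
})
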