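test_that("default cohort reproduces the study geometry and pairing", {
  co <- generateTrajectoryCohort(cohortSpec(seed = 11L))
  d <- as.data.frame(co$table)
  info <- voiInfo(co$table)
  expect_equal(nrow(info), 43L)
  expect_equal(sum(info$label == "ORN"), 22L)
  expect_equal(sum(info$label == "Control"), 21L)
  expect_equal(length(unique(info$patient_id)), 21L)
  expect_equal(nrow(d), 43L * 3L)
  expect_equal(obsMonths(co$table), c(0, 2, 6))
  # one patient contributes two ORN lesions
  ornPerPatient <- table(info$patient_id[info$label == "ORN"])
  expect_equal(sort(unique(as.integer(ornPerPatient))), c(1L, 2L))
  # every Control VOI shares its patient with an ORN VOI
  ornPatients <- unique(info$patient_id[info$label == "ORN"])
  expect_true(all(info$patient_id[info$label == "Control"] %in% ornPatients))
})

test_that("cohort generation is bit-reproducible and seed-sensitive", {
  a <- generateTrajectoryCohort(cohortSpec(seed = 5L))
  b <- generateTrajectoryCohort(cohortSpec(seed = 5L))
  c3 <- generateTrajectoryCohort(cohortSpec(seed = 6L))
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_false(identical(as.data.frame(a$table), as.data.frame(c3$table)))
})

test_that("no-signal cohorts show no systematic group difference", {
  rates <- vapply(1:8, function(s) {
    co <- generateTrajectoryCohort(cohortSpec(
      nPatients = 40L, nOrnVois = 40L, nControlVois = 40L,
      signalMode = "none", seed = s))
    scr <- mannWhitneyScreen(co$table, month = 0)
    mean(scr$significant)
  }, numeric(1))
  expect_lt(mean(rates), 0.15)
})

test_that("shape-signal cohorts hide the signal from baseline and delta", {
  co <- generateTrajectoryCohort(cohortSpec(
    nPatients = 100L, nOrnVois = 100L, nControlVois = 100L,
    signalMode = "shape", effectSize = 1.5, noiseSd = 0.2, seed = 1L))
  tab <- co$table
  info <- voiInfo(tab)
  m0 <- radkinetics:::monthMatrix(tab, 0)
  m2 <- radkinetics:::monthMatrix(tab, 2)
  m6 <- radkinetics:::monthMatrix(tab, 6)
  lab <- info$label[match(rownames(m0), info$voi_id)]
  sepOf <- function(m) abs(radkinetics:::standardizedSeparation(
    rowMeans(m[, co$truth$signal_features, drop = FALSE]), lab))
  expect_lt(sepOf(m0), 0.15)        # baseline uninformative
  expect_lt(sepOf(m6 - m0), 0.15)   # net change uninformative
  expect_gt(sepOf(m2), 1.0)         # month-2 detour carries the signal
})

test_that("baseline-signal shifts propagate so deltas stay uninformative", {
  seps <- vapply(1:5, function(s) {
    co <- generateTrajectoryCohort(cohortSpec(
      nPatients = 100L, nOrnVois = 100L, nControlVois = 100L,
      signalMode = "baseline", effectSize = 1.5, noiseSd = 0.2, seed = s))
    info <- voiInfo(co$table)
    m0 <- radkinetics:::monthMatrix(co$table, 0)
    m6 <- radkinetics:::monthMatrix(co$table, 6)
    lab <- info$label[match(rownames(m0), info$voi_id)]
    c(base = radkinetics:::standardizedSeparation(rowMeans(m0), lab),
      delta = radkinetics:::standardizedSeparation(rowMeans(m6 - m0), lab))
  }, numeric(2))
  expect_gt(min(abs(seps["base", ])), 1.0)   # shift visible at month 0
  expect_lt(abs(mean(seps["delta", ])), 0.1) # zero expected delta separation
})

test_that("within-block Spearman correlation matches the specification", {
  co <- generateTrajectoryCohort(cohortSpec(
    nPatients = 250L, nOrnVois = 250L, nControlVois = 250L,
    signalMode = "none", seed = 4L))
  m0 <- radkinetics:::monthMatrix(co$table, 0)
  rho <- cor(m0, method = "spearman")
  within <- c(rho[1:4, 1:4][upper.tri(diag(4))],
              rho[5:8, 5:8][upper.tri(diag(4))])
  between <- rho[1:4, 9:12]
  expect_lt(abs(mean(within) - 0.4), 0.1)
  expect_lt(abs(mean(between)), 0.1)
})

test_that("unknown signal mode and bad specs are rejected", {
  expect_error(cohortSpec(signalMode = "wiggle"), "signalMode")
  expect_error(cohortSpec(obsMonths = c(2, 6)), "obsMonths")
  expect_error(cohortSpec(correlationBlocks = list(c(20, 0.4))), "exceed")
})

test_that("basis curve generator recovers its construction", {
  phi <- monthBasis2()
  # noiseless rank-1: every centered curve is a multiple of the eigenfunction
  g1 <- generateCurvesFromBasis(phi[, 1, drop = FALSE], 1, n = 50,
                                noiseSd = 0, seed = 2L, grid = 0:6)
  ratios <- sweep(g1$curves, 2, phi[, 1], `/`)
  expect_lt(max(apply(ratios, 1, function(r) diff(range(r)))), 1e-10)
  # score variances near the requested eigenvalues
  g2 <- generateCurvesFromBasis(phi, c(4, 1), n = 200, noiseSd = 0.1,
                                seed = 7L, grid = 0:6)
  v <- apply(g2$scores, 2, var)
  expect_lt(abs(v[1] - 4) / 4, 0.25)
  expect_lt(abs(v[2] - 1) / 1, 0.25)
  # non-orthonormal basis is rejected
  expect_error(generateCurvesFromBasis(cbind(phi[, 1], phi[, 1]), c(1, 1),
                                       n = 5, grid = 0:6), "orthonormal")
})

test_that("textured phantom has valid geometry and known texture", {
  ph <- generateTexturedPhantom(phantomSpec(seed = 3L))
  expect_false(any(ph$maskA@indicator & ph$maskB@indicator))
  ph2 <- generateTexturedPhantom(phantomSpec(seed = 3L))
  expect_identical(ph$volume@values, ph2$volume@values)
  # amplitude 0, no noise: region A constant, GLCM contrast exactly 0
  flat <- generateTexturedPhantom(phantomSpec(
    textureA = c(100, 0, 4), noiseSd = 0, seed = 1L))
  inA <- flat$volume@values[flat$maskA@indicator]
  expect_equal(max(inA) - min(inA), 0)
  lev <- discretizeLevels(flat$volume, flat$maskA, 8)
  P <- computeGLCM(lev, mode = "3D")
  expect_equal(unname(glcmFeatures(P)["contrast"]), 0)
  # oversized mask is rejected
  expect_error(generateTexturedPhantom(phantomSpec(maskRadiusMM = 50)),
               "inside the grid")
})

test_that("distinct textures are detected across phantom replicates", {
  featA <- numeric(20); featB <- numeric(20)
  for (s in 1:20) {
    ph <- generateTexturedPhantom(phantomSpec(
      textureA = c(100, 20, 4), textureB = c(100, 40, 8), seed = s))
    fA <- glcmFeatures(computeGLCM(
      discretizeLevels(ph$volume, ph$maskA, 16), mode = "3D"))
    fB <- glcmFeatures(computeGLCM(
      discretizeLevels(ph$volume, ph$maskB, 16), mode = "3D"))
    featA[s] <- fA["contrast"]; featB[s] <- fB["contrast"]
  }
  scr <- mannWhitneyScreen(rbind(matrix(featA, dimnames = list(NULL, "glcm_contrast")),
                                 matrix(featB)),
                           labels = rep(c("ORN", "Control"), each = 20))
  expect_lt(scr$p, 0.05)
})
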