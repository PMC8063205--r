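mkTable <- function(values, months = c(0, 2, 6)) {
  # one VOI, one feature
  trajectoryTable(data.frame(voi_id = "v1", patient_id = "p1", label = "ORN",
                             timepoint_month = months, f1 = values))
}

test_that("spline completion interpolates and reproduces lines exactly", {
  cs <- splineComplete(mkTable(c(0, 2, 6)), grid = 0:6)
  expect_equal(as.numeric(cs@curves[1, , 1]), as.numeric(0:6))
  # interpolation property on a bent trajectory
  cs2 <- splineComplete(mkTable(c(1, 3, 2)), grid = 0:6)
  expect_equal(as.numeric(cs2@curves[1, c(1, 3, 7), 1]), c(1, 3, 2))
  # month-1 value matches an independent tridiagonal natural-spline solve
  expect_equal(cs2@curves[1, 2, 1],
               oracleNaturalSpline(c(0, 2, 6), c(1, 3, 2), 1),
               tolerance = 1e-12)
  # no extrapolation
  expect_error(splineComplete(mkTable(c(1, 3, 2)), grid = 0:7), "extrapolate")
  # a VOI missing one of the observed months is an error at this stage
  partial <- trajectoryTable(data.frame(
    voi_id = c(rep("v1", 3), rep("v2", 2)), patient_id = "p1", label = "ORN",
    timepoint_month = c(0, 2, 6, 0, 2), f1 = c(1, 3, 2, 1, 2)))
  expect_error(splineComplete(partial, grid = 0:6), "missing observed months")
})

test_that("UFPCA recovers a rank-1 structure exactly", {
  phi <- monthBasis2()[, 2]
  set.seed(5)
  a <- rnorm(40)
  a <- a - mean(a)
  curves <- outer(a, phi)
  u <- ufpca(curves, grid = 0:6)
  expect_equal(sum(u@lambda > 1e-10), 1L)
  expect_equal(u@pve[1], 1)
  cosSim <- sum(u@weights * u@phi[, 1] * phi) /
    sqrt(sum(u@weights * phi^2))
  expect_equal(abs(cosSim), 1, tolerance = 1e-8)
})

test_that("UFPCA recovers known eigenstructure from generated curves", {
  phi <- monthBasis2()
  g <- generateCurvesFromBasis(phi, c(4, 1), n = 200, noiseSd = 0.1,
                               seed = 7L, grid = 0:6)
  u <- ufpca(g$curves, grid = 0:6)
  expect_lt(abs(u@lambda[1] / u@lambda[2] - 4) / 4, 0.25)
  for (m in 1:2) {
    cosSim <- sum(u@weights * u@phi[, m] * phi[, m])
    expect_gt(abs(cosSim), 0.95)
  }
  # orthonormality under the quadrature inner product
  gram <- t(u@phi) %*% (u@weights * u@phi)
  expect_equal(gram, diag(nrow(gram)), tolerance = 1e-8)
  # eigenvalues non-increasing and non-negative
  expect_true(all(diff(u@lambda) <= 1e-12))
  expect_true(all(u@lambda >= -1e-10))
})

test_that("UFPCA with equal weights coincides with plain PCA", {
  set.seed(6)
  curves <- matrix(rnorm(30 * 5), 30)
  u <- ufpca(curves, grid = 0:4, weights = rep(1, 5))
  pc <- eigen(cov(curves), symmetric = TRUE)
  expect_equal(u@lambda, pmax(pc$values, 0), tolerance = 1e-10)
  for (m in 1:5)
    expect_equal(abs(u@phi[, m]), abs(pc$vectors[, m]), tolerance = 1e-8)
})

test_that("MFPCA degenerates to UFPCA for a single feature", {
  phi <- monthBasis2()
  g <- generateCurvesFromBasis(phi, c(4, 1), n = 100, noiseSd = 0.05,
                               seed = 3L, grid = 0:6)
  u <- ufpca(g$curves, grid = 0:6, pve = 1)
  mf <- mfpca(list(f1 = u), pve = 1)
  k <- mf@retained
  expect_equal(mf@values[1:k], u@lambda[1:k], tolerance = 1e-8)
  for (m in 1:2)
    expect_equal(abs(mf@scores[, m]), abs(u@scores[, m]), tolerance = 1e-8)
})

test_that("duplicated features load equally on the leading component", {
  phi <- monthBasis2()
  g <- generateCurvesFromBasis(phi, c(4, 1), n = 80, noiseSd = 0,
                               seed = 8L, grid = 0:6)
  u1 <- ufpca(g$curves, grid = 0:6, pve = 0.99)
  u2 <- ufpca(g$curves, grid = 0:6, pve = 0.99)
  mf <- mfpca(list(a = u1, b = u2), pve = 1)
  # leading eigenvector: equal-magnitude loadings on the two feature blocks
  Mj <- u1@retained
  v <- mf@vectors[, 1]
  expect_equal(abs(v[1:Mj]), abs(v[(Mj + 1):(2 * Mj)]), tolerance = 1e-8)
  # PVE matches a direct eigendecomposition of the duplicated score matrix
  Xi <- cbind(componentScores(u1), componentScores(u2))
  ev <- eigen(crossprod(scale(Xi, scale = FALSE)) / (nrow(Xi) - 1),
              symmetric = TRUE)$values
  expect_equal(mf@pve[1], ev[1] / sum(ev), tolerance = 1e-10)
})

test_that("variance is conserved and the pipeline is deterministic", {
  co <- smallShapeCohort(n = 30L, seed = 2L)
  k1 <- trajectoryKinetics(co$table)
  k2 <- trajectoryKinetics(co$table)
  expect_identical(k1$mfpca@scores, k2$mfpca@scores)
  Xi <- do.call(cbind, lapply(k1$ufpca, componentScores))
  totVar <- sum(apply(scale(Xi, scale = FALSE), 2, var))
  expect_equal(sum(k1$mfpca@values), totVar, tolerance = 1e-8)
  # multivariate scores have zero mean; eigenvectors orthonormal
  expect_lt(max(abs(colMeans(k1$mfpca@scores))), 1e-8 * max(abs(Xi)))
  V <- k1$mfpca@vectors
  expect_equal(t(V) %*% V, diag(ncol(V)), tolerance = 1e-8)
})

test_that("reconstruction error is monotone in M and spectral at M = 1", {
  phi <- monthBasis2()
  g <- generateCurvesFromBasis(phi, c(4, 1), n = 200, noiseSd = 0,
                               seed = 7L, grid = 0:6)
  u <- ufpca(g$curves, grid = 0:6, pve = 1)
  mf <- mfpca(list(f1 = u), pve = 1)
  mseAt <- function(M) {
    rec <- reconstructCurves(mf, M)@curves[, , 1]
    mean((rec - g$curves)^2)
  }
  mses <- vapply(0:length(mf@values), mseAt, numeric(1))
  expect_true(all(diff(mses) <= 1e-12))
  # full rank is lossless (noiseless rank-2 input)
  expect_lt(mseAt(length(mf@values)), 1e-16)
  # M = 0 reconstructs the mean curves
  rec0 <- reconstructCurves(mf, 0)@curves[, , 1]
  expect_equal(rec0[1, ], colMeans(g$curves), tolerance = 1e-12)
  # relative reconstruction error at M = 1 ~ lambda2/(lambda1 + lambda2) =
  # 1/5, in the quadrature norm the truncation is optimal under
  w <- u@weights
  err1 <- reconstructCurves(mf, 1)@curves[, , 1] - g$curves
  relMse <- sum(t(err1^2) * w) / sum(t(scale(g$curves, scale = FALSE)^2) * w)
  expect_lt(abs(relMse - 0.2), 0.06)
})

test_that("multivariate scores recover a known two-feature structure", {
  phiA <- monthBasis2()
  phiB <- monthBasis2()[, 2:1]
  set.seed(10)
  S <- cbind(rnorm(200, sd = 2), rnorm(200, sd = 1))   # shared latent scores
  curvesA <- S %*% t(phiA) + matrix(rnorm(200 * 7, sd = 0.1), 200)
  curvesB <- S %*% t(phiB) + matrix(rnorm(200 * 7, sd = 0.1), 200)
  mf <- mfpca(list(a = ufpca(curvesA, grid = 0:6),
                   b = ufpca(curvesB, grid = 0:6)), pve = 0.9)
  for (m in 1:2)
    expect_gt(max(abs(cor(mf@scores[, m], S))), 0.9)
})
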