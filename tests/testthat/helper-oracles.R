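# Independent brute-force oracles, deliberately written as plain double
# loops so they share no code path with the package implementations.

oracleOffsets3D <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
      out[[length(out) + 1L]] <- c(dx, dy, dz)
  }
  out
}

oracleOffsets2D <- function() list(c(1, 0, 0), c(-1, 1, 0), c(0, 1, 0), c(1, 1, 0))

# Symmetric normalised GLCM by per-voxel pair enumeration.
oracleGLCM <- function(lev, L, offsets) {
  dims <- dim(lev)
  counts <- matrix(0, L, L)
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2])) for (x in seq_len(dims[1])) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    for (off in offsets) {
      x2 <- x + off[1]; y2 <- y + off[2]; z2 <- z + off[3]
      if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2] ||
          z2 < 1 || z2 > dims[3]) next
      b <- lev[x2, y2, z2]
      if (is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

# All six Haralick-family features by explicit double loops.
oracleGLCMFeatures <- function(P) {
  L <- nrow(P)
  px <- numeric(L); py <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:L) * px); muy <- sum((1:L) * py)
  sdx <- sqrt(sum(((1:L) - mux)^2 * px))
  sdy <- sqrt(sum(((1:L) - muy)^2 * py))
  contrast <- 0; dissim <- 0; corrNum <- 0; shade <- 0; idmn <- 0
  HXY <- 0; HXY1 <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    contrast <- contrast + p * (i - j)^2
    dissim <- dissim + p * abs(i - j)
    corrNum <- corrNum + p * (i - mux) * (j - muy)
    shade <- shade + p * (i + j - mux - muy)^3
    idmn <- idmn + p / (1 + (i - j)^2 / L^2)
    if (p > 0) HXY <- HXY - p * log2(p)
    if (p > 0 && px[i] * py[j] > 0) HXY1 <- HXY1 - p * log2(px[i] * py[j])
  }
  HX <- 0; HY <- 0
  for (i in 1:L) {
    if (px[i] > 0) HX <- HX - px[i] * log2(px[i])
    if (py[i] > 0) HY <- HY - py[i] * log2(py[i])
  }
  c(contrast = contrast,
    correlation = if (sdx * sdy > 0) corrNum / (sdx * sdy) else NA_real_,
    dissimilarity = dissim, cluster_shade = shade,
    inverse_difference_moment_normalized = idmn,
    information_measure_correlation_1 =
      if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else NA_real_)
}

# Run-length matrix by walking every line start, one voxel at a time.
oracleGLRL <- function(lev, L, directions) {
  dims <- dim(lev)
  maxLen <- max(dims)
  R <- matrix(0, L, maxLen)
  inGrid <- function(x, y, z) x >= 1 && x <= dims[1] && y >= 1 &&
    y <= dims[2] && z >= 1 && z <= dims[3]
  for (d in directions) {
    for (z in seq_len(dims[3])) for (y in seq_len(dims[2])) for (x in seq_len(dims[1])) {
      v <- lev[x, y, z]
      if (is.na(v)) next
      px <- x - d[1]; py <- y - d[2]; pz <- z - d[3]
      isStart <- !inGrid(px, py, pz) || is.na(lev[px, py, pz]) ||
        lev[px, py, pz] != v
      if (!isStart) next
      len <- 1
      cx <- x; cy <- y; cz <- z
      repeat {
        cx <- cx + d[1]; cy <- cy + d[2]; cz <- cz + d[3]
        if (!inGrid(cx, cy, cz) || is.na(lev[cx, cy, cz]) ||
            lev[cx, cy, cz] != v) break
        len <- len + 1
      }
      R[v, len] <- R[v, len] + 1
    }
  }
  R
}

oracleGLRLFeatures <- function(lev, L, directions) {
  R <- oracleGLRL(lev, L, directions)
  Nr <- sum(R)
  Np <- sum(!is.na(lev))
  sre <- 0; lre <- 0
  for (i in 1:nrow(R)) for (l in 1:ncol(R)) {
    sre <- sre + R[i, l] / l^2
    lre <- lre + R[i, l] * l^2
  }
  c(short_run_emphasis = sre / Nr, long_run_emphasis = lre / Nr,
    gray_level_nonuniformity = sum(rowSums(R)^2) / Nr,
    run_length_nonuniformity = sum(colSums(R)^2) / Nr,
    run_percentage = Nr / (Np * length(directions)))
}

# NGTDM features via a per-voxel window loop.
oracleNGTDM <- function(lev, L, k, mode = "3D") {
  dims <- dim(lev)
  half <- (k - 1) / 2
  n <- numeric(L); s <- numeric(L); N <- 0
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2])) for (x in seq_len(dims[1])) {
    v <- lev[x, y, z]
    if (is.na(v)) next
    vals <- c()
    complete <- TRUE
    dzr <- if (mode == "3D") (-half):half else 0
    for (dz in dzr) for (dy in (-half):half) for (dx in (-half):half) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > dims[1] || y2 < 1 || y2 > dims[2] ||
          z2 < 1 || z2 > dims[3] || is.na(lev[x2, y2, z2])) {
        complete <- FALSE
      } else vals <- c(vals, lev[x2, y2, z2])
    }
    if (!complete) next
    n[v] <- n[v] + 1
    s[v] <- s[v] + abs(v - mean(vals))
    N <- N + 1
  }
  p <- n / N
  present <- which(p > 0)
  Ng <- length(present)
  ps <- sum(p * s)
  contrastV <- 0; busyDen <- 0; complexityV <- 0; strengthNum <- 0
  if (Ng >= 2) {
    for (i in present) for (j in present) {
      contrastV <- contrastV + p[i] * p[j] * (i - j)^2
      complexityV <- complexityV +
        abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      busyDen <- busyDen + abs(i * p[i] - j * p[j])
      strengthNum <- strengthNum + (n[i] + n[j]) * (i - j)^2
    }
    contrastV <- contrastV / (Ng * (Ng - 1)) * sum(s) / N
    complexityV <- complexityV / N
  }
  c(coarseness = if (ps > 0) 1 / ps else NA_real_,
    contrast = contrastV,
    busyness = if (busyDen > 0) ps / busyDen else 0,
    complexity = complexityV,
    texture_strength = if (sum(s) > 0) strengthNum / sum(s) else 0)
}

# Median local entropy with an explicit per-voxel 3x3x1 window loop.
oracleLocalEntropyMedian <- function(lev) {
  dims <- dim(lev)
  ents <- c()
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2])) for (x in seq_len(dims[1])) {
    if (is.na(lev[x, y, z])) next
    win <- c()
    for (dy in -1:1) for (dx in -1:1) {
      x2 <- x + dx; y2 <- y + dy
      if (x2 >= 1 && x2 <= dims[1] && y2 >= 1 && y2 <= dims[2] &&
          !is.na(lev[x2, y2, z]))
        win <- c(win, lev[x2, y2, z])
    }
    tab <- table(win)
    pr <- tab / sum(tab)
    ents <- c(ents, -sum(pr * log2(pr)))
  }
  median(ents)
}

# Natural cubic spline through (x, y) evaluated at xout, via the standard
# tridiagonal second-derivative solve (independent of stats::spline).
oracleNaturalSpline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  # solve for second derivatives M at knots; natural: M1 = Mn = 0
  M <- numeric(n)
  if (n > 2) {
    A <- matrix(0, n - 2, n - 2)
    b <- numeric(n - 2)
    for (i in 2:(n - 1)) {
      r <- i - 1
      if (r > 1) A[r, r - 1] <- h[i - 1] / 6
      A[r, r] <- (h[i - 1] + h[i]) / 3
      if (r < n - 2) A[r, r + 1] <- h[i] / 6
      b[r] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
    }
    M[2:(n - 1)] <- solve(A, b)
  }
  vapply(xout, function(t) {
    i <- max(1, min(n - 1, findInterval(t, x)))
    hi <- h[i]
    a <- (x[i + 1] - t) / hi
    bq <- (t - x[i]) / hi
    a * y[i] + bq * y[i + 1] +
      ((a^3 - a) * M[i] + (bq^3 - bq) * M[i + 1]) * hi^2 / 6
  }, numeric(1))
}

# AUC by exhaustive pair enumeration (ORN detected by LOW Control prob).
oracleAUC <- function(prob, labels) {
  po <- prob[labels == "ORN"]; pc <- prob[labels == "Control"]
  tot <- 0
  for (a in po) for (b in pc)
    tot <- tot + if (a < b) 1 else if (a == b) 0.5 else 0
  tot / (length(po) * length(pc))
}

# Trilinear value at one probe voxel of the output grid, by explicit
# corner-weight arithmetic.
oracleTrilinearAt <- function(V, sIn, sOut, idx) {
  dims <- dim(V)
  pos <- numeric(3)
  for (ax in 1:3) {
    center <- (idx[ax] - 0.5) * sOut[ax]
    p <- center / sIn[ax] + 0.5
    pos[ax] <- min(max(p, 1), dims[ax])
  }
  i0 <- pmin(floor(pos), dims - 1)
  f <- pos - i0
  val <- 0
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    w <- (if (a) f[1] else 1 - f[1]) * (if (b) f[2] else 1 - f[2]) *
      (if (c) f[3] else 1 - f[3])
    val <- val + w * V[i0[1] + a, i0[2] + b, i0[3] + c]
  }
  val
}
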