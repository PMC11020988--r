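# Independent brute-force oracles. These deliberately use different
# primitives from the package implementation (loops, cut(), exhaustive
# enumeration) so agreement is evidence, not tautology.

# all ten first-order features from raw masked values, by direct arithmetic
oracleFeatures <- function(vals, voxelVolMm3, nBins = 64) {
  n <- length(vals)
  mu <- sum(vals) / n
  sdPop <- sqrt(sum((vals - mu)^2) / n)
  mtv <- n * voxelVolMm3 / 1000
  mn <- min(vals); mx <- max(vals)
  if (mx > mn) {
    br <- seq(mn, mx, length.out = nBins + 1)
    # half-open bins, last closed: shift right edges except the last
    idx <- as.integer(cut(vals, breaks = br, include.lowest = TRUE,
                          right = FALSE))
    idx[vals == mx] <- nBins
    p <- as.numeric(table(factor(idx, levels = 1:nBins))) / n
    centers <- (br[-1] + br[-(nBins + 1)]) / 2
  } else {
    p <- c(1, rep(0, nBins - 1))
    centers <- rep(mn, nBins)
  }
  ent <- 0
  for (pi in p) if (pi > 0) ent <- ent - pi * log(pi) / log(2)
  unif <- sum(p * p)
  m <- sum(p * centers)
  m2 <- sum(p * (centers - m)^2)
  if (m2 > 1e-300) {
    skew <- sum(p * (centers - m)^3) / m2^1.5
    kurt <- sum(p * (centers - m)^4) / m2^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  c(max_suv = mx, mean_suv = mu, median_suv = as.numeric(stats::median(vals)),
    mtv_cm3 = mtv, tlg_g = mtv * mu, cov_suv = sdPop / mu,
    kurtosis = kurt, skewness = skew, entropy = ent, uniformity = unif)
}

# seed-connected component by plain R breadth-first search
oracleComponent <- function(above, seedIdx, connectivity = 26) {
  d <- dim(above)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  man <- rowSums(abs(offs))
  keep <- man > 0 & man <= switch(as.character(connectivity),
                                  "6" = 1, "18" = 2, "26" = 3)
  offs <- offs[keep, , drop = FALSE]
  out <- array(FALSE, dim = d)
  if (!above[seedIdx[1], seedIdx[2], seedIdx[3]]) return(out)
  queue <- list(seedIdx)
  out[seedIdx[1], seedIdx[2], seedIdx[3]] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (r in seq_len(nrow(offs))) {
      w <- v + offs[r, ]
      if (any(w < 1) || any(w > d)) next
      if (above[w[1], w[2], w[3]] && !out[w[1], w[2], w[3]]) {
        out[w[1], w[2], w[3]] <- TRUE
        queue[[length(queue) + 1]] <- w
      }
    }
  }
  out
}

# background shell by exhaustive distance to every mask voxel
oracleShell <- function(mask, spacing, inner, outer) {
  d <- dim(mask)
  idxMask <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, dim = d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (mask[x, y, z]) next
    dd <- sqrt(min(((x - idxMask[, 1]) * spacing[1])^2 +
                   ((y - idxMask[, 2]) * spacing[2])^2 +
                   ((z - idxMask[, 3]) * spacing[3])^2))
    if (dd >= inner && dd <= outer) out[x, y, z] <- TRUE
  }
  out
}

# the whole adaptive-threshold iteration, re-implemented without the package
oracleDelineate <- function(vol, spacing, seedIdx, weight = 0.3,
                            coreFrac = 0.7, inner = 8, outer = 16,
                            maxIter = 20, connectivity = 26,
                            localMaxRadius = 12) {
  d <- dim(vol)
  coords <- lapply(1:3, function(a) (seq_len(d[a]) - 0.5) * spacing[a])
  seedMM <- sapply(1:3, function(a) coords[[a]][seedIdx[a]])
  ball <- array(FALSE, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    dd <- sqrt(sum((c(coords[[1]][x], coords[[2]][y], coords[[3]][z]) - seedMM)^2))
    if (dd <= localMaxRadius) ball[x, y, z] <- TRUE
  }
  localMax <- max(vol[ball])
  hot <- which(ball & vol == localMax, arr.ind = TRUE)[1, ]
  thr <- 0.5 * localMax
  pick <- function(above) {
    s <- if (above[seedIdx[1], seedIdx[2], seedIdx[3]]) seedIdx else hot
    oracleComponent(above, s, connectivity)
  }
  est <- pick(vol > thr)
  for (it in seq_len(maxIter)) {
    shell <- oracleShell(est, spacing, inner, outer)
    bg <- mean(vol[shell])
    core <- vol[est][vol[est] > coreFrac * max(vol[est])]
    thr <- weight * mean(core) + bg
    nxt <- pick(vol > thr)
    if (identical(nxt, est)) break
    est <- nxt
  }
  list(mask = est, threshold = thr, iterations = it)
}

# Youden cutoff by O(n^2) confusion-matrix enumeration
oracleRocCutoff <- function(x, y) {
  u <- sort(unique(x))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- list(J = -Inf)
  for (cc in cuts) for (dir in c(">=", "<=")) {
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_along(x)) {
      pos <- if (dir == ">=") x[i] >= cc else x[i] <= cc
      if (pos && y[i] == 1) tp <- tp + 1
      if (pos && y[i] == 0) fp <- fp + 1
      if (!pos && y[i] == 1) fn <- fn + 1
      if (!pos && y[i] == 0) tn <- tn + 1
    }
    J <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (J > best$J + 1e-12) best <- list(cutoff = cc, J = J, direction = dir)
  }
  best
}

# Kruskal-Wallis H by the rank formula (valid without ties)
oracleKWNoTies <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  12 / (N * (N + 1)) * sum(lengths(groups) * rbar^2) - 3 * (N + 1)
}

# Dunn z for one pair by the direct formula
oracleDunnZ <- function(groups, i, j) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  ties <- table(r)
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, idx, mean)
  ni <- lengths(groups)
  (rbar[[i]] - rbar[[j]]) / sqrt(sigma2 * (1 / ni[i] + 1 / ni[j]))
}

# Cox partial log-likelihood for a single covariate, no ties
oraclePartialLogLik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# small random test volume + mask
randomMaskedVolume <- function(nx = 6, ny = 6, nz = 5, spacing = c(4.07, 4.07, 2.5)) {
  vals <- array(stats::runif(nx * ny * nz, 0.5, 12), dim = c(nx, ny, nz))
  m <- array(stats::runif(nx * ny * nz) < 0.4, dim = c(nx, ny, nz))
  if (!any(m)) m[1, 1, 1] <- TRUE
  list(volume = petromics::SUVVolume(vals, spacing = spacing),
       mask = petromics::VOIMask(m, spacing = spacing))
}

# number of mask voxels with a 6-connected neighbour outside the mask
surfaceVoxelCount <- function(m) {
  d <- dim(m)
  surf <- array(FALSE, d)
  pad <- function(a, shift, axis) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    src[[axis]] <- seq_len(d[axis] - 1) + (shift > 0)
    dst[[axis]] <- seq_len(d[axis] - 1) + (shift < 0)
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  inside <- m
  for (axis in 1:3) for (s in c(-1, 1))
    inside <- inside & pad(m, s, axis)
  sum(m & !inside)
}
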