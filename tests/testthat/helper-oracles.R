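# Independent brute-force oracles used to pin down the expected values of
# the equation-level operations. These are deliberately naive (loops,
# exhaustive scans) and never share code with the package internals.

# Three-factor tubularity computed directly from the printed formula.
oracleFrangi <- function(l1, l2, l3, alpha, beta, c, frobenius = FALSE) {
  if (l2 > 0 || l3 > 0) return(0)
  if (l3 == 0) return(0)
  ra <- abs(l2) / abs(l3)
  rb <- abs(l1) / sqrt(abs(l2 * l3))
  s <- if (frobenius) sqrt(l1^2 + l2^2 + l3^2) else sqrt(l1^2 + l2^2)
  (1 - exp(-ra^2 / (2 * alpha^2))) * exp(-rb^2 / (2 * beta^2)) *
    (1 - exp(-s^2 / (2 * c^2)))
}

# Offspring counts of systematic resampling for one explicit offset u.
oracleSystematic <- function(w, n, u) {
  cw <- cumsum(w)
  counts <- integer(length(w))
  for (k in 0:(n - 1)) {
    pos <- u + k / n
    j <- which(pos <= cw)[1]
    counts[j] <- counts[j] + 1L
  }
  counts
}

# Synchronous flat-kernel mean-shift, kernel fixed at the initial radius.
oracleMeanShift <- function(pos, r, cc, iterations, aspect = c(1, 1, 1)) {
  n <- nrow(pos)
  r0 <- r
  for (it in seq_len(iterations)) {
    newPos <- pos
    newR <- r
    newC <- cc
    for (i in seq_len(n)) {
      d <- sqrt(colSums((t(pos) - pos[i, ])^2 * aspect^2))
      nb <- which(d <= r0[i])
      newPos[i, ] <- colMeans(pos[nb, , drop = FALSE])
      newR[i] <- mean(r[nb])
      newC[i] <- mean(cc[nb])
    }
    pos <- newPos
    r <- newR
    cc <- newC
  }
  list(pos = pos, r = r, c = cc)
}

# Greedy grouping: repeatedly seed a group at the ungrouped node with the
# highest correlation (ties to the lower index) and claim every ungrouped
# node within rg of it.
oracleGroup <- function(pos, cc, rg, aspect = c(1, 1, 1)) {
  n <- nrow(pos)
  grp <- integer(n)
  g <- 0L
  while (any(grp == 0L)) {
    open <- which(grp == 0L)
    seedI <- open[which.max(cc[open])]
    g <- g + 1L
    d <- sqrt(colSums((t(pos) - pos[seedI, ])^2 * aspect^2))
    grp[grp == 0L & d <= rg] <- g
  }
  grp
}

# Exhaustive Kapur threshold scan with ties toward the lower index.
oracleMaxEntropy <- function(h) {
  p <- h / sum(h)
  best <- -Inf
  bestT <- NA
  for (t in 0:254) {
    p0 <- sum(p[1:(t + 1)])
    p1 <- 1 - p0
    if (p0 <= 0 || p1 <= 0) next
    lo <- p[1:(t + 1)] / p0
    hi <- p[(t + 2):256] / p1
    hval <- -sum(lo[lo > 0] * log(lo[lo > 0])) -
      sum(hi[hi > 0] * log(hi[hi > 0]))
    if (hval > best + 1e-12) {
      best <- hval
      bestT <- t
    }
  }
  bestT
}

# Naive cubic minimum filter with per-axis half-widths (replicate border).
oracleMinFilter <- function(vol, hw, hwz) {
  dims <- dim(vol)
  out <- vol
  idx <- function(i, n) pmin(pmax(i, 1), n)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    xs <- idx((x - hw):(x + hw), dims[1])
    ys <- idx((y - hw):(y + hw), dims[2])
    zs <- idx((z - hwz):(z + hwz), dims[3])
    out[x, y, z] <- min(vol[xs, ys, zs])
  }
  out
}
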