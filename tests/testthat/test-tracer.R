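test_that("transition sampling reproduces its closed-form statistics", {
  set.seed(101)
  n <- 1e5
  p <- matrix(0, n, 3)
  v <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  sigma <- rep(2, n)
  params <- tracerParams()
  tr <- sampleTransition(p, v, sigma, params)

  # step lengths: truncated Gaussian, mean d (symmetric truncation at
  # mean +- 3 sd), hard cap at 2d
  step <- sqrt(rowSums(tr$p^2))
  expect_lt(abs(mean(step) - 3) / 3, 0.01)
  expect_lte(max(step), 6 + 1e-9)
  expect_gt(min(step), 0)

  # directions: von Mises-Fisher mean resultant length coth(k) - 1/k
  rho <- sqrt(sum(colMeans(tr$v)^2))
  expect_lt(abs(rho - (1 / tanh(3) - 1 / 3)) / (1 / tanh(3) - 1 / 3), 0.02)

  # scale moves truncated to 3 zeta and the lower clamp
  expect_lte(max(abs(tr$sigma - 2)), 3 + 1e-9)
  expect_gte(min(tr$sigma), params$sigmaMin)

  # the stored direction is the normalized displacement
  expect_equal(tr$p / step, tr$v, tolerance = 1e-12)
})

test_that("high concentration collapses the direction prior", {
  set.seed(7)
  axis <- c(1, 2, 2) / 3
  v <- matrix(rep(axis, each = 500), 500, 3)
  p <- matrix(0, 500, 3)
  tr <- sampleTransition(p, v, rep(2, 500),
                         tracerParams(kappa = 5000))
  expect_gt(min(tr$v %*% axis), 0.99)
})

test_that("template correlation is exact on the template itself", {
  sigma <- 2
  dims <- c(19, 19, 9)
  ctr <- (dims - 1) / 2
  g <- array(0, dims)
  for (x in 1:dims[1]) for (y in 1:dims[2])
    g[x, y, ] <- exp(-((x - 1 - ctr[1])^2 + (y - 1 - ctr[2])^2) /
                       (2 * sigma^2))
  vol <- IntensityVolume(g, c(1, 1, 1))
  state <- list(p = ctr, v = c(0, 0, 1))
  expect_equal(zncc(vol, ctr, c(0, 0, 1), sigma), 1, tolerance = 1e-9)
  # inverse correlation and affine invariance
  inv <- IntensityVolume(-g, c(1, 1, 1))
  expect_equal(zncc(inv, ctr, c(0, 0, 1), sigma), -1, tolerance = 1e-9)
  aff <- IntensityVolume(5 * g + 100, c(1, 1, 1))
  expect_equal(zncc(aff, ctr, c(0, 0, 1), sigma), 1, tolerance = 1e-9)
  # constant patch: zero correlation, no NaN
  flat <- IntensityVolume(array(9, dims), c(1, 1, 1))
  expect_equal(zncc(flat, ctr, c(0, 0, 1), sigma), 0)
})

test_that("weight updates follow prior x transition x likelihood", {
  params <- tracerParams(K = 20)
  # identical particles stay uniform
  w <- updateWeights(rep(0.25, 4), rep(1.3, 4), rep(0.7, 4), params)
  expect_equal(w, rep(0.25, 4))
  # correlation 1 vs 0 at K = 20: weight ratio e^20
  w2 <- updateWeights(c(0.5, 0.5), c(1, 1), c(1, 0), params)
  expect_equal(w2[1] / w2[2], exp(20), tolerance = 1e-9)
  # K = 0 flattens the likelihood
  w3 <- updateWeights(c(0.5, 0.5), c(2, 1), c(1, 0), tracerParams(K = 0))
  expect_equal(w3, c(2 / 3, 1 / 3))
  expect_equal(sum(w2), 1)
  # total underflow resets to uniform with a warning
  expect_warning(w4 <- updateWeights(c(0.5, 0.5), c(0, 0), c(0, 0), params),
                 "degenerate")
  expect_equal(w4, c(0.5, 0.5))
})

test_that("effective sample size spans [1, N]", {
  expect_equal(effectiveSampleSize(rep(1 / 20, 20)), 20)
  expect_equal(effectiveSampleSize(c(1, rep(0, 9))), 1)
  expect_equal(effectiveSampleSize(c(0.5, 0.5, rep(0, 8))), 2)
})

test_that("systematic resampling matches enumeration over all offsets", {
  # (0.75, 0.25) with N = 4: always 3 + 1 offspring
  w <- c(0.75, 0.25)
  for (u in seq(0.001, 0.249, by = 0.016)) {
    idx <- systematicResample(w, n = 4, u = u)
    expect_equal(tabulate(idx, 2), oracleSystematic(w, 4, u))
    expect_equal(tabulate(idx, 2), c(3L, 1L))
  }
  # uniform weights reproduce every particle once
  expect_equal(sort(systematicResample(rep(0.25, 4))), 1:4)
  # a degenerate weight takes everything
  expect_equal(systematicResample(c(0, 1, 0, 0)), rep(2L, 4))
  # offspring counts stay within floor/ceil of N w
  set.seed(50)
  for (k in 1:50) {
    w <- runif(8)
    w <- w / sum(w)
    cnt <- tabulate(systematicResample(w), 8)
    expect_true(all(cnt >= floor(8 * w) & cnt <= ceiling(8 * w)))
  }
})

test_that("systematic resampling is unbiased", {
  set.seed(60)
  w <- c(0.5, 0.3, 0.15, 0.05)
  reps <- 1e4
  tot <- numeric(4)
  for (i in seq_len(reps)) tot <- tot + tabulate(systematicResample(w), 4)
  freq <- tot / (4 * reps)
  se <- sqrt(w * (1 - w) / (4 * reps))
  expect_true(all(abs(freq - w) <= 3 * pmax(se, 1e-4)))
})

test_that("the state estimate is the weighted centroid", {
  p <- rbind(c(0, 0, 0), c(2, 0, 0))
  v <- rbind(c(1, 0, 0), c(1, 0, 0))
  est <- estimateState(p, v, c(2, 4), c(0.5, 0.5), c(0.8, 0.6))
  expect_equal(est$p, c(1, 0, 0))
  expect_equal(est$sigma, 3)
  expect_equal(est$meanCorr, 0.7)
  est2 <- estimateState(p, v, c(2, 4), c(0.9, 0.1), c(1, 1))
  expect_equal(est2$sigma, 2.2)
  # single particle returns its own state
  est3 <- estimateState(p[1, , drop = FALSE], v[1, , drop = FALSE],
                        2, 1, 0.9)
  expect_equal(est3$p, c(0, 0, 0))
  expect_equal(est3$sigma, 2)
  # degenerate direction spread falls back to the previous direction
  vv <- rbind(c(1, 0, 0), c(-1, 0, 0))
  est4 <- estimateState(p, vv, c(2, 2), c(0.5, 0.5), c(1, 1),
                        prevV = c(0, 1, 0))
  expect_equal(est4$v, c(0, 1, 0))
})

test_that("traces follow a clean cylinder to the volume face", {
  shape <- c(128, 30, 30)
  cyl <- cylinderTree(shape, radius = 3)
  vol <- noiseFreeVolume(cyl, shape)
  seed <- data.frame(x = 64, y = 14.5, z = 14.5, vx = 1, vy = 0, vz = 0,
                     sigma = 3)
  params <- tracerParams(sigmaMax = 9)
  set.seed(9)
  plus <- traceBranch(seed, +1, vol, NULL, params)
  minus <- traceBranch(seed, -1, vol, NULL, params)
  nodes <- rbind(plus, minus)
  expect_gt(nrow(nodes), 20)
  rmse <- sqrt(mean((nodes$y - 14.5)^2 + (nodes$z - 14.5)^2))
  expect_lt(rmse, 1)
  span <- max(nodes$x) - min(nodes$x)
  expect_gte(span, 0.9 * shape[1])
})

test_that("estimated radius tracks the true radius across cylinders", {
  set.seed(13)
  sig <- vapply(c(1.5, 2, 3, 4), function(r) {
    shape <- c(96, 32, 32)
    vol <- noiseFreeVolume(cylinderTree(shape, r), shape)
    seed <- data.frame(x = 48, y = 15.5, z = 15.5, vx = 1, vy = 0, vz = 0,
                       sigma = 2)
    tr <- traceBranch(seed, +1, vol, NULL, tracerParams(sigmaMax = 9))
    mean(tr$r)
  }, 1.0)
  expect_gt(cor(sig, c(1.5, 2, 3, 4)), 0)
})

test_that("background noise terminates traces immediately", {
  set.seed(19)
  noise <- IntensityVolume(array(rpois(50 * 50 * 20, 10), c(50, 50, 20)),
                           c(1, 1, 1))
  lens <- vapply(1:100, function(i) {
    seed <- data.frame(x = runif(1, 10, 39), y = runif(1, 10, 39),
                       z = runif(1, 6, 13), vx = 1, vy = 0, vz = 0,
                       sigma = 2)
    nrow(traceBranch(seed, +1, noise, NULL, tracerParams()))
  }, 1L)
  expect_lte(max(lens), 2)

  # L = 0 returns an empty trace
  seed <- data.frame(x = 25, y = 25, z = 10, vx = 1, vy = 0, vz = 0,
                     sigma = 2)
  expect_equal(nrow(traceBranch(seed, +1, noise, NULL,
                                tracerParams(L = 0))), 0)
})

test_that("tracing all seeds respects the node density limit", {
  shape <- c(80, 24, 24)
  vol <- noiseFreeVolume(cylinderTree(shape, 2.5), shape)
  seeds <- extractSeeds(vol, seedParams())
  # replicate seeds to force heavy over-tracing pressure
  seeds <- do.call(rbind, rep(list(seeds), 10))
  set.seed(23)
  limited <- traceAll(seeds, vol, tracerParams(deltaN = 4, n = 9))
  set.seed(23)
  unlimited <- traceAll(seeds, vol, tracerParams(deltaN = 1e9, n = 9))
  nLim <- sum(vapply(limited$traces, nrow, 1L))
  nUnl <- sum(vapply(unlimited$traces, nrow, 1L))
  expect_lte(nLim, nUnl)
  # post-hoc audit: the density check runs against a node's own
  # neighborhood before it is appended, so no single voxel can collect
  # more than deltaN + 1 nodes
  expect_lte(max(limited$density$counts), 4 + 1)

  # zero seeds produce an empty collection
  none <- traceAll(seeds[0, ], vol, tracerParams())
  expect_equal(length(none$traces), 0)
})

test_that("a fixed RNG seed makes tracing reproducible", {
  vol <- simulateY(snr = 5, seed = 3)
  seeds <- extractSeeds(vol, seedParams())
  set.seed(71)
  a <- traceAll(seeds, vol, tracerParams())
  set.seed(71)
  b <- traceAll(seeds, vol, tracerParams())
  expect_identical(a$traces, b$traces)
})
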