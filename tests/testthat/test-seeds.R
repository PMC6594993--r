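test_that("Hessian eigen-analysis identifies tubes and flat fields", {
  flat <- IntensityVolume(array(42, c(12, 12, 12)), c(1, 1, 1))
  h <- hessianEigen(flat, 2)
  expect_true(all(abs(h$l1) < 1e-9))
  expect_true(all(abs(h$l3) < 1e-9))

  # bright tube along z: l1 ~ 0, l2 ~ l3 < 0, axis ~ z
  cyl <- SwcTree(data.frame(id = 1:2, type = 3L, x = 15, y = 15,
                            z = c(0, 29), radius = 3,
                            parent = c(-1L, 1L)), c(1, 1, 1))
  vol <- noiseFreeVolume(cyl, c(31, 31, 30))
  h <- hessianEigen(vol, 3)
  i <- c(16, 16, 15)
  expect_lt(abs(h$l1[i[1], i[2], i[3]]),
            0.2 * abs(h$l2[i[1], i[2], i[3]]))
  expect_lt(h$l2[i[1], i[2], i[3]], 0)
  expect_lt(h$l3[i[1], i[2], i[3]], 0)
  expect_gt(abs(h$vz[i[1], i[2], i[3]]), 0.99)

  expect_error(hessianEigen(flat, 0.3), "0.5")
})

test_that("tubularity matches the closed-form factors", {
  # worked example: l1 = 0, l2 = l3 = -10, alpha = beta = 0.5, c = 10
  expect_equal(frangiTubularity(0, -10, -10, 0.5, 0.5, c = 10),
               (1 - exp(-2)) * (1 - exp(-0.5)), tolerance = 1e-12)
  # brightness violations and null structure
  expect_equal(frangiTubularity(0.5, 1, -2, 0.5, 0.5, c = 1), 0)
  expect_equal(frangiTubularity(0, -1, 2, 0.5, 0.5, c = 1), 0)
  expect_equal(frangiTubularity(0, 0, 0, 0.5, 0.5, c = 1), 0)

  # random eigenvalue triples against the independent oracle
  set.seed(12)
  for (k in 1:200) {
    l <- sort(rnorm(3, 0, 5), decreasing = FALSE)
    l <- l[order(abs(l))]
    cc <- runif(1, 0.5, 10)
    expect_equal(frangiTubularity(l[1], l[2], l[3], 0.5, 0.5, cc),
                 oracleFrangi(l[1], l[2], l[3], 0.5, 0.5, cc),
                 tolerance = 1e-12)
    expect_equal(
      frangiTubularity(l[1], l[2], l[3], 0.5, 0.5, cc, frobenius = TRUE),
      oracleFrangi(l[1], l[2], l[3], 0.5, 0.5, cc, frobenius = TRUE),
      tolerance = 1e-12)
  }
})

test_that("multiscale tubularity takes the per-voxel max over scales", {
  cyl <- cylinderTree(c(60, 24, 24), radius = 3)
  vol <- noiseFreeVolume(cyl, c(60, 24, 24))
  single <- multiscaleTubularity(vol, seedParams(scales = 2))
  multi <- multiscaleTubularity(vol, seedParams(scales = c(2, 4, 6)))
  expect_true(all(multi$value >= single$value - 1e-12))
  expect_true(all(multi$value >= 0 & multi$value <= 1))
  # the single-scale map is one plain tubularity pass
  h <- hessianEigen(vol, 2)
  smeas <- sqrt(h$l1^2 + h$l2^2)
  u <- frangiTubularity(h$l1, h$l2, h$l3, 0.5, 0.5, 0.5 * max(smeas))
  expect_equal(single$value, array(u, dim(u)), tolerance = 1e-12)
})

test_that("noise-tolerant maxima follow the flood semantics", {
  # two ridges separated by a deep valley: both kept
  g <- array(0, c(30, 7, 7))
  g[8, 4, 4] <- 200
  g[22, 4, 4] <- 100
  g[15, 4, 4] <- 50
  # connect along x so the flood can travel
  for (x in 9:14) g[x, 4, 4] <- 50
  for (x in 16:21) g[x, 4, 4] <- 50
  m <- findMaxima3d(g, tau = 10)
  expect_equal(nrow(m), 2)
  expect_setequal(m[, 1], c(7, 21))  # 0-based positions

  # shallow valley at 95: the lower peak is swallowed
  g2 <- array(0, c(30, 7, 7))
  g2[8, 4, 4] <- 200
  g2[22, 4, 4] <- 100
  for (x in 9:21) g2[x, 4, 4] <- 95
  m2 <- findMaxima3d(g2, tau = 10)
  expect_equal(nrow(m2), 1)
  expect_equal(m2[1, ], c(7L, 3L, 3L))

  # constant grids have no maxima
  expect_equal(nrow(findMaxima3d(array(5, c(6, 6, 6)), 10)), 0)
})

test_that("maxima count is non-increasing in the tolerance", {
  set.seed(5)
  g <- array(runif(20 * 20 * 10, 0, 255), c(20, 20, 10))
  counts <- vapply(c(0, 5, 10, 20, 40), function(tau)
    nrow(findMaxima3d(g, tau)), 1L)
  expect_true(all(diff(counts) <= 0))
})

test_that("cylindrical non-maximum suppression enforces its geometry", {
  map <- list(value = array(0, c(40, 20, 20)))
  mk <- function(x, y, z, v, sigma = 2) {
    map$value[x + 1, y + 1, z + 1] <<- v
    data.frame(x = x, y = y, z = z, vx = 1, vy = 0, vz = 0,
               sigma = sigma, tubularity = v)
  }
  # isolated candidate survives
  s1 <- mk(5, 10, 10, 0.9)
  expect_equal(nrow(cylindricalNms(s1, map)), 1)

  # two candidates on one centerline, 1 voxel apart: only the higher kept
  # (axial distance 1 <= sigma/2 is false for sigma 2... use lateral)
  map$value[] <- 0
  a <- mk(20, 10, 10, 0.9)
  b <- mk(20, 11, 10, 0.8)  # lateral offset 1 < 3 sigma
  both <- rbind(a, b)
  kept <- cylindricalNms(both, map)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$tubularity, 0.9)

  # parallel branches 10 voxels apart with sigma 2: radius 6 cylinders
  # do not reach each other, both kept
  map$value[] <- 0
  c1 <- mk(20, 4, 10, 0.9)
  c2 <- mk(20, 14, 10, 0.8)
  expect_equal(nrow(cylindricalNms(rbind(c1, c2), map)), 2)
})

test_that("template correlation filtering separates tube from noise", {
  shape <- c(60, 24, 24)
  cyl <- cylinderTree(shape, radius = 2)
  clean <- noiseFreeVolume(cyl, shape)
  onAxis <- data.frame(x = 30, y = 11.5, z = 11.5, vx = 1, vy = 0, vz = 0,
                       sigma = 2, tubularity = 1)
  kept <- filterSeeds(onAxis, clean, cMin = 0.5)
  expect_equal(nrow(kept), 1)
  expect_gt(kept$corr, 0.7)

  # seeds in pure noise are dropped at cMin = 0.5 but kept vacuously at -1
  set.seed(77)
  noise <- IntensityVolume(array(rpois(40 * 40 * 20, 10), c(40, 40, 20)),
                           c(1, 1, 1))
  rnd <- data.frame(x = round(runif(50, 8, 31)), y = round(runif(50, 8, 31)),
                    z = round(runif(50, 5, 14)), vx = 1, vy = 0, vz = 0,
                    sigma = 2, tubularity = 1)
  expect_lt(nrow(filterSeeds(rnd, noise, cMin = 0.5)), 10)
  expect_equal(nrow(filterSeeds(rnd, noise, cMin = -1)), 50)
})

test_that("seeds on a clean cylinder sit on the centerline, aligned", {
  shape <- c(100, 30, 30)
  cyl <- cylinderTree(shape, radius = 3)
  vol <- noiseFreeVolume(cyl, shape)
  seeds <- extractSeeds(vol, seedParams())
  expect_gt(nrow(seeds), 0)
  offAxis <- sqrt((seeds$y - 14.5)^2 + (seeds$z - 14.5)^2)
  expect_gte(mean(offAxis <= 1), 0.9)
  expect_gte(mean(abs(seeds$vx) >= 0.95), 0.9)
  # ordered by decreasing tubularity
  expect_true(all(diff(seeds$tubularity) <= 1e-12))
})

test_that("seed count is non-increasing in tau and cMin", {
  sim <- simulateY(snr = 5, seed = 41)
  n1 <- nrow(extractSeeds(sim, seedParams(tau = 5)))
  n2 <- nrow(extractSeeds(sim, seedParams(tau = 20)))
  expect_lte(n2, n1)
  n3 <- nrow(extractSeeds(sim, seedParams(cMin = -1)))
  n4 <- nrow(extractSeeds(sim, seedParams(cMin = 0.8)))
  expect_lte(n4, n3)
})
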