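#' Particle-filter tracing parameters
#'
#' Defaults follow the method's standard configuration: N = 20 particles,
#' circular concentration kappa = 3, step size d = 3 voxels, scale
#' variance zeta = 1, likelihood sensitivity K = 20, correlation threshold
#' cMin = 0.5, iteration limit L = 200, node density limit delta = 4 over
#' the 9-voxel in-plane neighborhood.
#'
#' @param N particle count.
#' @param kappa von Mises-Fisher concentration of the direction prior.
#' @param d tracing step size (voxels); step lengths are Gaussian with
#'   mean d and sd d/3, truncated to (0, 2d].
#' @param zeta scale (radius) transition standard deviation; scale moves
#'   are truncated to |delta sigma| <= 3 zeta.
#' @param K likelihood sensitivity in \eqn{e^{K c}}.
#' @param cMin trace termination threshold on the mean template
#'   correlation.
#' @param L iteration limit per trace.
#' @param deltaN node density limit per n-voxel neighborhood.
#' @param n density neighborhood size: 1 (the voxel), 5 (+4 in-plane), or
#'   9 (+8 in-plane); in-plane neighborhoods suit anisotropic stacks.
#' @param resampleFrac systematic resampling is triggered when the
#'   effective sample size falls below this fraction of N.
#' @param sigmaMin,sigmaMax clamp for the particle scale, keeping the
#'   correlation template well-posed. \code{sigmaMax} defaults to the
#'   largest seed scale plus 3 zeta at trace time when NULL.
#' @return a parameter list of class \code{TracerParams}.
#' @export
tracerParams <- function(N = 20, kappa = 3, d = 3, zeta = 1, K = 20,
                         cMin = 0.5, L = 200, deltaN = 4, n = 9,
                         resampleFrac = 0.8, sigmaMin = 0.25,
                         sigmaMax = NULL) {
  stopifnot(N >= 1, kappa > 0, d > 0, zeta > 0, K >= 0, L >= 0,
            deltaN > 0, n %in% c(1, 5, 9),
            resampleFrac > 0, resampleFrac <= 1, sigmaMin > 0)
  structure(list(N = as.integer(N), kappa = kappa, d = d, zeta = zeta,
                 K = K, cMin = cMin, L = as.integer(L), deltaN = deltaN,
                 n = as.integer(n), resampleFrac = resampleFrac,
                 sigmaMin = sigmaMin, sigmaMax = sigmaMax),
            class = "TracerParams")
}

# Orthonormal frame (u, w) completing unit axis v; same construction as
# the C++ template kernel so poses agree across the package.
.frame <- function(v) {
  a <- if (abs(v[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- c(v[2] * a[3] - v[3] * a[2],
         v[3] * a[1] - v[1] * a[3],
         v[1] * a[2] - v[2] * a[1])
  u <- u / sqrt(sum(u^2))
  w <- c(v[2] * u[3] - v[3] * u[2],
         v[3] * u[1] - v[1] * u[3],
         v[1] * u[2] - v[2] * u[1])
  rbind(u = u, w = w)
}

# Inverse-CDF truncated normal draws on [lo, hi] (vectorized bounds).
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(plo + runif(n) * (phi - plo))
}

# von Mises-Fisher draws about per-row axes (matrix n x 3), exact
# inverse-CDF sampling of the axial cosine on the 2-sphere.
.rvmf <- function(axes, kappa) {
  n <- nrow(axes)
  u <- runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- 2 * pi * runif(n)
  s <- sqrt(pmax(0, 1 - w^2))
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    fr <- .frame(axes[i, ])
    out[i, ] <- w[i] * axes[i, ] +
      s[i] * (cos(phi[i]) * fr[1, ] + sin(phi[i]) * fr[2, ])
  }
  out
}

#' Sample the state transition prior
#'
#' Draws the next particle states: a direction from a von Mises-Fisher
#' distribution concentrated around the previous direction, a step length
#' from a Gaussian of mean d and sd d/3 truncated to (0, 2d], and a new
#' scale from a Gaussian about the previous scale truncated to
#' |delta sigma| <= 3 zeta and the configured clamp. The stored direction
#' is the normalized displacement between consecutive positions. The
#' transition density is returned up to a constant (normalization
#' constants cancel in the weight renormalization).
#'
#' @param p,v,sigma previous particle states: n x 3 position and direction
#'   matrices and a length-n scale vector.
#' @param params a \code{\link{tracerParams}} object.
#' @return list with new \code{p}, \code{v}, \code{sigma} and
#'   \code{transDensity} (unnormalized).
#' @export
sampleTransition <- function(p, v, sigma, params) {
  n <- nrow(p)
  d <- params$d
  dir <- .rvmf(v, params$kappa)
  step <- .rtruncnorm(n, d, d / 3, 1e-9, 2 * d)
  smax <- if (is.null(params$sigmaMax)) Inf else params$sigmaMax
  lo <- pmax(params$sigmaMin, sigma - 3 * params$zeta)
  hi <- pmin(sigma + 3 * params$zeta, smax)
  newSigma <- .rtruncnorm(n, sigma, params$zeta, lo, hi)
  newP <- p + dir * step
  dens <- exp(params$kappa * rowSums(dir * v) -
                (step - d)^2 / (2 * (d / 3)^2) -
                (newSigma - sigma)^2 / (2 * params$zeta^2))
  list(p = newP, v = dir, sigma = newSigma, transDensity = dens)
}

#' Cylindrical-template correlation at a trace state
#'
#' Zero-normalized cross-correlation between trilinearly sampled image
#' intensities and a cylindrical template with Gaussian cross-sectional
#' profile of scale sigma, constant along the axis. Invariant to intensity
#' scaling and offset; a constant image patch returns 0.
#'
#' @param volume an \code{\link{IntensityVolume}}.
#' @param p position (length 3 or n x 3 matrix).
#' @param v axis direction (length 3 or n x 3 matrix).
#' @param sigma template scale(s).
#' @return correlation value(s) in [-1, 1].
#' @export
zncc <- function(volume, p, v, sigma) {
  vol <- as.numeric(volumeData(volume))
  dims <- dim(volumeData(volume))
  p <- if (is.matrix(p)) p else matrix(p, ncol = 3)
  v <- if (is.matrix(v)) v else matrix(v, ncol = 3)
  znccBatchCpp(vol, dims, p, v, rep_len(sigma, nrow(p)))
}

#' Particle weight update
#'
#' Multiplies each previous weight by the (unnormalized) transition
#' density and the correlation likelihood \eqn{e^{K c}}, then
#' renormalizes. If every weight underflows to zero the set is reset to
#' uniform with a warning.
#'
#' @param w previous normalized weights.
#' @param transDensity transition densities from
#'   \code{\link{sampleTransition}}.
#' @param corr per-particle template correlations.
#' @param params a \code{\link{tracerParams}} object.
#' @return the new normalized weights.
#' @export
updateWeights <- function(w, transDensity, corr, params) {
  wn <- w * transDensity * exp(params$K * corr)
  s <- sum(wn)
  if (!is.finite(s) || s <= 0) {
    warning("degenerate likelihood: resetting weights to uniform")
    return(rep(1 / length(w), length(w)))
  }
  wn / s
}

#' Effective sample size of a weight set
#'
#' \eqn{N_{eff} = 1 / \sum_k w_k^2}; ranges from 1 (full degeneracy) to N
#' (uniform weights).
#'
#' @param w normalized weights.
#' @return the effective sample size.
#' @export
effectiveSampleSize <- function(w) 1 / sum(w^2)

#' Systematic resampling
#'
#' Low-variance offspring selection: a single uniform offset
#' u in [0, 1/N) is compared against the cumulative weights at positions
#' u + k/N. Offspring counts of particle k are between floor(N w_k) and
#' ceiling(N w_k), and the returned set is equally weighted.
#'
#' @param w normalized weights.
#' @param n number of offspring to draw (defaults to the particle count).
#' @param u optional fixed offset in [0, 1/n) (exposed for testing);
#'   drawn uniformly when NULL.
#' @return integer vector of n parent indices.
#' @export
systematicResample <- function(w, n = length(w), u = NULL) {
  if (is.null(u)) u <- runif(1) / n
  stopifnot(u >= 0, u < 1 / n)
  positions <- u + (seq_len(n) - 1) / n
  cw <- cumsum(w)
  cw[length(cw)] <- 1  # guard against rounding
  findInterval(positions, cw, left.open = TRUE) + 1L
}

#' Posterior state estimate from a particle set
#'
#' The weighted centroid of the particle states: weighted mean position
#' and scale, normalized weighted mean direction (the previous direction
#' is kept if the mean direction degenerates to zero norm), plus the
#' unweighted mean correlation used for trace termination.
#'
#' @param p,v,sigma particle states (matrices / vector as in
#'   \code{\link{sampleTransition}}).
#' @param w normalized weights.
#' @param corr per-particle correlations.
#' @param prevV fallback direction for degenerate spread.
#' @return list with \code{p}, \code{v}, \code{sigma}, \code{meanCorr}.
#' @export
estimateState <- function(p, v, sigma, w, corr, prevV = c(0, 0, 1)) {
  ph <- colSums(p * w)
  sh <- sum(sigma * w)
  vh <- colSums(v * w)
  nv <- sqrt(sum(vh^2))
  vh <- if (nv > 1e-12) vh / nv else prevV
  list(p = ph, v = vh, sigma = sh, meanCorr = mean(corr))
}

# Mutable node-density bookkeeping shared by all traces of a run.
.newDensityGrid <- function(dims) {
  env <- new.env(parent = emptyenv())
  env$counts <- array(0L, dim = dims)
  env$dims <- dims
  env
}

# Sum of node counts over the in-plane n-neighborhood of 0-based voxel vx.
.densityAt <- function(density, vx, n) {
  dims <- density$dims
  i <- vx + 1L
  if (any(i < 1L) || any(i > dims)) return(Inf)
  offs <- switch(as.character(n),
    "1" = cbind(0L, 0L),
    "5" = cbind(c(0L, 1L, -1L, 0L, 0L), c(0L, 0L, 0L, 1L, -1L)),
    "9" = as.matrix(expand.grid(dx = -1:1, dy = -1:1)))
  xs <- i[1] + offs[, 1]; ys <- i[2] + offs[, 2]
  ok <- xs >= 1L & xs <= dims[1] & ys >= 1L & ys <= dims[2]
  sum(density$counts[cbind(xs[ok], ys[ok], i[3])])
}

.incrementDensity <- function(density, vx) {
  i <- vx + 1L
  if (all(i >= 1L) && all(i <= density$dims))
    density$counts[i[1], i[2], i[3]] <- density$counts[i[1], i[2], i[3]] + 1L
  invisible(NULL)
}

#' Trace one branch from a seed in one direction
#'
#' Runs the particle filter from the seed state with direction
#' \code{sign * v}: predict via the transition prior, update weights with
#' the correlation likelihood, systematically resample when the effective
#' sample size drops below \code{resampleFrac * N}, and append the
#' weighted-centroid estimate as a trace node. Tracing stops when the mean
#' correlation falls below \code{cMin}, the iteration limit is reached,
#' the local node density exceeds \code{deltaN} (checked before
#' appending), or the estimate leaves the volume.
#'
#' @param seed one row of an \code{\link{extractSeeds}} frame (or any list
#'   with x, y, z, vx, vy, vz, sigma).
#' @param sign +1 or -1, the tracing direction along the seed axis.
#' @param volume the \code{\link{IntensityVolume}} being traced.
#' @param density a shared density grid (internal; created by
#'   \code{\link{traceAll}}), or NULL for a private one.
#' @param params a \code{\link{tracerParams}} object.
#' @return data.frame of trace nodes (x, y, z, r, c), possibly empty.
#' @export
traceBranch <- function(seed, sign, volume, density = NULL,
                        params = tracerParams()) {
  vol <- as.numeric(volumeData(volume))
  dims <- dim(volumeData(volume))
  if (is.null(density)) density <- .newDensityGrid(dims)
  N <- params$N
  p <- matrix(rep(c(seed$x, seed$y, seed$z), each = N), N, 3)
  v <- matrix(rep(sign * c(seed$vx, seed$vy, seed$vz), each = N), N, 3)
  sigma <- rep(seed$sigma, N)
  w <- rep(1 / N, N)
  nodes <- vector("list", params$L)
  nOut <- 0L
  prevV <- v[1, ]
  for (it in seq_len(params$L)) {
    tr <- sampleTransition(p, v, sigma, params)
    corr <- znccBatchCpp(vol, dims, tr$p, tr$v, tr$sigma)
    w <- updateWeights(w, tr$transDensity, corr, params)
    p <- tr$p; v <- tr$v; sigma <- tr$sigma
    if (effectiveSampleSize(w) < params$resampleFrac * N) {
      idx <- systematicResample(w)
      p <- p[idx, , drop = FALSE]
      v <- v[idx, , drop = FALSE]
      sigma <- sigma[idx]
      corr <- corr[idx]
      w <- rep(1 / N, N)
    }
    est <- estimateState(p, v, sigma, w, corr, prevV)
    prevV <- est$v
    if (est$meanCorr < params$cMin) break
    vx <- as.integer(round(est$p))
    if (any(vx < 0L) || any(vx > dims - 1L)) break
    if (.densityAt(density, vx, params$n) > params$deltaN) break
    nOut <- nOut + 1L
    nodes[[nOut]] <- c(est$p, est$sigma, est$meanCorr)
    .incrementDensity(density, vx)
  }
  if (nOut == 0L) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      r = numeric(), c = numeric()))
  }
  m <- do.call(rbind, nodes[seq_len(nOut)])
  data.frame(x = m[, 1], y = m[, 2], z = m[, 3], r = pmax(m[, 4], 1e-6),
             c = m[, 5])
}

#' Trace all seeds
#'
#' Runs \code{\link{traceBranch}} twice per seed (along +v and -v) against
#' a density grid shared across the whole run, so the same branch is
#' traced repeatedly -- but probabilistically independently -- until the
#' local node density limit takes over. The two half-traces of a seed are
#' joined through a node at the seed itself so each kept trace is one
#' connected polyline.
#'
#' @param seeds data.frame from \code{\link{extractSeeds}}, ordered by
#'   decreasing tubularity.
#' @param volume the \code{\link{IntensityVolume}} being traced.
#' @param params a \code{\link{tracerParams}} object.
#' @param deadline optional \code{Sys.time()} deadline; seeds are skipped
#'   once it passes (logged), keeping runs inside a wall-clock budget.
#' @return list with \code{traces} (list of node data.frames) and
#'   \code{density} (the final density grid environment).
#' @export
traceAll <- function(seeds, volume, params = tracerParams(),
                     deadline = NULL) {
  dims <- dim(volumeData(volume))
  density <- .newDensityGrid(dims)
  vol <- as.numeric(volumeData(volume))
  traces <- list()
  if (is.null(params$sigmaMax) && nrow(seeds))
    params$sigmaMax <- max(seeds$sigma) + 3 * params$zeta
  for (i in seq_len(nrow(seeds))) {
    if (!is.null(deadline) && Sys.time() > deadline) {
      message(sprintf("tracing budget reached; skipping %d remaining seeds",
                      nrow(seeds) - i + 1))
      break
    }
    seed <- seeds[i, ]
    svx <- as.integer(round(c(seed$x, seed$y, seed$z)))
    if (.densityAt(density, svx, params$n) > params$deltaN) next
    plus <- traceBranch(seed, +1, volume, density, params)
    minus <- traceBranch(seed, -1, volume, density, params)
    if (nrow(plus) + nrow(minus) == 0L) next
    seedCorr <- znccBatchCpp(vol, dims,
                             matrix(c(seed$x, seed$y, seed$z), 1),
                             matrix(c(seed$vx, seed$vy, seed$vz), 1),
                             seed$sigma)
    seedNode <- data.frame(x = seed$x, y = seed$y, z = seed$z,
                           r = seed$sigma, c = seedCorr)
    trace <- rbind(minus[rev(seq_len(nrow(minus))), , drop = FALSE],
                   seedNode, plus)
    .incrementDensity(density, svx)
    traces[[length(traces) + 1L]] <- trace
  }
  list(traces = traces, density = density)
}
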