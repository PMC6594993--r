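#' Seed extraction parameters
#'
#' @param scales Gaussian scales (voxels) of the multiscale tubularity
#'   filter; Table defaults \{2, 4, 6\}.
#' @param tau noise tolerance for local-maxima pruning, on the 8-bit scale
#'   of the affinely rescaled tubularity map.
#' @param alpha,beta tubularity plate/blob sensitivity constants.
#' @param cFrac fraction of the maximum Hessian norm (over all voxels and
#'   scales) defining the structureness constant c.
#' @param cMin template-correlation threshold shared with trace
#'   termination.
#' @param frobenius if TRUE the structureness measure uses all three
#'   eigenvalues (classic Frobenius norm) instead of
#'   \eqn{\sqrt{\lambda_1^2 + \lambda_2^2}}.
#' @return a parameter list of class \code{SeedParams}.
#' @export
seedParams <- function(scales = c(2, 4, 6), tau = 10, alpha = 0.5,
                       beta = 0.5, cFrac = 0.5, cMin = 0.5,
                       frobenius = FALSE) {
  stopifnot(length(scales) >= 1, all(scales >= 0.5), tau >= 0,
            alpha > 0, beta > 0, cFrac > 0)
  structure(list(scales = sort(as.numeric(scales)), tau = tau,
                 alpha = alpha, beta = beta, cFrac = cFrac, cMin = cMin,
                 frobenius = frobenius),
            class = "SeedParams")
}

#' Hessian eigen-analysis of a volume at one scale
#'
#' Computes the Hessian of the Gaussian-smoothed image by separable
#' Gaussian-derivative filtering (derivative scale along z divided by the
#' z voxel aspect, responses scale-normalized by sigma^2) and decomposes
#' it per voxel. Eigenvalues are sorted by absolute value and the
#' eigenvector of the smallest one (the local axis of a tube) is
#' sign-normalized to a non-negative z component.
#'
#' @param volume an \code{\link{IntensityVolume}}.
#' @param sigma Gaussian derivative scale, at least 0.5 voxel.
#' @return list of 3D arrays \code{l1,l2,l3} (|l1| <= |l2| <= |l3|) and
#'   \code{vx,vy,vz} (unit eigenvector of l1).
#' @export
hessianEigen <- function(volume, sigma) {
  stopifnot(is(volume, "IntensityVolume"))
  if (sigma < 0.5) stop("sigma below 0.5 voxel: derivative kernels degenerate")
  v <- as.numeric(volumeData(volume))
  dims <- dim(volumeData(volume))
  asp <- voxelAspect(volume)
  sz <- max(sigma / asp[3], 0.5)
  g0 <- .gaussKernel(sigma, 0); g1 <- .gaussKernel(sigma, 1)
  g2 <- .gaussKernel(sigma, 2)
  h0 <- .gaussKernel(sz, 0); h1 <- .gaussKernel(sz, 1)
  h2 <- .gaussKernel(sz, 2)
  der <- function(kx, ky, kz) {
    x <- convSepAxis(v, dims, kx, 0L)
    x <- convSepAxis(x, dims, ky, 1L)
    convSepAxis(x, dims, kz, 2L)
  }
  s2 <- sigma^2
  dxx <- s2 * der(g2, g0, h0); dyy <- s2 * der(g0, g2, h0)
  dzz <- s2 * der(g0, g0, h2)
  dxy <- s2 * der(g1, g1, h0); dxz <- s2 * der(g1, g0, h1)
  dyz <- s2 * der(g0, g1, h1)
  r <- hessianEigenCpp(dxx, dyy, dzz, dxy, dxz, dyz)
  names(r) <- c("l1", "l2", "l3", "vx", "vy", "vz")
  lapply(r, array, dim = dims)
}

#' Tubularity of a single Hessian eigenvalue triple
#'
#' The three-factor vesselness: 0 whenever \eqn{\lambda_2 > 0} or
#' \eqn{\lambda_3 > 0} (tubes are bright on dark), otherwise
#' \deqn{(1 - e^{-R_a^2/2\alpha^2}) e^{-R_b^2/2\beta^2}
#'       (1 - e^{-S^2/2c^2})}
#' with \eqn{R_a = |\lambda_2|/|\lambda_3|},
#' \eqn{R_b = |\lambda_1|/\sqrt{|\lambda_2 \lambda_3|}} and
#' \eqn{S = \sqrt{\lambda_1^2 + \lambda_2^2}} (or the Frobenius norm of
#' all three when \code{frobenius}). Division guards return 0, never NaN.
#'
#' @param l1,l2,l3 eigenvalues with |l1| <= |l2| <= |l3| (vectorized).
#' @param alpha,beta,c tubularity constants (c > 0).
#' @param frobenius use the all-eigenvalue structureness variant.
#' @return tubularity values in [0, 1].
#' @export
frangiTubularity <- function(l1, l2, l3, alpha = 0.5, beta = 0.5, c,
                             frobenius = FALSE) {
  stopifnot(c > 0)
  ra2 <- ifelse(l3 == 0, 0, (l2 / l3)^2)
  rb2 <- ifelse(l2 * l3 == 0, 0, l1^2 / abs(l2 * l3))
  s2 <- if (frobenius) l1^2 + l2^2 + l3^2 else l1^2 + l2^2
  up <- (1 - exp(-ra2 / (2 * alpha^2))) * exp(-rb2 / (2 * beta^2)) *
    (1 - exp(-s2 / (2 * c^2)))
  up[l2 > 0 | l3 > 0 | l3 == 0] <- 0
  up
}

#' Multiscale tubularity map
#'
#' Per voxel, the maximum tubularity over the configured scales, together
#' with the scale attaining it and the corresponding local axis
#' (eigenvector of the smallest absolute eigenvalue). The structureness
#' constant c is set once to \code{cFrac} times the maximum Hessian norm
#' over all voxels and scales; a per-scale constant would flatten the
#' structureness factor across scales and destroy scale selection on
#' solid tubes.
#'
#' @param volume an \code{\link{IntensityVolume}}.
#' @param params a \code{\link{seedParams}} object.
#' @return list of 3D arrays: \code{value} (tubularity in [0,1]),
#'   \code{scale} (argmax sigma), \code{vx,vy,vz} (unit axis).
#' @export
multiscaleTubularity <- function(volume, params = seedParams()) {
  stopifnot(is(volume, "IntensityVolume"), inherits(params, "SeedParams"))
  dims <- dim(volumeData(volume))
  best <- array(0, dims)
  scl <- array(params$scales[1], dims)
  vx <- array(0, dims); vy <- array(0, dims); vz <- array(1, dims)
  hs <- lapply(params$scales, function(s) hessianEigen(volume, s))
  smax <- 0
  for (h in hs) {
    smeas <- if (params$frobenius) sqrt(h$l1^2 + h$l2^2 + h$l3^2)
             else sqrt(h$l1^2 + h$l2^2)
    smax <- max(smax, max(smeas))
  }
  cc <- params$cFrac * smax
  if (cc > 0) {
    for (k in seq_along(params$scales)) {
      h <- hs[[k]]
      u <- frangiTubularity(h$l1, h$l2, h$l3, params$alpha, params$beta,
                            cc, params$frobenius)
      gain <- u > best
      best[gain] <- u[gain]
      scl[gain] <- params$scales[k]
      vx[gain] <- h$vx[gain]; vy[gain] <- h$vy[gain]
      vz[gain] <- h$vz[gain]
    }
  }
  list(value = best, scale = scl, vx = vx, vy = vy, vz = vz)
}

#' Noise-tolerant 3D local maxima
#'
#' Local maxima of a 3D grid under 26-connectivity, pruned with a noise
#' tolerance: processing candidates in decreasing value, a candidate is
#' kept only if its flood region (connected voxels within \code{tau} below
#' its value, on the 8-bit-rescaled grid) reaches neither a higher voxel
#' nor the territory of a higher, already-claimed maximum.
#'
#' @param value 3D numeric array.
#' @param tau non-negative tolerance on the 8-bit scale.
#' @return integer matrix of 0-based voxel positions (x, y, z), one row
#'   per maximum.
#' @export
findMaxima3d <- function(value, tau) {
  stopifnot(tau >= 0)
  dims <- dim(value)
  rng <- range(value)
  if (diff(rng) == 0) return(matrix(integer(0), ncol = 3))
  scaled <- (as.numeric(value) - rng[1]) / diff(rng) * 255
  findMaxima3dCpp(scaled, dims, tau)
}

#' Cylindrical non-maximum suppression of seed candidates
#'
#' A candidate survives only if its tubularity is strictly the maximum of
#' the map over the voxels inside its own oriented cylinder of radius
#' 3 sigma and total length sigma, centered at the candidate and aligned
#' with its axis. Value ties are broken toward the lexicographically
#' lower (x, y, z) position.
#'
#' @param seeds data.frame with columns x, y, z (0-based integer voxel
#'   positions), vx, vy, vz, sigma, tubularity.
#' @param map a tubularity map from \code{\link{multiscaleTubularity}}.
#' @return the surviving subset of \code{seeds}.
#' @export
cylindricalNms <- function(seeds, map) {
  if (!nrow(seeds)) return(seeds)
  keep <- cylindricalNmsCpp(
    as.numeric(map$value), dim(map$value),
    as.matrix(seeds[, c("x", "y", "z")]),
    as.matrix(seeds[, c("vx", "vy", "vz")]),
    seeds$sigma)
  seeds[keep, , drop = FALSE]
}

#' Filter seeds by cylindrical-template correlation
#'
#' Keeps a seed only if the zero-normalized cross-correlation of the image
#' with the cylindrical Gaussian template at the seed's pose is at least
#' \code{cMin} -- exactly the criterion used for trace termination.
#'
#' @param seeds seed data.frame (see \code{\link{cylindricalNms}}).
#' @param volume the \code{\link{IntensityVolume}} being traced.
#' @param cMin correlation threshold.
#' @return the surviving subset of \code{seeds}, with a \code{corr} column.
#' @export
filterSeeds <- function(seeds, volume, cMin) {
  if (!nrow(seeds)) {
    seeds$corr <- numeric(0)
    return(seeds)
  }
  v <- as.numeric(volumeData(volume))
  dims <- dim(volumeData(volume))
  corr <- znccBatchCpp(v, dims, as.matrix(seeds[, c("x", "y", "z")]),
                       as.matrix(seeds[, c("vx", "vy", "vz")]),
                       seeds$sigma)
  seeds$corr <- corr
  seeds[corr >= cMin, , drop = FALSE]
}

#' Extract tracer seeds from a volume
#'
#' Full seed pipeline: multiscale tubularity, noise-tolerant maxima,
#' cylindrical non-maximum suppression, and template-correlation
#' filtering. Seeds are returned in decreasing tubularity order (ties by
#' position) -- the deterministic order in which they are traced.
#'
#' @param volume an \code{\link{IntensityVolume}}.
#' @param params a \code{\link{seedParams}} object.
#' @return data.frame of seeds: x, y, z, vx, vy, vz, sigma, tubularity,
#'   corr.
#' @export
extractSeeds <- function(volume, params = seedParams()) {
  map <- multiscaleTubularity(volume, params)
  pos <- findMaxima3d(map$value, params$tau)
  if (!nrow(pos)) {
    return(data.frame(x = integer(), y = integer(), z = integer(),
                      vx = numeric(), vy = numeric(), vz = numeric(),
                      sigma = numeric(), tubularity = numeric(),
                      corr = numeric()))
  }
  i <- pos + 1L
  lin <- cbind(i[, 1], i[, 2], i[, 3])
  seeds <- data.frame(
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    vx = map$vx[lin], vy = map$vy[lin], vz = map$vz[lin],
    sigma = map$scale[lin], tubularity = map$value[lin])
  # voxels with zero tubularity carry no meaningful axis
  seeds <- seeds[seeds$tubularity > 0, , drop = FALSE]
  nv <- sqrt(seeds$vx^2 + seeds$vy^2 + seeds$vz^2)
  ok <- nv > 0
  seeds <- seeds[ok, , drop = FALSE]
  nv <- nv[ok]
  seeds$vx <- seeds$vx / nv; seeds$vy <- seeds$vy / nv
  seeds$vz <- seeds$vz / nv
  seeds <- cylindricalNms(seeds, map)
  seeds <- filterSeeds(seeds, volume, params$cMin)
  o <- order(-seeds$tubularity, seeds$x, seeds$y, seeds$z)
  seeds <- seeds[o, , drop = FALSE]
  rownames(seeds) <- NULL
  seeds
}
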