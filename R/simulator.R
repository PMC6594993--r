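#' Simulation parameters for synthetic fluorescence stacks
#'
#' Bundles the image-formation settings used by \code{\link{simulateStack}}.
#' The signal-to-noise ratio follows the Poisson convention: mean intensity
#' inside the neuron above background, divided by the noise standard
#' deviation inside the neuron. \code{cor} is the Gaussian scale (voxels)
#' of the smoothing used to induce inter-voxel correlation.
#'
#' @param snr positive target signal-to-noise ratio.
#' @param cor non-negative Gaussian smoothing scale (voxels); 0 disables.
#' @param backgroundLevel expected background photon count (default 10;
#'   a nonzero background keeps the Poisson SNR equation well-posed).
#' @param supersample subsamples per axis for partial-volume estimation.
#' @param voxelAspect voxel aspect of the simulated stack.
#' @param seed optional RNG seed applied by \code{simulateStack}.
#' @return a validated parameter list of class \code{SimulationParams}.
#' @export
simulationParams <- function(snr, cor = 0, backgroundLevel = 10,
                             supersample = 2, voxelAspect = c(1, 1, 1),
                             seed = NULL) {
  stopifnot(is.numeric(snr), length(snr) == 1, snr > 0,
            is.numeric(cor), length(cor) == 1, cor >= 0,
            backgroundLevel > 0, supersample >= 1,
            length(voxelAspect) == 3, all(voxelAspect > 0))
  structure(list(snr = snr, cor = cor, backgroundLevel = backgroundLevel,
                 supersample = as.integer(supersample),
                 voxelAspect = as.numeric(voxelAspect), seed = seed),
            class = "SimulationParams")
}

#' Partial-volume occupancy of a morphology
#'
#' Renders an SWC tree into a volume whose voxels hold the fraction of
#' their volume inside the union of tapered capsules (cone frusta with
#' hemispherical caps) spanning each parent-child edge, estimated on a
#' supersample^3 subgrid. Geometry outside the requested shape is clipped.
#'
#' @param tree an \code{\link{SwcTree}} with positive radii.
#' @param shape integer(3) volume extents (x, y, z).
#' @param params a \code{\link{simulationParams}} object (only
#'   \code{supersample} and \code{voxelAspect} are used).
#' @return an \code{\link{IntensityVolume}} with values in [0, 1].
#' @export
voxelizeTree <- function(tree, shape, params = simulationParams(snr = 4)) {
  stopifnot(is(tree, "SwcTree"), length(shape) == 3)
  shape <- as.integer(shape)
  edges <- .swcEdges(tree)
  if (nrow(edges) == 0) {
    warning("empty tree: returning all-zero occupancy")
    return(IntensityVolume(array(0, dim = shape), params$voxelAspect))
  }
  occ <- voxelizeCapsulesCpp(shape, edges, params$supersample)
  IntensityVolume(array(occ, dim = shape), params$voxelAspect)
}

#' Foreground photon level for a target Poisson SNR
#'
#' Solves \eqn{(\lambda_f - \lambda_b)/\sqrt{\lambda_f} = SNR} for the
#' expected foreground photon count \eqn{\lambda_f}, i.e.
#' \eqn{\sqrt{\lambda_f} = (SNR + \sqrt{SNR^2 + 4\lambda_b})/2}.
#'
#' @param snr non-negative target SNR.
#' @param backgroundLevel expected background count \eqn{\lambda_b}.
#' @return the expected foreground count \eqn{\lambda_f}.
#' @examples
#' photonLevels(4, 0)   # 16
#' @export
photonLevels <- function(snr, backgroundLevel) {
  stopifnot(snr >= 0, backgroundLevel >= 0)
  ((snr + sqrt(snr^2 + 4 * backgroundLevel)) / 2)^2
}

#' Measured SNR of a volume over foreground/background masks
#'
#' \code{(mean(fg) - mean(bg)) / sd(fg)}: the intensity inside the neuron
#' above background divided by the noise standard deviation inside.
#'
#' @param volume an \code{\link{IntensityVolume}} or 3D array.
#' @param fgMask,bgMask logical arrays congruent with the volume.
#' @return the measured SNR.
#' @export
measureSnr <- function(volume, fgMask, bgMask) {
  v <- if (is(volume, "IntensityVolume")) volumeData(volume) else volume
  (mean(v[fgMask]) - mean(v[bgMask])) / sd(v[fgMask])
}

#' Simulate a fluorescence microscopy stack from an SWC morphology
#'
#' Renders the tree as partial-volume occupancy, draws one Poisson sample
#' per voxel at expected count
#' \eqn{\lambda = \lambda_b + occ (\lambda_f - \lambda_b)}, optionally
#' smooths the noisy volume at scale \code{cor} (divided by the z aspect
#' along z) and then rescales the signal-component contrast so the
#' measured SNR over the known occupancy mask re-matches the target, and
#' finally min-max quantizes to 8 bits. The point spread function is
#' deliberately not modeled: at typical magnifications the voxel exceeds
#' the PSF, so digitization partial volume dominates optical blur.
#'
#' @param tree an \code{\link{SwcTree}} (the ground-truth reconstruction).
#' @param shape integer(3) stack extents.
#' @param params a \code{\link{simulationParams}} object.
#' @return list with \code{volume} (8-bit \code{\link{IntensityVolume}}),
#'   \code{occupancy} (\code{IntensityVolume} in [0,1]) and \code{lambda}
#'   (expected-count array).
#' @export
simulateStack <- function(tree, shape, params) {
  stopifnot(inherits(params, "SimulationParams"))
  if (!is.null(params$seed)) set.seed(params$seed)
  occV <- voxelizeTree(tree, shape, params)
  occ <- volumeData(occV)
  lb <- params$backgroundLevel
  lf <- photonLevels(params$snr, lb)
  lambda <- lb + occ * (lf - lb)
  noisy <- array(rpois(length(lambda), lambda), dim = dim(lambda))
  out <- noisy
  if (params$cor > 0) {
    sig <- params$cor
    out <- .gaussSmooth3d(noisy, sig, params$voxelAspect)
    # measure the SNR over interior voxels: partial-volume edge voxels
    # carry a signal gradient that would dominate the variance after
    # smoothing and make the noise level unrecoverable
    fg <- occ >= 0.999
    if (sum(fg) < 100) fg <- occ >= 0.5
    bg <- occ == 0
    if (any(fg) && any(bg) && sd(out[fg]) > 0) {
      # smoothing suppresses noise more than contrast, raising the measured
      # SNR; re-match it by scaling the smoothed noise-free expectation
      # component (an affine map of the whole image would cancel out)
      es <- .gaussSmooth3d(lambda, sig, params$voxelAspect)
      esc <- es - mean(es[bg])
      snrOf <- function(g) {
        v <- out + (g - 1) * esc
        (mean(v[fg]) - mean(v[bg])) / sd(v[fg])
      }
      gstar <- tryCatch(
        uniroot(function(g) snrOf(g) - params$snr,
                lower = 1e-3, upper = 50, extendInt = "upX")$root,
        error = function(e) NA_real_)
      if (is.finite(gstar)) out <- out + (gstar - 1) * esc
      else warning("SNR re-matching failed; keeping smoothed contrast")
    }
  }
  out <- pmax(out, 0)
  rng <- range(out)
  if (diff(rng) > 0) out <- (out - rng[1]) / diff(rng)
  img <- array(round(255 * out), dim = dim(out))
  list(volume = IntensityVolume(img, params$voxelAspect),
       occupancy = occV, lambda = lambda)
}

# Separable Gaussian smoothing; the scale along z is divided by the z
# voxel aspect.
.gaussSmooth3d <- function(vol, sigma, aspect = c(1, 1, 1)) {
  dims <- dim(vol)
  v <- as.numeric(vol)
  kz <- .gaussKernel(max(sigma / aspect[3], 1e-3), order = 0)
  kxy <- .gaussKernel(sigma, order = 0)
  v <- convSepAxis(v, dims, kxy, 0L)
  v <- convSepAxis(v, dims, kxy, 1L)
  v <- convSepAxis(v, dims, kz, 2L)
  array(v, dim = dims)
}

# Sampled Gaussian (order 0), first (order 1) or second (order 2)
# derivative kernel. Order 0 normalized to unit sum; order 2 corrected to
# zero sum so constant images yield exactly zero response.
.gaussKernel <- function(sigma, order = 0) {
  r <- max(1L, ceiling(3 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  if (order == 0) return(g / sum(g))
  gn <- g / (sigma * sqrt(2 * pi))
  if (order == 1) return(-x / sigma^2 * gn)
  k <- (x^2 - sigma^2) / sigma^4 * gn
  k - mean(k)
}

#' Deterministic toy morphologies for simulation and testing
#'
#' \code{line}: a straight 2-node branch along +x. \code{Y}: a trunk with
#' one bifurcation and two oblique daughters (3 terminals).
#' \code{spiral}: a curved helical branch of approximately the requested
#' arc length.
#'
#' @param kind one of "line", "Y", "spiral".
#' @param length total (arc) length in voxels.
#' @param radius branch radius in voxels.
#' @param origin position of the first node.
#' @param voxelAspect aspect attached to the returned tree.
#' @return an \code{\link{SwcTree}}.
#' @export
generateToyTree <- function(kind = c("line", "Y", "spiral"), length = 40,
                            radius = 2, origin = c(0, 0, 0),
                            voxelAspect = c(1, 1, 1)) {
  kind <- match.arg(kind)
  stopifnot(length > 0, radius > 0)
  o <- as.numeric(origin)
  if (kind == "line") {
    nd <- data.frame(id = 1:2, type = c(3L, 3L),
                     x = c(o[1], o[1] + length), y = o[2], z = o[3],
                     radius = radius, parent = c(-1L, 1L))
  } else if (kind == "Y") {
    trunk <- 0.5 * length
    arm <- 0.5 * length
    ang <- 40 * pi / 180
    nd <- data.frame(
      id = 1:4, type = 3L,
      x = c(o[1], o[1] + trunk,
            o[1] + trunk + arm * cos(ang),
            o[1] + trunk + arm * cos(ang)),
      y = c(o[2], o[2],
            o[2] + arm * sin(ang),
            o[2] - arm * sin(ang)),
      z = o[3],
      radius = radius, parent = c(-1L, 1L, 2L, 2L))
  } else {
    # helix with pitch chosen so the curve stays gently curved
    rHelix <- 0.25 * length
    pitch <- 0.1 * length
    speed <- sqrt(rHelix^2 + (pitch / (2 * pi))^2)  # |dp/dt|
    tmax <- length / speed
    t <- seq(0, tmax, length.out = max(8, ceiling(length / 2)))
    nd <- data.frame(
      id = seq_along(t), type = 3L,
      x = o[1] + rHelix * cos(t) - rHelix,
      y = o[2] + rHelix * sin(t),
      z = o[3] + pitch * t / (2 * pi),
      radius = radius,
      parent = c(-1L, seq_along(t)[-base::length(t)]))
  }
  SwcTree(nd, voxelAspect)
}

#' Conditions of the synthetic robustness experiment
#'
#' Enumerates the full factorial simulation grid: each morphology at every
#' combination of SNR and COR level, one image stack per cell.
#'
#' @param nNeurons number of distinct morphologies.
#' @param snrLevels,corLevels image-quality factor levels.
#' @return data.frame with one row per stack (neuron, snr, cor).
#' @export
syntheticGridConditions <- function(nNeurons = 10,
                                    snrLevels = c(1, 2, 3, 4, 5, 10, 20),
                                    corLevels = c(0, 0.5, 1, 1.5, 2)) {
  grid <- expand.grid(neuron = seq_len(nNeurons), snr = snrLevels,
                      cor = corLevels, KEEP.OUT.ATTRS = FALSE)
  grid[order(grid$neuron, grid$snr, grid$cor), , drop = FALSE]
}

#' Read/write an 8-bit grayscale TIFF stack
#'
#' One TIFF page per z-slice, z-major order; page rows are y and columns
#' are x of the volume.
#'
#' @param volume an \code{\link{IntensityVolume}} with values in [0, 255].
#' @param path file path.
#' @param voxelAspect aspect attached to a volume being read.
#' @return \code{writeTiffStack}: the path, invisibly;
#'   \code{readTiffStack}: an \code{IntensityVolume} with values 0-255.
#' @export
writeTiffStack <- function(volume, path) {
  v <- volumeData(volume)
  pages <- lapply(seq_len(dim(v)[3]), function(z) t(v[, , z]) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeTiffStack
#' @export
readTiffStack <- function(path, voxelAspect = c(1, 1, 2)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # drop extra channels
    round(255 * t(p))
  })
  arr <- array(unlist(slices),
               dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  IntensityVolume(arr, voxelAspect)
}
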