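#' Soma detection parameters
#'
#' @param rs erosion radius in voxels; must exceed the largest expected
#'   branch radius and stay below the expected soma radius. \code{rs = 0}
#'   disables soma detection entirely.
#' @return a parameter list of class \code{SomaParams}.
#' @export
somaParams <- function(rs = 6) {
  stopifnot(is.numeric(rs), length(rs) == 1, rs >= 0)
  structure(list(rs = rs), class = "SomaParams")
}

#' Separable grayscale erosion
#'
#' Minimum filter with half-width \code{rs} applied per axis sequentially;
#' the z half-width is divided by the z voxel aspect (and kept at least 1).
#' Erosion is anti-extensive: the output never exceeds the input.
#'
#' @param volume an \code{\link{IntensityVolume}}.
#' @param rs erosion radius in voxels, at least 1.
#' @return the eroded \code{IntensityVolume}.
#' @export
erodeSeparable <- function(volume, rs) {
  stopifnot(is(volume, "IntensityVolume"))
  if (!is.numeric(rs) || rs < 1) stop("erosion radius must be >= 1")
  v <- volumeData(volume)
  dims <- dim(v)
  asp <- voxelAspect(volume)
  hw <- as.integer(round(rs))
  hwz <- max(1L, as.integer(round(rs / asp[3])))
  x <- as.numeric(v)
  x <- minFilterAxis(x, dims, hw, 0L)
  x <- minFilterAxis(x, dims, hw, 1L)
  x <- minFilterAxis(x, dims, hwz, 2L)
  IntensityVolume(array(x, dim = dims), asp)
}

#' Maximum-entropy (Kapur) threshold of a 256-bin histogram
#'
#' Returns the bin index t (0-254) maximizing the sum of Shannon entropies
#' of the normalized histogram partitions at or below t and above t. Ties
#' are broken toward the lower threshold.
#'
#' @param histogram integer counts for bins 0..255.
#' @return the threshold bin index (foreground is strictly above it).
#' @export
maxEntropyThreshold <- function(histogram) {
  stopifnot(length(histogram) == 256, all(histogram >= 0))
  if (sum(histogram > 0) < 2)
    stop("degenerate histogram: need at least 2 nonempty bins")
  p <- histogram / sum(histogram)
  best <- -Inf
  bestT <- NA_integer_
  csum <- cumsum(p)
  for (t in 0:254) {
    p0 <- csum[t + 1]
    p1 <- 1 - p0
    if (p0 <= 0 || p1 <= 0) next
    lo <- p[seq_len(t + 1)]
    hi <- p[seq(t + 2, 256)]
    lo <- lo[lo > 0] / p0
    hi <- hi[hi > 0] / p1
    h <- -sum(lo * log(lo)) - sum(hi * log(hi))
    if (h > best + 1e-12) {
      best <- h
      bestT <- t
    }
  }
  bestT
}

#' Detect the soma as a single spherical node
#'
#' Pipeline: grayscale erosion with radius \code{rs} (removing all
#' branches thinner than the structuring element), Gaussian smoothing at
#' sigma \code{rs}, max-entropy thresholding of the 8-bit-scaled result,
#' and selection of the largest connected foreground blob. The soma model
#' is the blob centroid with radius equal to the average (anisotropy-aware)
#' distance of the blob voxels to the centroid. Two rules guard against
#' false detections: the fitted radius must reach \code{rs} (by
#' construction of the erosion radius the soma exceeds the branch scale),
#' and the blob must be foreground in the original image -- its mean
#' intensity at least one global standard deviation above the median --
#' which rejects blobs carved out of eroded background noise.
#'
#' @param volume an \code{\link{IntensityVolume}}.
#' @param params a \code{\link{somaParams}} object.
#' @return a \code{\link{SomaModel}}; absence is reported via
#'   \code{found = FALSE}, never an error.
#' @export
extractSoma <- function(volume, params = somaParams()) {
  stopifnot(is(volume, "IntensityVolume"), inherits(params, "SomaParams"))
  rs <- params$rs
  if (rs == 0) return(SomaModel())
  asp <- voxelAspect(volume)
  dims <- dim(volumeData(volume))
  eroded <- erodeSeparable(volume, rs)
  sm <- .gaussSmooth3d(volumeData(eroded), rs, asp)
  rng <- range(sm)
  if (diff(rng) == 0) return(SomaModel())
  scaled <- (sm - rng[1]) / diff(rng) * 255
  counts <- tabulate(pmin(floor(scaled), 255) + 1L, nbins = 256L)
  t <- tryCatch(maxEntropyThreshold(counts), error = function(e) NA_integer_)
  if (is.na(t)) return(SomaModel())
  mask <- scaled > t
  if (!any(mask)) return(SomaModel())
  labels <- labelComponentsCpp(as.logical(mask), dims)
  tab <- tabulate(labels[labels > 0])
  blobMask <- array(labels, dims) == which.max(tab)
  blob <- which(blobMask, arr.ind = TRUE) - 1
  center <- colMeans(blob)
  d <- sqrt(colSums((t(blob) - center)^2 * asp^2))
  radius <- mean(d)
  if (!is.finite(radius) || radius < rs) return(SomaModel())
  # the candidate region must be foreground in the original image: a true
  # soma blob sits at least one noise standard deviation above the
  # background level, while blobs carved out of eroded background noise
  # (branch-only or empty stacks) sit at the image median
  v <- volumeData(volume)
  if ((mean(v[blobMask]) - median(v)) / max(sd(v), 1e-12) < 1)
    return(SomaModel())
  SomaModel(center = center, radius = radius, found = TRUE)
}
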