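# Shared geometry helpers. All distances multiply per-axis coordinate
# differences by the voxel aspect before taking the Euclidean norm, so
# anisotropy enters the pipeline exactly once.

.anisoDist <- function(p, q, aspect) {
  d <- (p - q) * aspect
  sqrt(sum(d * d))
}

.scaleCoords <- function(mat, aspect) {
  sweep(mat, 2, aspect, `*`)
}

# Resample a polyline carrying arbitrary per-node values so that
# consecutive points are at most `step` apart (anisotropy-aware).
# points: n x 3 matrix; values: n x k matrix (linearly interpolated).
.resamplePath <- function(points, values, step, aspect = c(1, 1, 1)) {
  points <- as.matrix(points)
  values <- as.matrix(values)
  n <- nrow(points)
  if (n == 1) return(list(points = points, values = values))
  outP <- list(points[1, , drop = FALSE])
  outV <- list(values[1, , drop = FALSE])
  for (i in seq_len(n - 1)) {
    len <- .anisoDist(points[i, ], points[i + 1, ], aspect)
    nseg <- max(1L, ceiling(len / step))
    t <- seq_len(nseg) / nseg
    outP[[length(outP) + 1L]] <-
      outer(1 - t, points[i, ]) + outer(t, points[i + 1, ])
    outV[[length(outV) + 1L]] <-
      outer(1 - t, values[i, ]) + outer(t, values[i + 1, ])
  }
  list(points = do.call(rbind, outP), values = do.call(rbind, outV))
}

#' Densify a polyline to a maximum step size
#'
#' Inserts points along each segment of an ordered 3D polyline so that no
#' two consecutive points are further apart than \code{step}
#' (anisotropy-aware distance). The first and last input points are
#' preserved and radii are linearly interpolated.
#'
#' @param points n x 3 matrix of ordered positions (voxel units).
#' @param radii numeric vector of per-point radii.
#' @param step positive maximum spacing (voxels).
#' @param aspect voxel aspect used for distances.
#' @return list with densified \code{points} (matrix) and \code{radii}.
#' @examples
#' p <- rbind(c(0, 0, 0), c(4, 0, 0))
#' resamplePolyline(p, c(1, 2), step = 1)
#' @export
resamplePolyline <- function(points, radii, step, aspect = c(1, 1, 1)) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0)
    stop("step must be a positive scalar")
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("at least one point required")
  res <- .resamplePath(points, cbind(radii), step, aspect)
  list(points = res$points, radii = as.numeric(res$values[, 1]))
}
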