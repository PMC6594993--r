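#' Full reconstruction configuration
#'
#' All tunable parameters of the pipeline with their standard defaults:
#' erosion radius rs = 6, tubularity scales \{2, 4, 6\}, maxima tolerance
#' tau = 10 (8-bit scale), N = 20 particles, kappa = 3, step d = 3,
#' scale variance zeta = 1, likelihood sensitivity K = 20, correlation
#' threshold cMin = 0.5, iteration limit L = 200, node density limit
#' deltaN = 4 over the 9-voxel neighborhood, and grouping radius rg = 2.
#'
#' @param rs soma erosion radius (voxels); 0 disables soma detection.
#' @param scales tubularity scale set (voxels).
#' @param tau local-maxima noise tolerance (8-bit scale).
#' @param N,kappa,d,zeta,K,cMin,L,deltaN,n tracer parameters; see
#'   \code{\link{tracerParams}}.
#' @param rg node grouping radius (voxels).
#' @param meanShiftIterations mean-shift refinement iterations.
#' @param minComponent smallest disconnected component kept in the tree.
#' @param prune drop single-node terminal branches.
#' @param voxelAspect x:y:z voxel aspect (1:1:2 when unknown).
#' @param seed RNG seed making a run reproducible.
#' @return a configuration list of class \code{ReconstructionConfig}.
#' @export
reconstructionConfig <- function(rs = 6, scales = c(2, 4, 6), tau = 10,
                                 N = 20, kappa = 3, d = 3, zeta = 1,
                                 K = 20, cMin = 0.5, L = 200, deltaN = 4,
                                 n = 9, rg = 2, meanShiftIterations = 5,
                                 minComponent = 3, prune = TRUE,
                                 voxelAspect = c(1, 1, 2), seed = 1) {
  cfg <- list(rs = rs, scales = scales, tau = tau, N = N, kappa = kappa,
              d = d, zeta = zeta, K = K, cMin = cMin, L = L,
              deltaN = deltaN, n = n, rg = rg,
              meanShiftIterations = meanShiftIterations,
              minComponent = minComponent, prune = prune,
              voxelAspect = voxelAspect, seed = seed)
  # delegate range validation to the stage constructors
  somaParams(cfg$rs)
  seedParams(scales = cfg$scales, tau = cfg$tau, cMin = cfg$cMin)
  tracerParams(N = cfg$N, kappa = cfg$kappa, d = cfg$d, zeta = cfg$zeta,
               K = cfg$K, cMin = cfg$cMin, L = cfg$L, deltaN = cfg$deltaN,
               n = cfg$n)
  stopifnot(cfg$rg > 0, length(cfg$voxelAspect) == 3,
            all(cfg$voxelAspect > 0))
  structure(cfg, class = "ReconstructionConfig")
}

#' Read a reconstruction configuration from a flat YAML file
#'
#' Field names mirror the arguments of
#' \code{\link{reconstructionConfig}}; unknown fields are rejected,
#' missing ones take the defaults. Values passed in \code{overrides}
#' (e.g. from command-line flags) win over the file.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list of overriding values.
#' @return a \code{ReconstructionConfig}.
#' @export
readConfig <- function(path = NULL, overrides = list()) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(reconstructionConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  do.call(reconstructionConfig, vals)
}
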