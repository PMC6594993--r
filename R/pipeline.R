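# Reproducible end-to-end runs: each command writes its outputs plus a
# YAML provenance sidecar (parameters, seed, package version) sufficient
# to replay the run exactly.

.provenance <- function(path, record) {
  record$package <- as.character(packageVersion("NeuronSMC"))
  record$rversion <- as.character(getRversion())
  yaml::write_yaml(record, path)
  invisible(path)
}

#' Simulate a fluorescence stack from an SWC file
#'
#' Reads the morphology, renders it at the requested SNR and COR, writes
#' the 8-bit TIFF stack, a copy of the ground-truth SWC next to it, and a
#' YAML metadata sidecar.
#'
#' @param swcPath input SWC morphology.
#' @param out output TIFF path.
#' @param snr,cor image quality factors (see
#'   \code{\link{simulationParams}}).
#' @param shape integer(3) stack extents.
#' @param seed RNG seed.
#' @param voxelAspect voxel aspect of the simulated stack.
#' @param backgroundLevel,supersample forwarded to
#'   \code{\link{simulationParams}}.
#' @return invisibly, a list with the written paths.
#' @export
runSimulate <- function(swcPath, out, snr, cor = 0, shape, seed = 1,
                        voxelAspect = c(1, 1, 1), backgroundLevel = 10,
                        supersample = 2) {
  tree <- readSwc(swcPath, voxelAspect)
  params <- simulationParams(snr = snr, cor = cor,
                             backgroundLevel = backgroundLevel,
                             supersample = supersample,
                             voxelAspect = voxelAspect, seed = seed)
  sim <- simulateStack(tree, shape, params)
  writeTiffStack(sim$volume, out)
  truthOut <- sub("\\.tiff?$", ".truth.swc", out, ignore.case = TRUE)
  if (truthOut == out) truthOut <- paste0(out, ".truth.swc")
  file.copy(swcPath, truthOut, overwrite = TRUE)
  meta <- sub("\\.tiff?$", ".yaml", out, ignore.case = TRUE)
  if (meta == out) meta <- paste0(out, ".yaml")
  .provenance(meta, list(command = "simulate", swc = swcPath, snr = snr,
                         cor = cor, shape = as.integer(shape), seed = seed,
                         backgroundLevel = backgroundLevel,
                         supersample = supersample,
                         voxelAspect = voxelAspect))
  invisible(list(tiff = out, truth = truthOut, metadata = meta))
}

#' Reconstruct a neuron from a TIFF stack
#'
#' Runs the full pipeline on the stack, logging per-stage counts and
#' timing to stderr, and writes the reconstruction as SWC together with a
#' provenance sidecar. With a finite \code{budget} (seconds) the tracing
#' stage stops accepting new seeds at the deadline so the run still
#' completes.
#'
#' @param tiffPath input 8-bit TIFF stack.
#' @param out output SWC path.
#' @param config a \code{\link{reconstructionConfig}}.
#' @param budget wall-clock budget in seconds (Inf to disable).
#' @return invisibly, the reconstructed \code{\link{SwcTree}}.
#' @export
runReconstruct <- function(tiffPath, out,
                           config = reconstructionConfig(),
                           budget = Inf) {
  if (!file.exists(tiffPath)) stop("TIFF stack not found: ", tiffPath)
  vol <- readTiffStack(tiffPath, config$voxelAspect)
  deadline <- if (is.finite(budget)) Sys.time() + budget else NULL
  t0 <- proc.time()[["elapsed"]]
  tree <- reconstructNeuron(vol, config, deadline = deadline,
                            verbose = TRUE)
  message(sprintf("reconstruction finished in %.1f s",
                  proc.time()[["elapsed"]] - t0))
  if (!nNodes(tree)) message("note: reconstruction is empty")
  writeSwc(tree, out)
  meta <- sub("\\.swc$", ".yaml", out)
  if (meta == out) meta <- paste0(out, ".yaml")
  cfg <- unclass(config)
  cfg$scales <- as.numeric(cfg$scales)
  .provenance(meta, c(list(command = "reconstruct", tiff = tiffPath), cfg))
  invisible(tree)
}

#' Score a reconstruction against a gold standard SWC
#'
#' Runs \code{\link{scoreSweep}} over the requested thresholds, writes a
#' CSV report (one row per S) and prints the S = 2 row (or the first
#' requested S) to the console.
#'
#' @param reconPath,truthPath SWC files to compare.
#' @param S thresholds to sweep.
#' @param out optional CSV output path.
#' @param voxelAspect voxel aspect for distances.
#' @return the report data.frame, invisibly.
#' @export
runEvaluate <- function(reconPath, truthPath, S = 2, out = NULL,
                        voxelAspect = c(1, 1, 2)) {
  recon <- readSwc(reconPath, voxelAspect)
  truth <- readSwc(truthPath, voxelAspect)
  rep <- scoreSweep(recon, truth, S, voxelAspect)
  if (!is.null(out)) write.csv(rep, out, row.names = FALSE)
  show <- if (2 %in% S) rep[rep$S == 2, ] else rep[1, ]
  print(show, row.names = FALSE)
  invisible(rep)
}

#' Parameter sweep around a base configuration
#'
#' Reconstructs the stack for every combination of the supplied parameter
#' values (a named list of vectors overriding the base configuration),
#' scores each result at S = 2, and reports the argmax-F and argmin-SSD
#' rows. Individual failures are logged and the sweep continues.
#'
#' @param tiffPath input stack.
#' @param truthPath gold-standard SWC.
#' @param grid named list of parameter value vectors, e.g.
#'   \code{list(tau = c(6, 8, 10))}.
#' @param config base \code{\link{reconstructionConfig}}.
#' @param out optional CSV path for the full result table.
#' @return list with the result table and the best rows by F and SSD.
#' @export
runSweep <- function(tiffPath, truthPath, grid,
                     config = reconstructionConfig(), out = NULL) {
  stopifnot(length(grid) >= 1, !is.null(names(grid)))
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  truth <- readSwc(truthPath, config$voxelAspect)
  vol <- readTiffStack(tiffPath, config$voxelAspect)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    for (nm in names(cells)) cfg[[nm]] <- cells[i, nm]
    row <- tryCatch({
      tree <- reconstructNeuron(vol, cfg)
      sc <- scoreReconstruction(tree, truth, 2, config$voxelAspect)
      cbind(cells[i, , drop = FALSE], sc, failed = FALSE)
    }, error = function(e) {
      message(sprintf("sweep cell %d failed: %s", i, conditionMessage(e)))
      cbind(cells[i, , drop = FALSE],
            S = 2, sd = NA, ssd = NA, pctSsd = NA, precision = NA,
            recall = NA, f = NA, tp = NA, fp = NA, fn = NA,
            ssdDefined = NA, failed = TRUE)
    })
    rows[[i]] <- row
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(out)) write.csv(res, out, row.names = FALSE)
  ok <- which(!res$failed)
  list(results = res,
       bestF = if (length(ok)) res[ok[which.max(res$f[ok])], ] else NULL,
       bestSsd = if (length(ok)) res[ok[which.min(res$ssd[ok])], ] else NULL)
}
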