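#' Score a reconstruction against a gold standard
#'
#' Both trees are densely resampled so adjacent nodes are at most one
#' voxel apart; every reconstruction node is then matched to its nearest
#' gold-standard node and vice versa. Reported are the average minimal
#' reciprocal spatial distance (SD), the substantial spatial distance
#' (SSD: the mean over reciprocal distances larger than the threshold S;
#' 0 with \code{ssdDefined = FALSE} when no node exceeds S), the
#' percentage of such substantially distant nodes (pctSsd), and the
#' node-overlap measures: TP/FP are reconstruction nodes within/beyond S
#' of the gold standard, FN are gold-standard nodes beyond S of the
#' reconstruction, and precision, recall and F follow.
#'
#' @param recon,truth nonempty \code{\link{SwcTree}} objects.
#' @param S spatial distance threshold (voxels); 2 by convention.
#' @param aspect voxel aspect for distances; defaults to the gold
#'   standard's metadata.
#' @return one-row data.frame: S, sd, ssd, pctSsd, precision, recall, f,
#'   tp, fp, fn, ssdDefined.
#' @export
scoreReconstruction <- function(recon, truth, S = 2,
                                aspect = voxelAspect(truth)) {
  stopifnot(is(recon, "SwcTree"), is(truth, "SwcTree"), S > 0)
  if (!nNodes(recon) || !nNodes(truth))
    stop("cannot score an empty tree")
  a <- .treePointCloud(recon, 1)
  b <- .treePointCloud(truth, 1)
  dAB <- nnDistCpp(a, b, aspect)
  dBA <- nnDistCpp(b, a, aspect)
  all <- c(dAB, dBA)
  over <- all > S
  tp <- sum(dAB <= S)
  fp <- sum(dAB > S)
  fn <- sum(dBA > S)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  data.frame(S = S, sd = mean(all),
             ssd = if (any(over)) mean(all[over]) else 0,
             pctSsd = 100 * mean(over),
             precision = precision, recall = recall, f = f,
             tp = tp, fp = fp, fn = fn, ssdDefined = any(over))
}

#' Score a reconstruction over a range of distance thresholds
#'
#' One \code{\link{scoreReconstruction}} row per threshold. On a fixed
#' pair of trees F is non-decreasing and SSD non-decreasing in S.
#'
#' @param recon,truth \code{\link{SwcTree}} objects.
#' @param S numeric vector of positive thresholds.
#' @param aspect voxel aspect for distances.
#' @return data.frame with one row per threshold.
#' @export
scoreSweep <- function(recon, truth, S = c(1, 2, 3, 4, 5, 6),
                       aspect = voxelAspect(truth)) {
  stopifnot(all(S > 0))
  do.call(rbind, lapply(S, function(s)
    scoreReconstruction(recon, truth, s, aspect)))
}
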