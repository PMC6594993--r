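#' Read an SWC morphology file
#'
#' Parses the plain-text SWC format: "#"-prefixed comment lines are
#' ignored, every other non-blank line must hold the seven whitespace
#' separated fields id, type, x, y, z, radius, parent. The record order of
#' the file is preserved and the resulting tree is validated (unique ids,
#' resolvable parents, no cycles, positive radii).
#'
#' @param path path to an SWC file.
#' @param voxelAspect voxel aspect to attach to the tree; defaults to the
#'   1:1:2 convention used when the physical voxel size is unknown.
#' @return an \code{\link{SwcTree}}.
#' @seealso \code{\link{writeSwc}}
#' @export
readSwc <- function(path, voxelAspect = c(1, 1, 2)) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) {
    return(SwcTree(data.frame(id = integer(), type = integer(),
                              x = numeric(), y = numeric(), z = numeric(),
                              radius = numeric(), parent = integer()),
                   voxelAspect))
  }
  parts <- strsplit(trimws(lines[rows]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 7L)
  if (length(bad))
    stop(sprintf("malformed SWC line %d: expected 7 fields, got %d",
                 rows[bad[1]], length(parts[[bad[1]]])))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = 7, byrow = TRUE)
  nabad <- which(apply(m, 1, function(r) any(!is.finite(r))))
  if (length(nabad))
    stop(sprintf("malformed SWC line %d: non-numeric field", rows[nabad[1]]))
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  SwcTree(nodes, voxelAspect)
}

#' Write an SwcTree to an SWC file
#'
#' Nodes are written in their stored order with coordinates and radii at
#' three decimals, so that \code{readSwc(writeSwc(t))} reproduces the tree
#' to printed precision. The tree is re-validated before writing; an
#' invalid structure (e.g. a cycle) is refused.
#'
#' @param tree an \code{\link{SwcTree}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeSwc <- function(tree, path) {
  stopifnot(is(tree, "SwcTree"))
  validObject(tree)
  nd <- swcNodes(tree)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  if (nrow(nd))
    writeLines(sprintf("%d %d %.3f %.3f %.3f %.3f %d",
                       nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius,
                       nd$parent), con)
  invisible(path)
}

# Parent-child edges of a tree as a matrix (x0,y0,z0,r0,x1,y1,z1,r1);
# isolated nodes (roots without children) become degenerate edges so they
# still render as spheres.
.swcEdges <- function(tree) {
  nd <- swcNodes(tree)
  if (!nrow(nd)) return(matrix(numeric(0), ncol = 8))
  pidx <- match(nd$parent, nd$id)
  has <- !is.na(pidx)
  edges <- cbind(nd$x[pidx[has]], nd$y[pidx[has]], nd$z[pidx[has]],
                 nd$radius[pidx[has]],
                 nd$x[has], nd$y[has], nd$z[has], nd$radius[has])
  lonely <- nd$parent == -1 & !nd$id %in% nd$parent
  if (any(lonely)) {
    iso <- cbind(nd$x[lonely], nd$y[lonely], nd$z[lonely], nd$radius[lonely],
                 nd$x[lonely], nd$y[lonely], nd$z[lonely], nd$radius[lonely])
    edges <- rbind(edges, iso)
  }
  edges
}

# Dense point cloud of a tree: every parent-child segment resampled to at
# most `step` spacing; isolated roots contribute their own position.
.treePointCloud <- function(tree, step = 1) {
  nd <- swcNodes(tree)
  asp <- voxelAspect(tree)
  if (!nrow(nd)) return(matrix(numeric(0), ncol = 3))
  pidx <- match(nd$parent, nd$id)
  pts <- list()
  for (i in seq_len(nrow(nd))) {
    if (is.na(pidx[i])) {
      pts[[length(pts) + 1L]] <- matrix(c(nd$x[i], nd$y[i], nd$z[i]), ncol = 3)
    } else {
      j <- pidx[i]
      seg <- rbind(c(nd$x[j], nd$y[j], nd$z[j]), c(nd$x[i], nd$y[i], nd$z[i]))
      pts[[length(pts) + 1L]] <-
        .resamplePath(seg, cbind(c(0, 0)), step, asp)$points
    }
  }
  do.call(rbind, pts)
}
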