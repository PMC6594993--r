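#' Accessors for NeuronSMC data classes
#'
#' \code{swcNodes} returns the node table of an \code{SwcTree};
#' \code{volumeData} the array of an \code{IntensityVolume};
#' \code{voxelAspect} the x:y:z voxel scaling of either;
#' \code{nNodes} the number of SWC nodes.
#'
#' @param x an \code{SwcTree} or \code{IntensityVolume}.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("swcNodes", function(x) standardGeneric("swcNodes"))

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname accessors
#' @export
setGeneric("voxelAspect", function(x) standardGeneric("voxelAspect"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setMethod("swcNodes", "SwcTree", function(x) x@nodes)

#' @rdname accessors
#' @export
setMethod("volumeData", "IntensityVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelAspect", "SwcTree", function(x) x@voxelAspect)

#' @rdname accessors
#' @export
setMethod("voxelAspect", "IntensityVolume", function(x) x@voxelAspect)

#' @rdname accessors
#' @export
setMethod("nNodes", "SwcTree", function(x) nrow(x@nodes))

setMethod("show", "SwcTree", function(object) {
  nd <- object@nodes
  nroot <- sum(nd$parent == -1)
  cat(sprintf("SwcTree with %d node(s), %d root(s), voxel aspect %s\n",
              nrow(nd), nroot,
              paste(format(object@voxelAspect), collapse = ":")))
  if (nrow(nd)) {
    print(head(nd, 5))
    if (nrow(nd) > 5) cat(sprintf("... and %d more\n", nrow(nd) - 5))
  }
  invisible(NULL)
})

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "IntensityVolume %d x %d x %d, range [%g, %g], voxel aspect %s\n",
    d[1], d[2], d[3], min(object@data), max(object@data),
    paste(format(object@voxelAspect), collapse = ":")))
  invisible(NULL)
})

setMethod("show", "SomaModel", function(object) {
  if (object@found)
    cat(sprintf("SomaModel: center (%.2f, %.2f, %.2f), radius %.2f\n",
                object@center[1], object@center[2], object@center[3],
                object@radius))
  else cat("SomaModel: no soma found\n")
  invisible(NULL)
})
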