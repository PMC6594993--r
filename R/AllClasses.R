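#' SwcTree: a neuron morphology in SWC node form
#'
#' An ordered set of SWC records (id, type, x, y, z, radius, parent)
#' forming one or more rooted trees, together with the x:y:z voxel aspect
#' of the image the coordinates live in. Coordinates are voxel units,
#' 0-based, with a node at integer position lying at the center of that
#' voxel. When the physical voxel size is unknown the conventional
#' fluorescence-stack default aspect 1:1:2 is assumed.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent}.
#' @slot voxelAspect numeric(3), positive per-axis physical scaling applied
#'   to coordinate differences before distances are computed.
#' @aliases SwcTree-class
#' @exportClass SwcTree
setClass("SwcTree",
  representation(nodes = "data.frame", voxelAspect = "numeric"),
  prototype(
    nodes = data.frame(id = integer(), type = integer(), x = numeric(),
                       y = numeric(), z = numeric(), radius = numeric(),
                       parent = integer()),
    voxelAspect = c(1, 1, 2)
  )
)

.validSwcTree <- function(object) {
  nd <- object@nodes
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  if (length(object@voxelAspect) != 3 || any(object@voxelAspect <= 0))
    return("voxelAspect must be 3 positive scalars")
  if (nrow(nd) == 0) return(TRUE)
  if (anyDuplicated(nd$id)) return("node ids must be unique")
  if (any(nd$id <= 0)) return("node ids must be positive")
  if (any(!is.finite(nd$radius)) || any(nd$radius <= 0))
    return("node radii must be positive")
  nonroot <- nd$parent != -1
  if (any(!nd$parent[nonroot] %in% nd$id))
    return(sprintf("dangling parent id(s): %s",
                   paste(setdiff(nd$parent[nonroot], nd$id), collapse = ", ")))
  if (any(nd$parent == nd$id)) return("node cannot be its own parent")
  # cycle check: walk each node to a root, memoizing resolved nodes
  idx <- match(nd$parent, nd$id)          # NA for roots
  state <- integer(nrow(nd))              # 0 unseen, 1 on path, 2 done
  for (s in seq_len(nrow(nd))) {
    if (state[s] == 2L) next
    path <- integer(0)
    k <- s
    repeat {
      if (is.na(k) || state[k] == 2L) break
      if (state[k] == 1L) return("parent links contain a cycle")
      state[k] <- 1L
      path <- c(path, k)
      k <- idx[k]
    }
    state[path] <- 2L
  }
  TRUE
}
setValidity("SwcTree", .validSwcTree)

#' Construct an SwcTree
#'
#' @param nodes data.frame with columns id, type, x, y, z, radius, parent
#'   (parent is -1 for a root).
#' @param voxelAspect positive numeric(3); x:y:z physical voxel scaling.
#'   Defaults to the 1:1:2 convention used when the voxel size is unknown.
#' @return a validated \code{SwcTree}.
#' @examples
#' nd <- data.frame(id = 1:2, type = c(1L, 3L), x = c(0, 3), y = 0, z = 0,
#'                  radius = c(2, 1), parent = c(-1L, 1L))
#' SwcTree(nd, voxelAspect = c(1, 1, 1))
#' @export
SwcTree <- function(nodes, voxelAspect = c(1, 1, 2)) {
  nodes <- as.data.frame(nodes)
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  new("SwcTree", nodes = nodes, voxelAspect = as.numeric(voxelAspect))
}

#' IntensityVolume: a 3D grayscale image stack
#'
#' A 3D grid of scalar intensities with voxel aspect metadata; the image
#' being traced or simulated. Array dimensions are (x, y, z).
#'
#' @slot data 3D numeric array.
#' @slot voxelAspect numeric(3), positive per-axis physical scaling.
#' @aliases IntensityVolume-class
#' @exportClass IntensityVolume
setClass("IntensityVolume",
  representation(data = "array", voxelAspect = "numeric")
)

setValidity("IntensityVolume", function(object) {
  if (length(dim(object@data)) != 3) return("data must be a 3D array")
  if (length(object@voxelAspect) != 3 || any(object@voxelAspect <= 0))
    return("voxelAspect must be 3 positive scalars")
  TRUE
})

#' Construct an IntensityVolume
#'
#' @param data 3D numeric array with dimensions (x, y, z).
#' @param voxelAspect positive numeric(3).
#' @return an \code{IntensityVolume}.
#' @export
IntensityVolume <- function(data, voxelAspect = c(1, 1, 2)) {
  new("IntensityVolume", data = data, voxelAspect = as.numeric(voxelAspect))
}

#' SomaModel: the detected cell body as a single sphere
#'
#' @slot center numeric(3), voxel coordinates of the blob centroid.
#' @slot radius average distance of the blob voxels to the centroid.
#' @slot found logical; FALSE when no acceptable soma blob was detected.
#' @aliases SomaModel-class
#' @exportClass SomaModel
setClass("SomaModel",
  representation(center = "numeric", radius = "numeric", found = "logical"),
  prototype(center = c(NA_real_, NA_real_, NA_real_), radius = NA_real_,
            found = FALSE)
)

setValidity("SomaModel", function(object) {
  if (object@found && (!is.finite(object@radius) || object@radius <= 0))
    return("radius must be positive when a soma was found")
  TRUE
})

#' @rdname SomaModel-class
#' @param center,radius,found see slots.
#' @export
SomaModel <- function(center = c(NA_real_, NA_real_, NA_real_),
                      radius = NA_real_, found = FALSE) {
  new("SomaModel", center = as.numeric(center), radius = as.numeric(radius),
      found = found)
}
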