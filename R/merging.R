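# Traces are merged in three stages: mean-shift refinement of the
# accumulated (1-voxel resampled) trace nodes, greedy grouping of refined
# nodes into representative group nodes, and breadth-first construction of
# the final SWC tree.

# Flatten a list of trace data.frames (x,y,z,r,c) into one node table
# plus the symmetric link set (consecutive nodes within each trace).
.assembleNodes <- function(traces) {
  if (!length(traces)) {
    return(list(nodes = data.frame(x = numeric(), y = numeric(),
                                   z = numeric(), r = numeric(),
                                   c = numeric()),
                edges = matrix(integer(0), ncol = 2)))
  }
  nodes <- do.call(rbind, traces)
  rownames(nodes) <- NULL
  sizes <- vapply(traces, nrow, 1L)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  edges <- do.call(rbind, lapply(seq_along(traces), function(t) {
    n <- sizes[t]
    if (n < 2) return(matrix(integer(0), ncol = 2))
    cbind(offs[t] + seq_len(n - 1L), offs[t] + seq_len(n - 1L) + 1L)
  }))
  list(nodes = nodes, edges = edges)
}

# Resample every trace to at most `step` node spacing, interpolating
# radius and correlation.
.resampleTraces <- function(traces, step = 1, aspect = c(1, 1, 1)) {
  lapply(traces, function(tr) {
    res <- .resamplePath(as.matrix(tr[, c("x", "y", "z")]),
                         as.matrix(tr[, c("r", "c")]), step, aspect)
    data.frame(x = res$points[, 1], y = res$points[, 2],
               z = res$points[, 3], r = res$values[, 1],
               c = res$values[, 2])
  })
}

#' Mean-shift refinement of trace nodes
#'
#' Iteratively replaces every node's position, radius and correlation by
#' the unweighted mean over the nodes within its own initial radius (flat
#' kernel, anisotropy-aware distance). Updates within an iteration are
#' synchronous: all nodes move against the previous iteration's values.
#' Node count and linking are unchanged -- refinement only sharpens the
#' estimates; five iterations suffice in practice for radial alignment of
#' redundant traces.
#'
#' @param nodes data.frame with columns x, y, z, r, c.
#' @param iterations number of mean-shift iterations.
#' @param aspect voxel aspect for distances.
#' @return the refined node data.frame (same rows, same order).
#' @export
meanShiftRefine <- function(nodes, iterations = 5, aspect = c(1, 1, 1)) {
  if (!nrow(nodes) || iterations == 0) return(nodes)
  res <- meanShiftCpp(as.matrix(nodes[, c("x", "y", "z")]), nodes$r,
                      nodes$c, as.integer(iterations), aspect)
  data.frame(x = res$pos[, 1], y = res$pos[, 2], z = res$pos[, 3],
             r = res$r, c = res$c)
}

#' Greedy grouping of refined nodes
#'
#' Repeatedly takes the ungrouped node with the highest correlation (ties
#' toward the lower index), claims every still-ungrouped node within
#' Euclidean distance \code{rg} of it as one group, and averages the
#' member fields without weighting. Links between refined nodes are
#' projected onto their groups, so all inter-node connectivity is
#' preserved in the group graph.
#'
#' @param nodes refined node data.frame (x, y, z, r, c).
#' @param edges integer matrix of symmetric refined-node links (i, j).
#' @param rg grouping radius (voxels).
#' @param aspect voxel aspect for distances.
#' @return list with \code{nodes} (group table: x, y, z, r, c, size),
#'   \code{edges} (inter-group links), and \code{membership} (group id
#'   per refined node).
#' @export
groupNodes <- function(nodes, edges, rg = 2, aspect = c(1, 1, 1)) {
  if (!nrow(nodes)) {
    return(list(nodes = cbind(nodes, size = integer(0)),
                edges = matrix(integer(0), ncol = 2),
                membership = integer(0)))
  }
  stopifnot(rg > 0)
  ord <- order(-nodes$c, seq_len(nrow(nodes))) - 1L
  grp <- groupNodesCpp(as.matrix(nodes[, c("x", "y", "z")]), ord, rg,
                       aspect)
  ng <- max(grp)
  agg <- function(v) as.numeric(rowsum(v, grp)) / tabulate(grp, ng)
  gnodes <- data.frame(x = agg(nodes$x), y = agg(nodes$y),
                       z = agg(nodes$z), r = agg(nodes$r),
                       c = agg(nodes$c), size = tabulate(grp, ng))
  gedges <- matrix(integer(0), ncol = 2)
  if (nrow(edges)) {
    ge <- cbind(grp[edges[, 1]], grp[edges[, 2]])
    ge <- ge[ge[, 1] != ge[, 2], , drop = FALSE]
    if (nrow(ge)) {
      ge <- t(apply(ge, 1, sort))
      gedges <- unique(ge)
    }
  }
  list(nodes = gnodes, edges = gedges, membership = grp)
}

#' Build the final SWC tree from group nodes
#'
#' Breadth-first traversal of the group graph. The root is the detected
#' soma (written as a type-1 sphere, with every group center within
#' soma radius + group radius attached to it) or, when no soma was found,
#' the group node with the highest correlation. Each visited node is
#' parented by its discoverer, which drops cycle back-edges. Unvisited
#' connected components with at least \code{minComponent} groups are
#' emitted as additional roots; smaller ones are discarded as isolated
#' false positives. With \code{prune}, single-node terminal twigs
#' (leaves hanging off a through-path or junction) are removed.
#'
#' @param groups result of \code{\link{groupNodes}}.
#' @param soma a \code{\link{SomaModel}}.
#' @param aspect voxel aspect recorded in the output tree.
#' @param minComponent minimum size of a disconnected component to keep.
#' @param prune drop single-node terminal branches.
#' @return an \code{\link{SwcTree}}.
#' @export
buildTree <- function(groups, soma = SomaModel(), aspect = c(1, 1, 1),
                      minComponent = 3, prune = TRUE) {
  gn <- groups$nodes
  ng <- nrow(gn)
  if (!ng) {
    warning("no group nodes: returning empty tree")
    return(SwcTree(data.frame(id = integer(), type = integer(),
                              x = numeric(), y = numeric(), z = numeric(),
                              radius = numeric(), parent = integer()),
                   aspect))
  }
  adj <- vector("list", ng)
  if (nrow(groups$edges)) {
    for (k in seq_len(nrow(groups$edges))) {
      i <- groups$edges[k, 1]; j <- groups$edges[k, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
    adj <- lapply(adj, function(a) sort(unique(a)))
  }
  parent <- rep(NA_integer_, ng)   # 0 = component root
  compRoot <- integer(0)
  visited <- rep(FALSE, ng)
  bfs <- function(starts) {
    q <- starts
    visited[starts] <<- TRUE
    order <- integer(0)
    while (length(q)) {
      cur <- q[1]; q <- q[-1]
      order <- c(order, cur)
      for (nb in adj[[cur]]) {
        if (!visited[nb]) {
          visited[nb] <<- TRUE
          parent[nb] <<- cur
          q <- c(q, nb)
        }
      }
    }
    order
  }

  useSoma <- soma@found
  if (useSoma) {
    d <- sqrt(colSums((t(as.matrix(gn[, c("x", "y", "z")])) -
                         soma@center)^2 * aspect^2))
    attached <- which(d <= soma@radius + gn$r)
    if (!length(attached)) {
      # soma disconnected from every trace: fall back to the best group
      useSoma <- FALSE
    } else {
      parent[attached] <- 0L
      visitOrder <- bfs(attached)
    }
  }
  if (!useSoma) {
    start <- which.max(gn$c)
    parent[start] <- 0L
    compRoot <- start
    visitOrder <- bfs(start)
  }
  # remaining components, largest-correlation node first
  repeat {
    left <- which(!visited)
    if (!length(left)) break
    start <- left[which.max(gn$c[left])]
    parent[start] <- 0L
    comp <- bfs(start)
    if (length(comp) >= minComponent) {
      compRoot <- c(compRoot, start)
      visitOrder <- c(visitOrder, comp)
    } else {
      parent[comp] <- NA_integer_  # discarded
    }
  }

  keep <- !is.na(parent)
  if (prune && any(keep)) {
    # degree within the emitted tree (parent links only)
    childCount <- tabulate(parent[keep][parent[keep] > 0], ng)
    deg <- childCount
    hasPar <- keep & parent > 0
    deg[hasPar] <- deg[hasPar]  # children already counted
    degOf <- function(i) childCount[i] + (parent[i] > 0)
    leaves <- which(keep & childCount == 0 & parent > 0)
    spur <- leaves[vapply(leaves, function(l) degOf(parent[l]) >= 3, TRUE)]
    keep[spur] <- FALSE
  }

  emit <- intersect(visitOrder, which(keep))
  if (!length(emit) && !useSoma) {
    warning("all group nodes pruned: returning empty tree")
    return(SwcTree(data.frame(id = integer(), type = integer(),
                              x = numeric(), y = numeric(), z = numeric(),
                              radius = numeric(), parent = integer()),
                   aspect))
  }
  idOf <- integer(ng)
  rows <- list()
  nextId <- 1L
  if (useSoma) {
    rows[[nextId]] <- data.frame(id = 1L, type = 1L, x = soma@center[1],
                                 y = soma@center[2], z = soma@center[3],
                                 radius = soma@radius, parent = -1L)
    somaId <- 1L
    nextId <- 2L
  }
  for (g in emit) {
    idOf[g] <- nextId
    par <- if (parent[g] == 0L) {
      if (useSoma) somaId else -1L
    } else idOf[parent[g]]
    rows[[nextId]] <- data.frame(id = nextId, type = 3L, x = gn$x[g],
                                 y = gn$y[g], z = gn$z[g],
                                 radius = gn$r[g], parent = par)
    nextId <- nextId + 1L
  }
  SwcTree(do.call(rbind, rows), aspect)
}

#' Reconstruct a neuron from an image stack
#'
#' The full pipeline: soma extraction, seed extraction, particle-filter
#' tracing of every seed in both directions, 1-voxel trace resampling,
#' mean-shift refinement, greedy node grouping, and breadth-first tree
#' construction. Deterministic for a fixed \code{config$seed}.
#'
#' @param volume an \code{\link{IntensityVolume}}.
#' @param config a \code{\link{reconstructionConfig}} object.
#' @param deadline optional wall-clock deadline passed to the tracer.
#' @param verbose log per-stage counts to stderr.
#' @return an \code{\link{SwcTree}}.
#' @export
reconstructNeuron <- function(volume, config = reconstructionConfig(),
                              deadline = NULL, verbose = FALSE) {
  stopifnot(is(volume, "IntensityVolume"))
  set.seed(config$seed)
  asp <- voxelAspect(volume)
  log <- function(...) if (verbose) message(sprintf(...))

  soma <- extractSoma(volume, somaParams(config$rs))
  log("soma: %s", if (soma@found) "found" else "none")

  sp <- seedParams(scales = config$scales, tau = config$tau,
                   cMin = config$cMin)
  seeds <- extractSeeds(volume, sp)
  log("seeds: %d", nrow(seeds))
  if (!nrow(seeds)) {
    warning("no seeds: returning empty tree")
    return(SwcTree(data.frame(id = integer(), type = integer(),
                              x = numeric(), y = numeric(), z = numeric(),
                              radius = numeric(), parent = integer()),
                   asp))
  }
  tp <- tracerParams(N = config$N, kappa = config$kappa, d = config$d,
                     zeta = config$zeta, K = config$K, cMin = config$cMin,
                     L = config$L, deltaN = config$deltaN, n = config$n,
                     sigmaMax = max(config$scales) + 3 * config$zeta)
  traced <- traceAll(seeds, volume, tp, deadline)
  log("traces: %d (%d nodes)", length(traced$traces),
      sum(vapply(traced$traces, nrow, 1L)))

  resampled <- .resampleTraces(traced$traces, 1, asp)
  acc <- .assembleNodes(resampled)
  refined <- meanShiftRefine(acc$nodes, config$meanShiftIterations, asp)
  groups <- groupNodes(refined, acc$edges, config$rg, asp)
  log("refined nodes: %d -> groups: %d", nrow(refined), nrow(groups$nodes))

  tree <- buildTree(groups, soma, asp, config$minComponent, config$prune)
  log("tree nodes: %d", nNodes(tree))
  tree
}
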