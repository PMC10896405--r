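#' 1-ring adjacency list of a mesh
#'
#' Graph edges are mesh edges: two vertices are adjacent iff they share a
#' triangle edge.
#'
#' @param mesh a \linkS4class{TopoMesh}.
#' @return list of sorted integer neighbor vectors, one per vertex.
#' @export
graphAdjacency <- function(mesh) {
  n <- nVertices(mesh)
  f <- mesh@faces
  if (!nrow(f)) return(rep(list(integer()), n))
  ii <- c(f[, 1], f[, 2], f[, 3], f[, 2], f[, 3], f[, 1])
  jj <- c(f[, 2], f[, 3], f[, 1], f[, 1], f[, 2], f[, 3])
  adj <- split(jj, factor(ii, levels = seq_len(n)))
  lapply(adj, function(v) sort(unique(v)))
}

## Breadth-first ball: all vertices within `depth` hops of `start` (inclusive).
.bfsBall <- function(adj, start, depth) {
  seen <- start
  frontier <- start
  if (depth >= 1L) for (h in seq_len(depth)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

## Greedy stride-s cover: repeatedly retain the lowest-index unmarked vertex
## and mark everything within hop distance < s. Ties broken by vertex index;
## fully deterministic.
.strideSelect <- function(adj, stride) {
  n <- length(adj)
  marked <- logical(n)
  retained <- integer()
  for (v in seq_len(n)) {
    if (marked[v]) next
    retained <- c(retained, v)
    marked[.bfsBall(adj, v, stride - 1L)] <- TRUE
  }
  retained
}

.buildLevel <- function(adj, radius, stride) {
  retained <- .strideSelect(adj, stride)
  neighborhoods <- lapply(retained, function(v) sort(.bfsBall(adj, v, radius)))
  covered <- unique(unlist(neighborhoods, use.names = FALSE))
  if (length(covered) < length(adj))
    .stopCond("shapecompHierarchyError",
              sprintf("level leaves %d parent vertices uncovered (radius %d too small for stride %d)",
                      length(adj) - length(covered), radius, stride))
  # child graph: retained u ~ v iff parent hop distance <= 2*stride - 1;
  # keeps the decimated graph connected whenever the parent graph is.
  reach <- 2L * stride - 1L
  pos <- integer(length(adj)); pos[retained] <- seq_along(retained)
  childAdj <- lapply(retained, function(v) {
    ball <- .bfsBall(adj, v, reach)
    hits <- pos[ball[pos[ball] > 0L]]
    sort(setdiff(hits, pos[v]))
  })
  new("GraphLevel", vertexIds = as.integer(retained),
      neighborhoods = neighborhoods,
      radius = as.integer(radius), stride = as.integer(stride),
      childAdjacency = childAdj)
}

#' Build the multi-level graph hierarchy for mesh convolution
#'
#' Deterministic decimation of the template graph, computed once per topology
#' in a preprocessing step: at each level a greedy breadth-first cover retains
#' a subset of parent vertices (stride), and each retained vertex is assigned
#' the parent vertices within \code{radius} hops as its convolution support.
#' Every parent vertex is covered by at least one retained neighborhood.
#'
#' @param mesh a connected \linkS4class{TopoMesh} (or pass an adjacency list
#'   via \code{buildHierarchyGraph} for non-mesh graphs).
#' @param nLevels number of decimation levels.
#' @param radius,stride hop counts, both >= 1; \code{radius >= stride - 1} is
#'   required so neighborhoods cover the parent set. Default 2 and 2.
#' @return a \linkS4class{GraphHierarchy}.
#' @export
buildHierarchy <- function(mesh, nLevels, radius = 2L, stride = 2L) {
  buildHierarchyGraph(graphAdjacency(mesh), nLevels, radius, stride,
                      topologyId = mesh@topologyId)
}

#' @rdname buildHierarchy
#' @param adjacency list of integer neighbor vectors (1-based), one per vertex.
#' @param topologyId token recorded on the hierarchy.
#' @export
buildHierarchyGraph <- function(adjacency, nLevels, radius = 2L, stride = 2L,
                                topologyId = "graph") {
  stopifnot(nLevels >= 1, radius >= 1, stride >= 1)
  if (radius < stride - 1L)
    .stopCond("shapecompHierarchyError",
              "radius must be >= stride - 1 so neighborhoods cover every parent vertex")
  n0 <- length(adjacency)
  levels <- vector("list", nLevels)
  sizes <- integer(nLevels + 1L); sizes[1] <- n0
  adj <- adjacency
  for (l in seq_len(nLevels)) {
    lev <- .buildLevel(adj, radius, stride)
    if (stride > 1L && length(lev@vertexIds) >= length(adj))
      .stopCond("shapecompHierarchyError",
                sprintf("hierarchy failed at level %d: %d vertices cannot be decimated further",
                        l, length(adj)))
    levels[[l]] <- lev
    sizes[l + 1L] <- length(lev@vertexIds)
    adj <- lev@childAdjacency
  }
  new("GraphHierarchy", topologyId = topologyId, nVertices = as.integer(n0),
      levels = levels, levelSizes = sizes)
}

#' Save / load a graph hierarchy archive
#'
#' Single JSON archive keyed by topology and (radius, stride, nLevels), so a
#' hierarchy can be precomputed once per template and reused.
#'
#' @param hierarchy a \linkS4class{GraphHierarchy}.
#' @param path archive path (JSON).
#' @return \code{saveHierarchy}: path invisibly; \code{loadHierarchy}: the
#'   \linkS4class{GraphHierarchy}.
#' @export
saveHierarchy <- function(hierarchy, path) {
  lv <- lapply(hierarchy@levels, function(l) list(
    vertexIds = l@vertexIds, neighborhoods = l@neighborhoods,
    radius = l@radius, stride = l@stride, childAdjacency = l@childAdjacency))
  key <- list(topologyId = hierarchy@topologyId,
              nVertices = hierarchy@nVertices,
              nLevels = length(hierarchy@levels),
              radius = hierarchy@levels[[1]]@radius,
              stride = hierarchy@levels[[1]]@stride)
  jsonlite::write_json(list(key = key, levelSizes = hierarchy@levelSizes,
                            levels = lv),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveHierarchy
#' @export
loadHierarchy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  levels <- lapply(x$levels, function(l) new(
    "GraphLevel", vertexIds = as.integer(l$vertexIds),
    neighborhoods = lapply(l$neighborhoods, as.integer),
    radius = as.integer(l$radius), stride = as.integer(l$stride),
    childAdjacency = lapply(l$childAdjacency, as.integer)))
  new("GraphHierarchy", topologyId = x$key$topologyId,
      nVertices = as.integer(x$key$nVertices), levels = levels,
      levelSizes = as.integer(x$levelSizes))
}
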