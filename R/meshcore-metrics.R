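#' Mean per-vertex reconstruction error between two meshes (mm)
#'
#' The geometric mean absolute error used throughout to score shape-model
#' reconstructions: the mean over vertices of the Euclidean distance between
#' corresponding vertex positions. Defined over vertex positions (not over the
#' 3N scalar coordinates), so a uniform 1 mm translation gives exactly 1 mm.
#'
#' @param a,b \linkS4class{TopoMesh} objects sharing a topology.
#' @return nonnegative scalar, mm.
#' @export
vertexMAE <- function(a, b) {
  stopifnot(is(a, "TopoMesh"), is(b, "TopoMesh"))
  if (a@topologyId != b@topologyId)
    .stopCond("shapecompTopologyError",
              sprintf("topology mismatch: '%s' vs '%s'", a@topologyId, b@topologyId))
  d <- a@vertices - b@vertices
  mean(sqrt(rowSums(d * d)))
}

## Coordinate flattening used by every shape model: vertex-major
## (x1, y1, z1, x2, y2, z2, ...).
flattenVertices <- function(v) as.numeric(t(v))

unflattenVertices <- function(x) matrix(x, ncol = 3, byrow = TRUE)

## Bounding-box diagonal, the scale reference for relative-error thresholds.
meshDiameter <- function(mesh) {
  r <- apply(mesh@vertices, 2, range)
  sqrt(sum((r[2, ] - r[1, ])^2))
}
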