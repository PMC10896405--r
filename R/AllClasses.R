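#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal forceSymmetric Cholesky mat2triplet
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Fixed-topology triangle mesh
#'
#' The atomic observation of the pipeline: vertex coordinates (in mm) on a
#' triangulation shared by every mesh in a dataset. Meshes that share a
#' \code{topologyId} are guaranteed to have identical face lists and vertex
#' counts, so vertex \code{i} corresponds anatomically across subjects.
#'
#' @slot vertices numeric N x 3 matrix of coordinates in mm.
#' @slot faces integer F x 3 matrix of 1-based vertex indices.
#' @slot topologyId single string naming the shared triangulation.
#' @export
setClass("TopoMesh", representation(
  vertices = "matrix",
  faces = "matrix",
  topologyId = "character"
))

setValidity("TopoMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must be an N x 3 matrix")
  if (!all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f) > 0L) {
    if (ncol(f) != 3L) return("faces must be an F x 3 matrix")
    if (min(f) < 1L || max(f) > nrow(v))
      return("face indices out of range [1, N]")
  }
  if (length(object@topologyId) != 1L) return("topologyId must be a single string")
  TRUE
})

#' One level of a mesh graph hierarchy
#'
#' Describes the transition from a parent vertex set to a decimated child set:
#' which parent vertices are retained, and for each retained vertex the parent
#' vertices within \code{radius} hops that its convolution kernel covers.
#'
#' @slot vertexIds integer indices (into the parent level) of retained vertices.
#' @slot neighborhoods list, one integer vector of parent indices per retained
#'   vertex (graph distance <= radius on the parent edge graph).
#' @slot radius,stride integer hop counts.
#' @slot childAdjacency adjacency list among retained vertices (child indexing),
#'   used to build the next level.
#' @export
setClass("GraphLevel", representation(
  vertexIds = "integer",
  neighborhoods = "list",
  radius = "integer",
  stride = "integer",
  childAdjacency = "list"
))

#' Multi-level graph hierarchy for mesh convolution
#'
#' Precomputed once per mesh template: an ordered list of \linkS4class{GraphLevel}
#' objects from full resolution down to the bottleneck, deterministic given the
#' topology and (radius, stride, n_levels).
#'
#' @slot topologyId topology the hierarchy was built for.
#' @slot nVertices full-resolution vertex count.
#' @slot levels list of \linkS4class{GraphLevel}.
#' @slot levelSizes integer vector: vertex count per level, full resolution first.
#' @export
setClass("GraphHierarchy", representation(
  topologyId = "character",
  nVertices = "integer",
  levels = "list",
  levelSizes = "integer"
))

setValidity("GraphHierarchy", function(object) {
  s <- object@levelSizes
  if (length(s) != length(object@levels) + 1L)
    return("levelSizes must have one more entry than levels")
  if (s[1] != object@nVertices) return("levelSizes[1] must equal nVertices")
  if (length(s) > 1L) {
    d <- diff(s)
    strides <- vapply(object@levels, function(l) l@stride, integer(1))
    if (any(d > 0L)) return("levelSizes must be nonincreasing")
    if (any(d == 0L & strides > 1L))
      return("levelSizes must strictly decrease at stride > 1 levels")
  }
  TRUE
})

#' Linear (PCA) statistical shape model
#'
#' PCA over flattened vertex coordinates (vertex-major order x1,y1,z1,x2,...),
#' the linear baseline shape model. Components are the top-d right singular
#' vectors of the mean-centered data matrix, sign-fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @slot meanShape numeric 3N vector (mm).
#' @slot components d x 3N matrix with orthonormal rows.
#' @slot explainedVariance per-component variance, nonincreasing.
#' @slot d number of components retained.
#' @slot faces,topologyId template triangulation used to rebuild meshes.
#' @export
setClass("PCAShapeModel", representation(
  meanShape = "numeric",
  components = "matrix",
  explainedVariance = "numeric",
  d = "integer",
  faces = "matrix",
  topologyId = "character"
))

setValidity("PCAShapeModel", function(object) {
  if (nrow(object@components) != object@d) return("components must have d rows")
  if (length(object@explainedVariance) != object@d)
    return("explainedVariance must have length d")
  if (is.unsorted(rev(object@explainedVariance)))
    return("explainedVariance must be nonincreasing")
  G <- tcrossprod(object@components)
  if (max(abs(G - diag(nrow(G)))) > 1e-8)
    return("component rows must be orthonormal")
  TRUE
})

#' Graph convolutional mesh autoencoder
#'
#' A symmetric encoder/decoder over a fixed \linkS4class{GraphHierarchy} with
#' spatially varying convolution kernels: each edge weight is a learned
#' combination of M shared basis matrices. The flattened bottleneck activation
#' is the latent shape code.
#'
#' @slot hierarchy the precomputed \linkS4class{GraphHierarchy}.
#' @slot config list: channelPlan, bottleneckChannels, M, activation, and the
#'   input centering/scaling statistics.
#' @slot layers list of layer descriptors (triplet indices + weight shapes).
#' @slot weights list of layer weights (basis array, coeffs, bias).
#' @slot faces,topologyId template triangulation.
#' @export
setClass("MeshAutoencoder", representation(
  hierarchy = "GraphHierarchy",
  config = "list",
  layers = "list",
  weights = "list",
  faces = "matrix",
  topologyId = "character"
))

#' Gaussian process regression model with a squared dot-product kernel
#'
#' Posterior-mean GPR with kernel k(x, z) = (sigma0^2 + x.z)^2, equivalent to
#' Bayesian regression over degree-2 polynomials of the features: the model
#' class matched to shape-to-composition maps that are nonlinear but monotone
#' in first and second derivatives.
#'
#' @slot Xtrain standardized training features (n x p).
#' @slot dual (K + alpha I)^-1 y, one column per target (n x T).
#' @slot sigma0,alpha kernel inhomogeneity and observation-noise jitter.
#' @slot xCenter,xScale,yCenter,yScale standardization statistics.
#' @slot targetNames character vector of target variables.
#' @export
setClass("GPRModel", representation(
  Xtrain = "matrix",
  dual = "matrix",
  sigma0 = "numeric",
  alpha = "numeric",
  xCenter = "numeric",
  xScale = "numeric",
  yCenter = "numeric",
  yScale = "numeric",
  targetNames = "character"
))

#' Ordinary least squares regression model (minimum-norm)
#'
#' Linear baseline fitted by pseudoinverse so that underdetermined systems
#' (more features than subjects, e.g. 4284 shape coefficients) get the
#' minimum-norm solution. Intercept included.
#'
#' @slot coef (p + 1) x T coefficient matrix, intercept first.
#' @slot xCenter,xScale standardization statistics (identity if unscaled).
#' @slot targetNames character vector of target variables.
#' @export
setClass("OLSModel", representation(
  coef = "matrix",
  xCenter = "numeric",
  xScale = "numeric",
  targetNames = "character"
))

#' Cohort of subjects with meshes, demographics and composition targets
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: the single assay
#' \code{"coords"} holds flattened vertex coordinates (3N rows, one column per
#' scan); \code{colData} carries subject id, sex, height (cm), weight (kg),
#' age (years), scan index (1 or 2 for same-day duplicates), split membership
#' (pretrain / finetune / eval / test) and the ten composition targets.
#' \code{metadata} stores the template mesh, generator config and ground truth.
#'
#' @export
setClass("ShapeCohort", contains = "SummarizedExperiment")

setValidity("ShapeCohort", function(object) {
  if (!"coords" %in% assayNames(object)) return("assay 'coords' is required")
  need <- c("subject_id", "sex", "height", "weight", "age", "scan", "split")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss)) return(paste("colData missing columns:", paste(miss, collapse = ", ")))
  if (nrow(assay(object, "coords")) %% 3L != 0L)
    return("coords must have 3N rows")
  TRUE
})

setMethod("show", "TopoMesh", function(object) {
  cat("TopoMesh:", nrow(object@vertices), "vertices,", nrow(object@faces),
      "faces, topology", object@topologyId, "\n")
})

setMethod("show", "GraphHierarchy", function(object) {
  cat("GraphHierarchy on topology", object@topologyId, "\n",
      "level sizes:", paste(object@levelSizes, collapse = " -> "), "\n")
})

setMethod("show", "PCAShapeModel", function(object) {
  cat("PCAShapeModel: d =", object@d, "components over",
      length(object@meanShape) / 3, "vertices\n")
})

setMethod("show", "MeshAutoencoder", function(object) {
  cfg <- object@config
  cat("MeshAutoencoder:", length(object@hierarchy@levels), "levels,",
      "channels [", paste(cfg$channelPlan, collapse = ", "), "],",
      "bottleneck", cfg$bottleneckChannels, "ch x",
      rev(object@hierarchy@levelSizes)[1], "vertices =",
      latentSize(object), "latents\n")
})

setMethod("show", "GPRModel", function(object) {
  cat("GPRModel: squared dot-product kernel, sigma0 =", object@sigma0,
      ", alpha =", object@alpha, ",", nrow(object@Xtrain), "training points,",
      length(object@targetNames), "targets\n")
})
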