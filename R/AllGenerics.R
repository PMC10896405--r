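#' @importFrom stats predict
#' @export
setGeneric("predict")

#' Accessors for mesh and model objects
#'
#' @param x object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname accessors
#' @export
setGeneric("topologyId", function(x) standardGeneric("topologyId"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @export
setMethod("meshVertices", "TopoMesh", function(x) x@vertices)
#' @export
setMethod("meshFaces", "TopoMesh", function(x) x@faces)
#' @export
setMethod("topologyId", "TopoMesh", function(x) x@topologyId)
#' @export
setMethod("nVertices", "TopoMesh", function(x) nrow(x@vertices))
#' @export
setMethod("topologyId", "GraphHierarchy", function(x) x@topologyId)
#' @export
setMethod("nVertices", "GraphHierarchy", function(x) x@nVertices)
#' @export
setMethod("topologyId", "PCAShapeModel", function(x) x@topologyId)
#' @export
setMethod("topologyId", "MeshAutoencoder", function(x) x@topologyId)

#' Encode a mesh to shape features / decode features to a mesh
#'
#' \code{shapeEncode} maps a \linkS4class{TopoMesh} to a d-dimensional feature
#' vector under a shape model (PCA coefficients, or the flattened autoencoder
#' bottleneck); \code{shapeDecode} maps a code back to a mesh on the model's
#' template topology. For both model classes \code{shapeDecode(shapeEncode(x))}
#' defines the reconstruction whose error \code{\link{vertexMAE}} measures.
#'
#' @param model a \linkS4class{PCAShapeModel} or \linkS4class{MeshAutoencoder}.
#' @param mesh a \linkS4class{TopoMesh} on the model's topology.
#' @param code numeric latent vector of the model's latent size.
#' @return \code{shapeEncode}: numeric vector; \code{shapeDecode}: \linkS4class{TopoMesh}.
#' @export
setGeneric("shapeEncode", function(model, mesh) standardGeneric("shapeEncode"))

#' @rdname shapeEncode
#' @export
setGeneric("shapeDecode", function(model, code) standardGeneric("shapeDecode"))

#' Latent code length of a shape model
#'
#' For an autoencoder this is bottleneck vertex count times bottleneck
#' channels (e.g. 7 x 612 = 4284 on the full-body template); for PCA it is d.
#'
#' @param x shape model, or an integer bottleneck vertex count.
#' @param ... for the numeric form, \code{channels}.
#' @export
setGeneric("latentSize", function(x, ...) standardGeneric("latentSize"))

#' @export
setMethod("latentSize", "PCAShapeModel", function(x, ...) x@d)
#' @export
setMethod("latentSize", "MeshAutoencoder", function(x, ...) {
  as.integer(rev(x@hierarchy@levelSizes)[1] * x@config$bottleneckChannels)
})
#' @describeIn latentSize arithmetic form: \code{latentSize(7, channels = 612)}.
#' @param channels bottleneck channel count.
#' @export
setMethod("latentSize", "numeric", function(x, channels) {
  stopifnot(x >= 1, channels >= 1)
  as.integer(x * channels)
})
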