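#' Construct a graph convolutional mesh autoencoder
#'
#' Builds the symmetric encoder/decoder over a precomputed graph hierarchy.
#' The encoder applies one full-resolution convolution (3 -> channelPlan[1])
#' followed by one decimating convolution per hierarchy level; the final
#' encoder layer produces the bottleneck map (bottleneck vertices x
#' bottleneckChannels), whose vertex-major flattening is the latent code. The
#' decoder mirrors the encoder with transpose convolutions over the same
#' neighborhoods. ELU nonlinearities sit between layers; the output layer is
#' linear. Input coordinates are centered and scaled by template statistics
#' stored in the model, and decoded outputs are mapped back to mm.
#'
#' @param template \linkS4class{TopoMesh} defining the shared topology.
#' @param channelPlan integer vector of per-level channels; its length sets
#'   the number of hierarchy levels. Default \code{c(16, 32, 64, 128)}.
#' @param bottleneckChannels channels f at the coarsest level; the latent size
#'   is bottleneck vertex count x f.
#' @param M kernel basis size (default 37).
#' @param radius,stride hop counts for the hierarchy (default 2, 2).
#' @param hierarchy optional precomputed \linkS4class{GraphHierarchy}.
#' @param seed RNG seed for weight initialization.
#' @return a \linkS4class{MeshAutoencoder} with randomly initialized weights.
#' @export
newMeshAutoencoder <- function(template, channelPlan = c(16L, 32L, 64L, 128L),
                               bottleneckChannels = 8L, M = 37L,
                               radius = 2L, stride = 2L,
                               hierarchy = NULL, seed = 1L) {
  nLevels <- length(channelPlan)
  if (is.null(hierarchy))
    hierarchy <- buildHierarchy(template, nLevels, radius, stride)
  stopifnot(hierarchy@topologyId == template@topologyId,
            length(hierarchy@levels) == nLevels)
  adj <- graphAdjacency(template)
  level0 <- .buildLevel(adj, radius, 1L)        # full-resolution support

  chanIn <- c(3L, channelPlan)                   # encoder in-channels
  chanOut <- c(channelPlan, bottleneckChannels)  # encoder out-channels
  encLevels <- c(list(level0), hierarchy@levels)
  parentSizes <- c(hierarchy@nVertices, hierarchy@levelSizes)

  mkLayer <- function(level, nParent, inCh, outCh, transposed, act) {
    tr <- .tripletsOf(level)
    nChild <- length(level@vertexIds)
    if (transposed) {
      pat <- .sparsePattern(tr$tj, tr$ti, nParent, nChild)
      list(ti = tr$tj, tj = tr$ti, pat = pat, nChild = nParent,
           nParent = nChild, inCh = inCh, outCh = outCh, M = M, act = act)
    } else {
      pat <- .sparsePattern(tr$ti, tr$tj, nChild, nParent)
      list(ti = tr$ti, tj = tr$tj, pat = pat, nChild = nChild,
           nParent = nParent, inCh = inCh, outCh = outCh, M = M, act = act)
    }
  }

  layers <- list()
  for (l in seq_len(nLevels + 1L))
    layers[[l]] <- mkLayer(encLevels[[l]], parentSizes[l],
                           chanIn[l], chanOut[l], transposed = FALSE, act = TRUE)
  for (l in rev(seq_len(nLevels + 1L))) {
    k <- length(layers) + 1L
    layers[[k]] <- mkLayer(encLevels[[l]], parentSizes[l],
                           inCh = chanOut[l], outCh = chanIn[l],
                           transposed = TRUE, act = (l != 1L))
  }

  set.seed(seed)
  weights <- lapply(layers, function(lay) {
    avgNbr <- max(1, length(lay$ti) / lay$nChild)
    sdB <- 1 / sqrt(M * avgNbr * lay$inCh)
    list(basis = lapply(seq_len(M), function(m)
           matrix(stats::rnorm(lay$outCh * lay$inCh, sd = sdB), lay$outCh, lay$inCh)),
         coeffs = matrix(stats::rnorm(length(lay$ti) * M), ncol = M),
         bias = numeric(lay$outCh))
  })

  v <- template@vertices
  center <- colMeans(v)
  scale <- sqrt(mean(sweep(v, 2, center)^2))
  cfg <- list(channelPlan = as.integer(channelPlan),
              bottleneckChannels = as.integer(bottleneckChannels),
              M = as.integer(M), radius = as.integer(radius),
              stride = as.integer(stride), activation = "elu",
              center = center, scale = scale, nLevels = as.integer(nLevels),
              seed = as.integer(seed))
  new("MeshAutoencoder", hierarchy = hierarchy, config = cfg, layers = layers,
      weights = weights, faces = template@faces,
      topologyId = template@topologyId)
}

.aeNormalize <- function(model, v)
  sweep(v, 2, model@config$center) / model@config$scale
.aeDenormalize <- function(model, X)
  sweep(X * model@config$scale, 2, model@config$center, "+")

## Full forward pass; returns the input map and the post-activation map of
## every layer (encoder then decoder). Deterministic: no dropout/noise.
.aeForward <- function(model, X0) {
  L <- length(model@layers)
  maps <- vector("list", L + 1L)
  maps[[1L]] <- X0
  for (l in seq_len(L)) {
    lay <- model@layers[[l]]
    Y <- .convForward(maps[[l]], lay, model@weights[[l]])
    maps[[l + 1L]] <- if (lay$act) .eluF(Y) else Y
  }
  maps
}

.nEncoderLayers <- function(model) model@config$nLevels + 1L

#' @describeIn newMeshAutoencoder encode: the flattened (vertex-major)
#'   bottleneck activation of a mesh.
#' @param model a \linkS4class{MeshAutoencoder}.
#' @param mesh a \linkS4class{TopoMesh} on the model topology.
#' @export
setMethod("shapeEncode", signature("MeshAutoencoder", "TopoMesh"),
  function(model, mesh) {
    extractFeatures(model, mesh, layerIndex = model@config$nLevels)
  })

#' @describeIn newMeshAutoencoder decode: run the decoder on a latent code of
#'   length \code{latentSize(model)}; returns a full-topology mesh.
#' @param code numeric latent vector.
#' @export
setMethod("shapeDecode", signature("MeshAutoencoder", "numeric"),
  function(model, code) {
    nB <- rev(model@hierarchy@levelSizes)[1]
    f <- model@config$bottleneckChannels
    if (length(code) != nB * f)
      .stopCond("shapecompDimensionError",
                sprintf("latent length %d != bottleneck %d x %d", length(code), nB, f))
    X <- matrix(code, nrow = nB, ncol = f, byrow = TRUE)
    L <- length(model@layers)
    for (l in (.nEncoderLayers(model) + 1L):L) {
      lay <- model@layers[[l]]
      X <- .convForward(X, lay, model@weights[[l]])
      if (lay$act) X <- .eluF(X)
    }
    TopoMesh(.aeDenormalize(model, X), model@faces, topologyId = model@topologyId)
  })

#' Reconstruct a mesh through the autoencoder
#'
#' \code{decode(encode(x))}: the reconstruction whose \code{\link{vertexMAE}}
#' against the input is the model's per-mesh loss metric.
#'
#' @param model a \linkS4class{MeshAutoencoder}.
#' @param mesh input \linkS4class{TopoMesh}.
#' @return reconstructed \linkS4class{TopoMesh}.
#' @export
reconstructMesh <- function(model, mesh) {
  .checkMeshTopology(model, mesh)
  maps <- .aeForward(model, .aeNormalize(model, mesh@vertices))
  TopoMesh(.aeDenormalize(model, maps[[length(maps)]]), model@faces,
           topologyId = model@topologyId)
}

.checkMeshTopology <- function(model, mesh) {
  if (mesh@topologyId != model@topologyId)
    .stopCond("shapecompTopologyError",
              sprintf("mesh topology '%s' does not match model topology '%s'",
                      mesh@topologyId, model@topologyId))
}

#' Extract flattened features from an autoencoder layer
#'
#' Layer 0 is the full-resolution convolution output (level-0 vertex count x
#' channelPlan[1]); layer \code{nLevels} is the bottleneck. Activations are
#' flattened vertex-major, so the bottleneck of a model with 7 bottleneck
#' vertices and 43 channels has length 301.
#'
#' @param model a \linkS4class{MeshAutoencoder}.
#' @param mesh a \linkS4class{TopoMesh} on the model topology.
#' @param layerIndex integer in [0, nLevels].
#' @return numeric feature vector.
#' @export
extractFeatures <- function(model, mesh, layerIndex) {
  .checkMeshTopology(model, mesh)
  if (layerIndex < 0L || layerIndex > model@config$nLevels)
    .stopCond("shapecompIndexError",
              sprintf("layerIndex %d outside [0, %d]", layerIndex, model@config$nLevels))
  maps <- .aeForward(model, .aeNormalize(model, mesh@vertices))
  as.numeric(t(maps[[layerIndex + 2L]]))
}

#' Parameter count of an autoencoder
#'
#' @param model a \linkS4class{MeshAutoencoder}.
#' @param part \code{"all"}, \code{"encoder"} or \code{"decoder"}.
#' @return integer parameter count.
#' @export
aeParameterCount <- function(model, part = c("all", "encoder", "decoder")) {
  part <- match.arg(part)
  idx <- switch(part,
    all = seq_along(model@layers),
    encoder = seq_len(.nEncoderLayers(model)),
    decoder = (.nEncoderLayers(model) + 1L):length(model@layers))
  sum(vapply(model@weights[idx], function(w)
    sum(lengths(w$basis)) + length(w$coeffs) + length(w$bias), numeric(1)))
}
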