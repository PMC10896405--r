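#' Fit a linear (PCA) statistical shape model
#'
#' PCA over flattened vertex coordinates (vertex-major order), the linear
#' baseline against which the nonlinear autoencoder is ablated. Components are
#' the top-d right singular vectors of the mean-centered data matrix; each
#' component's sign is fixed so its largest-magnitude loading is positive,
#' making the fit fully deterministic. No variance-fraction truncation is
#' applied: d is always explicit, capped at the number of training meshes.
#'
#' @param meshes list of \linkS4class{TopoMesh} sharing one topology.
#' @param d number of components, 1 <= d <= length(meshes).
#' @return a \linkS4class{PCAShapeModel}.
#' @export
fitPCAShape <- function(meshes, d) {
  stopifnot(length(meshes) >= 1, d >= 1)
  if (d > length(meshes))
    .stopCond("shapecompDimensionError",
              sprintf("d = %d exceeds the number of training meshes (%d)",
                      d, length(meshes)))
  tid <- meshes[[1]]@topologyId
  for (m in meshes) if (m@topologyId != tid)
    .stopCond("shapecompTopologyError", "training meshes must share one topology")
  X <- t(vapply(meshes, function(m) flattenVertices(m@vertices),
                numeric(3L * nVertices(meshes[[1]]))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(d, min(dim(Xc))))
  k <- ncol(sv$v)
  V <- t(sv$v)                                  # k x 3N, orthonormal rows
  if (k < d) {
    # pad with an orthonormal completion when d exceeds numerical rank
    Q <- qr.Q(qr(cbind(t(V), diag(ncol(Xc)))))[, seq_len(d), drop = FALSE]
    V <- t(Q)
  }
  # sign convention: largest-magnitude loading positive
  for (i in seq_len(nrow(V))) {
    j <- which.max(abs(V[i, ]))
    if (V[i, j] < 0) V[i, ] <- -V[i, ]
  }
  ev <- (sv$d^2) / max(1L, nrow(X) - 1L)
  ev <- c(ev, numeric(d))[seq_len(d)]
  new("PCAShapeModel", meanShape = mu, components = V[seq_len(d), , drop = FALSE],
      explainedVariance = ev, d = as.integer(d),
      faces = meshes[[1]]@faces, topologyId = tid)
}

#' @describeIn fitPCAShape encode: project a mesh onto the component span;
#'   the mean mesh encodes to the zero vector.
#' @export
setMethod("shapeEncode", signature("PCAShapeModel", "TopoMesh"),
  function(model, mesh) {
    if (mesh@topologyId != model@topologyId)
      .stopCond("shapecompTopologyError", "mesh topology does not match the model")
    as.numeric(model@components %*% (flattenVertices(mesh@vertices) - model@meanShape))
  })

#' @describeIn fitPCAShape decode: mean shape plus the coded linear combination
#'   of components; \code{decode(encode(x))} is the orthogonal projection of x
#'   onto the model span.
#' @export
setMethod("shapeDecode", signature("PCAShapeModel", "numeric"),
  function(model, code) {
    if (length(code) != model@d)
      .stopCond("shapecompDimensionError",
                sprintf("code length %d != model d %d", length(code), model@d))
    x <- model@meanShape + as.numeric(crossprod(model@components, code))
    TopoMesh(unflattenVertices(x), model@faces, topologyId = model@topologyId)
  })
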