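#' Sparse nearest-neighbor correspondence matrix
#'
#' One row per template vertex with a single 1 in the column of the Euclidean
#' nearest source vertex, so \code{C \%*\% sourceVertices} resamples an
#' arbitrary-topology scan onto the template topology. Ties go to the lower
#' source index.
#'
#' @param template,source \linkS4class{TopoMesh} objects (topologies may differ).
#' @return a sparse \code{dgCMatrix}, nTemplate x nSource, row sums all 1.
#' @export
nearestNeighborMatrix <- function(template, source) {
  tv <- template@vertices; sv <- source@vertices
  if (!nrow(sv)) .stopCond("shapecompValueError", "source mesh is empty")
  if (!nrow(tv)) .stopCond("shapecompValueError", "template mesh is empty")
  idx <- .nnIndex(tv, sv)
  Matrix::sparseMatrix(i = seq_len(nrow(tv)), j = idx, x = 1,
                       dims = c(nrow(tv), nrow(sv)))
}

## Row-blocked brute-force nearest neighbor; which.min takes the first
## (lowest-index) minimizer, the documented tie-break.
.nnIndex <- function(query, ref, block = 512L) {
  refSq <- rowSums(ref * ref)
  out <- integer(nrow(query))
  for (s in seq(1L, nrow(query), by = block)) {
    e <- min(s + block - 1L, nrow(query))
    q <- query[s:e, , drop = FALSE]
    D <- outer(rowSums(q * q), refSq, "+") - 2 * q %*% t(ref)
    out[s:e] <- apply(D, 1, which.min)
  }
  out
}

#' Apply a correspondence matrix to a source mesh
#'
#' @param C sparse correspondence matrix from \code{\link{nearestNeighborMatrix}}.
#' @param source source \linkS4class{TopoMesh}.
#' @param template template \linkS4class{TopoMesh} supplying faces/topology.
#' @return \linkS4class{TopoMesh} on the template topology.
#' @export
applyCorrespondence <- function(C, source, template) {
  TopoMesh(as.matrix(C %*% source@vertices), template@faces,
           topologyId = template@topologyId)
}

#' Write / read a correspondence matrix as sparse triplet text
#'
#' Plain-text triplet format: a header line \code{nrow ncol nnz} followed by
#' one \code{row col value} line per nonzero (1-based).
#'
#' @param C sparse matrix.
#' @param path file path.
#' @export
writeCorrespondence <- function(C, path) {
  T3 <- Matrix::mat2triplet(C)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("%d %d %d", nrow(C), ncol(C), length(T3$i)), con)
  writeLines(sprintf("%d %d %.9g", T3$i, T3$j, T3$x), con)
  invisible(path)
}

#' @rdname writeCorrespondence
#' @export
readCorrespondence <- function(path) {
  hdr <- scan(path, what = numeric(), nlines = 1, quiet = TRUE)
  m <- matrix(scan(path, what = numeric(), skip = 1, quiet = TRUE),
              ncol = 3, byrow = TRUE)
  Matrix::sparseMatrix(i = m[, 1], j = m[, 2], x = m[, 3],
                       dims = c(hdr[1], hdr[2]))
}

.meshEdges <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Nonrigid registration of a template mesh to a target scan
#'
#' Deforms the template with one 3x4 affine transform per vertex by minimizing
#' \deqn{E = w_d \sum_i \|T_i v_i - nn_{target}(T_i v_i)\|^2 +
#'       w_s \sum_{(i,j) \in edges} \|T_i - T_j\|_F^2}
#' by alternating closed-form steps: fix transforms and take nearest-target
#' correspondences, then fix correspondences and solve the sparse least-squares
#' problem for all transforms jointly (the three coordinate rows decouple).
#' Both steps are exact minimizations of E in their block, so E is
#' nonincreasing across iterations.
#'
#' @param template connected \linkS4class{TopoMesh} to deform.
#' @param target \linkS4class{TopoMesh} (any topology) to fit.
#' @param dataWeight,smoothWeight nonnegative energy weights.
#' @param nIters outer alternation iterations.
#' @return list with \code{mesh} (deformed template, template topology
#'   preserved), \code{transforms} (N x 3 x 4 array), \code{energy} (per-
#'   iteration trace), and the weights.
#' @export
nonrigidRegister <- function(template, target, dataWeight = 1,
                             smoothWeight = 1, nIters = 10L) {
  stopifnot(dataWeight >= 0, smoothWeight >= 0, nIters >= 1)
  tv <- template@vertices
  n <- nrow(tv)
  Vh <- cbind(tv, 1)                      # homogeneous template vertices, n x 4
  edges <- .meshEdges(template)

  # normal-equation matrix, shared by the three coordinate rows:
  # dataWeight * blockdiag(v~ v~^T) + smoothWeight * (L (x) I4) + tiny ridge
  bi <- rep(4L * (seq_len(n) - 1L), each = 16L)
  ia <- bi + rep(rep(1:4, each = 4), n)
  ja <- bi + rep(rep(1:4, times = 4), n)
  xa <- as.numeric(t(Vh[, rep(1:4, each = 4), drop = FALSE] *
                     Vh[, rep(1:4, times = 4), drop = FALSE]))
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  iL <- c(4L * (rep(seq_len(n), each = 4) - 1L) + 1:4,
          4L * (rep(edges[, 1], each = 4) - 1L) + 1:4,
          4L * (rep(edges[, 2], each = 4) - 1L) + 1:4)
  jL <- c(4L * (rep(seq_len(n), each = 4) - 1L) + 1:4,
          4L * (rep(edges[, 2], each = 4) - 1L) + 1:4,
          4L * (rep(edges[, 1], each = 4) - 1L) + 1:4)
  xL <- c(rep(deg, each = 4), rep(-1, 8L * nrow(edges)))
  A <- Matrix::sparseMatrix(i = c(ia, iL), j = c(ja, jL),
                            x = c(dataWeight * xa, smoothWeight * xL),
                            dims = c(4L * n, 4L * n))
  ridge <- 1e-12 * max(abs(A@x))
  A <- A + Matrix::Diagonal(4L * n, ridge)
  A <- Matrix::forceSymmetric(A)
  ch <- Matrix::Cholesky(A, LDL = FALSE)

  # transforms stored as n x 12 (rows of T stacked: t^x, t^y, t^z each length 4)
  Tm <- matrix(rep(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0), each = n), nrow = n)
  energyOf <- function(def, corr) {
    ed <- sum((def - corr)^2)
    d <- Tm[edges[, 1], , drop = FALSE] - Tm[edges[, 2], , drop = FALSE]
    dataWeight * ed + smoothWeight * sum(d * d)
  }
  applyT <- function() cbind(rowSums(Vh * Tm[, 1:4]),
                             rowSums(Vh * Tm[, 5:8]),
                             rowSums(Vh * Tm[, 9:12]))
  energy <- numeric(nIters)
  for (it in seq_len(nIters)) {
    def <- applyT()
    corr <- target@vertices[.nnIndex(def, target@vertices), , drop = FALSE]
    for (r in 1:3) {
      b <- numeric(4L * n)
      b[rep(4L * (seq_len(n) - 1L), each = 4L) + 1:4] <-
        dataWeight * as.numeric(t(Vh * corr[, r]))
      sol <- as.numeric(Matrix::solve(ch, b))
      Tm[, (4L * r - 3L):(4L * r)] <- matrix(sol, nrow = n, byrow = TRUE)
    }
    energy[it] <- energyOf(applyT(), corr)
    if (!is.finite(energy[it]))
      .stopCond("shapecompOptimError",
                sprintf("registration energy diverged at iteration %d", it))
  }
  def <- applyT()
  transforms <- array(0, dim = c(n, 3, 4))
  for (r in 1:3) transforms[, r, ] <- Tm[, (4L * r - 3L):(4L * r)]
  list(mesh = TopoMesh(def, template@faces, topologyId = template@topologyId),
       transforms = transforms, energy = energy,
       dataWeight = dataWeight, smoothWeight = smoothWeight)
}
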