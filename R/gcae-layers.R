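## Spatially varying graph convolution.
##
## For retained vertex i with neighborhood N(i) on the parent graph:
##   y_i = bias + sum_{j in N(i)} ( sum_m A[i,j,m] * B_m ) x_j
## where the M basis matrices B_m (out x in) are shared across the mesh and
## the per-edge coefficients A make the kernel spatially varying. With
## S_m = sparse(A[,,m]) this is y = sum_m S_m X B_m', which is how both the
## forward and backward passes are evaluated (one sparse and one dense
## multiply per basis element).

.tripletsOf <- function(level) {
  nb <- level@neighborhoods
  list(ti = rep(seq_along(nb), lengths(nb)),
       tj = unlist(nb, use.names = FALSE))
}

## dgCMatrix reorders triplets internally; cache the permutation so coeffs can
## be written straight into @x on every use without rebuilding the pattern.
.sparsePattern <- function(ti, tj, nChild, nParent) {
  S0 <- Matrix::sparseMatrix(i = ti, j = tj, x = seq_along(ti),
                             dims = c(nChild, nParent))
  T0 <- Matrix::sparseMatrix(i = tj, j = ti, x = seq_along(ti),
                             dims = c(nParent, nChild))
  list(S0 = S0, ord = as.integer(S0@x), T0 = T0, ordT = as.integer(T0@x))
}

.eluF <- function(x) ifelse(x > 0, x, exp(x) - 1)
## derivative recovered from the activation value: elu'(x) = 1 (x>0), elu(x)+1 (x<=0)
.eluDfromPost <- function(post) ifelse(post > 0, 1, post + 1)

#' Spatially varying graph convolution (reference form)
#'
#' Evaluates one convolution over a \linkS4class{GraphLevel}: for each retained
#' vertex the output is the bias plus the sum over its neighborhood of a
#' per-edge mixture of M shared basis matrices applied to the parent features.
#' This is the reference entry point; trained models use the same math with
#' cached sparse patterns.
#'
#' @param x parent feature map, nParent x inChannels.
#' @param level a \linkS4class{GraphLevel}.
#' @param basis list of M (outChannels x inChannels) basis matrices.
#' @param coeffs nEdges x M coefficient matrix, rows ordered neighborhood-major
#'   (all edges of retained vertex 1 in neighborhood order, then vertex 2, ...).
#' @param bias numeric outChannels vector.
#' @return child feature map, nRetained x outChannels.
#' @export
vcConv <- function(x, level, basis, coeffs, bias) {
  tr <- .tripletsOf(level)
  nChild <- length(level@vertexIds)
  nParent <- nrow(x)
  coeffs <- as.matrix(coeffs)
  if (nrow(coeffs) != length(tr$ti) || ncol(coeffs) != length(basis))
    .stopCond("shapecompWeightError",
              sprintf("coeffs must be %d x %d (edges x basis size), got %d x %d",
                      length(tr$ti), length(basis), nrow(coeffs), ncol(coeffs)))
  if (max(tr$tj) > nParent)
    .stopCond("shapecompWeightError", "feature map smaller than the level's parent set")
  pat <- .sparsePattern(tr$ti, tr$tj, nChild, nParent)
  W <- list(basis = basis, coeffs = coeffs, bias = bias)
  lay <- list(pat = pat, nChild = nChild, M = length(basis))
  .convForward(x, lay, W)
}

.convForward <- function(X, lay, W) {
  out <- matrix(W$bias, nrow = lay$nChild, ncol = length(W$bias), byrow = TRUE)
  for (m in seq_len(lay$M)) {
    S <- lay$pat$S0
    S@x <- W$coeffs[lay$pat$ord, m]
    out <- out + as.matrix(S %*% (X %*% t(W$basis[[m]])))
  }
  out
}

## Backward pass: G is dLoss/dY (nChild x out). Returns gradients for the
## input map and every weight tensor.
.convBackward <- function(G, X, lay, W) {
  M <- lay$M
  dX <- matrix(0, nrow = nrow(X), ncol = ncol(X))
  dBasis <- vector("list", M)
  dCoeffs <- matrix(0, nrow = length(lay$ti), ncol = M)
  for (m in seq_len(M)) {
    S <- lay$pat$S0
    S@x <- W$coeffs[lay$pat$ord, m]
    Bm <- W$basis[[m]]
    P <- X %*% t(Bm)                            # nParent x out
    H <- as.matrix(S %*% X)                     # nChild x in
    dX <- dX + as.matrix(Matrix::crossprod(S, G) %*% Bm)
    dBasis[[m]] <- crossprod(G, H)              # out x in
    dCoeffs[, m] <- rowSums(G[lay$ti, , drop = FALSE] * P[lay$tj, , drop = FALSE])
  }
  list(dX = dX, dBasis = dBasis, dCoeffs = dCoeffs, dBias = colSums(G))
}
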