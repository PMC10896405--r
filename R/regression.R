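#' The ten body-composition target variables
#'
#' Total, regional and visceral fat/lean masses in kg, and percent body fat
#' as a percentage: the DXA-style quantities the regression heads predict.
#'
#' @export
compositionTargets <- function() c(
  "total_fat", "total_lean", "visceral_fat", "percent_fat",
  "trunk_fat", "trunk_lean", "arm_fat", "arm_lean", "leg_fat", "leg_lean")

#' Assemble the regression feature vector for one subject
#'
#' Shape features concatenated with the demographic triple
#' [height (cm), weight (kg), age (years)], in that fixed column order. With
#' empty shape features this yields the demographics-only baseline input.
#'
#' @param shapeFeatures numeric vector (possibly length 0).
#' @param height,weight,age demographic scalars; all must be present.
#' @return numeric vector of length \code{length(shapeFeatures) + 3}.
#' @export
assembleFeatures <- function(shapeFeatures, height, weight, age) {
  if (anyNA(c(height, weight, age)) || any(!is.finite(c(height, weight, age))))
    .stopCond("shapecompRecordError", "missing demographic (height/weight/age)")
  c(as.numeric(shapeFeatures), height, weight, age)
}

## Feature scaling with training statistics; constant columns map to 0.
## mode "column": classic per-column z-scaling. mode "pooled": center columns
## and divide all of them by one pooled SD, preserving the relative variance
## structure — for dot-product kernels over PCA-style features this keeps
## low-variance (noise-dominated) directions from being amplified to the same
## kernel weight as the dominant shape modes.
.colScaleFit <- function(X, mode = c("column", "pooled")) {
  mode <- match.arg(mode)
  ctr <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- if (mode == "column") 1 else NA
  if (mode == "pooled") {
    pooled <- sqrt(mean(sd^2, na.rm = TRUE))
    if (!is.finite(pooled) || pooled < 1e-12) pooled <- 1
    sd <- rep(pooled, length(sd))
  }
  list(center = ctr, scale = sd)
}
.colScaleApply <- function(X, sc) sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")

#' Fit ordinary least squares with a minimum-norm solution
#'
#' Least squares via the SVD pseudoinverse with an intercept, so the
#' underdetermined case (more features than subjects, e.g. thousands of shape
#' coefficients) yields the minimum-norm coefficient vector with ~zero
#' residuals rather than failing.
#'
#' @param X n x p feature matrix.
#' @param y n-vector or n x T matrix of targets.
#' @param intercept include an intercept column (default TRUE).
#' @param targetNames optional target labels.
#' @return an \linkS4class{OLSModel}.
#' @export
fitOLS <- function(X, y, intercept = TRUE, targetNames = NULL) {
  X <- as.matrix(X); y <- as.matrix(y)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    .stopCond("shapecompDataError", "non-finite entries in X or y")
  if (is.null(targetNames))
    targetNames <- colnames(y) %||% paste0("y", seq_len(ncol(y)))
  Xd <- if (intercept) cbind(1, X) else X
  sv <- svd(Xd)
  tol <- max(dim(Xd)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])
  if (!intercept) coef <- rbind(0, coef)
  new("OLSModel", coef = coef,
      xCenter = numeric(ncol(X)), xScale = rep(1, ncol(X)),
      targetNames = targetNames)
}

#' Predict from an OLS model
#'
#' @param object an \linkS4class{OLSModel}.
#' @param X n x p feature matrix.
#' @param ... unused.
#' @return n x T matrix of predictions.
#' @export
setMethod("predict", "OLSModel", function(object, X, ...) {
  X <- .colScaleApply(as.matrix(X), list(center = object@xCenter,
                                         scale = object@xScale))
  out <- cbind(1, X) %*% object@coef
  colnames(out) <- object@targetNames
  out
})

#' Squared dot-product kernel
#'
#' \eqn{k(x, z) = (\sigma_0^2 + x \cdot z)^2}: the inner product of explicit
#' degree-2 polynomial feature maps, matching shape-to-composition relations
#' assumed nonlinear but monotone in first and second derivatives.
#'
#' @param x,z numeric vectors of equal length.
#' @param sigma0 nonnegative inhomogeneity parameter.
#' @return scalar kernel value.
#' @export
sqdotKernel <- function(x, z, sigma0 = 1) {
  if (length(x) != length(z))
    .stopCond("shapecompDimensionError",
              sprintf("kernel input lengths differ: %d vs %d", length(x), length(z)))
  (sigma0^2 + sum(x * z))^2
}

.sqdotGram <- function(A, B, sigma0) (sigma0^2 + A %*% t(B))^2

#' Gaussian process regression with the squared dot-product kernel
#'
#' Closed-form posterior mean: \eqn{m(x_*) = k_*^T (K + \alpha I)^{-1} y},
#' fitted per target after optional column z-scaling of features (dot-product
#' kernels are scale-sensitive) and standardization of targets (undone at
#' prediction). With \code{optimizeSigma0} the kernel inhomogeneity is chosen
#' by maximizing the log marginal likelihood of the first target from 3
#' restarts; otherwise sigma0 is fixed.
#'
#' @param X n x p feature matrix.
#' @param y n-vector or n x T target matrix.
#' @param sigma0 kernel inhomogeneity. The default \code{"auto"} sets
#'   \eqn{\sigma_0^2} to the mean squared norm of the (scaled) training
#'   features, balancing the kernel's constant, linear and quadratic terms
#'   against the feature scale; a numeric value fixes it.
#' @param alpha observation-noise jitter added to the kernel diagonal
#'   (default 1e-2 on standardized targets).
#' @param standardizeX feature scaling: \code{"pooled"} (default; center
#'   columns, divide all by one pooled SD so the relative variance structure
#'   of e.g. PCA features survives), \code{"column"} (per-column z-scaling),
#'   or \code{"none"}. \code{TRUE}/\code{FALSE} map to column/none.
#' @param standardizeY standardize targets with training statistics (undone
#'   at prediction).
#' @param optimizeSigma0 marginal-likelihood selection of sigma0.
#' @param targetNames optional target labels.
#' @return a \linkS4class{GPRModel}.
#' @export
fitGPR <- function(X, y, sigma0 = "auto", alpha = 1e-2,
                   standardizeX = "pooled", standardizeY = TRUE,
                   optimizeSigma0 = FALSE, targetNames = NULL) {
  stopifnot(alpha > 0, is.character(sigma0) || sigma0 >= 0)
  X <- as.matrix(X); y <- as.matrix(y)
  if (is.null(targetNames))
    targetNames <- colnames(y) %||% paste0("y", seq_len(ncol(y)))
  if (isTRUE(standardizeX)) standardizeX <- "column"
  if (isFALSE(standardizeX)) standardizeX <- "none"
  sx <- if (standardizeX != "none") .colScaleFit(X, standardizeX) else
    list(center = numeric(ncol(X)), scale = rep(1, ncol(X)))
  Xs <- .colScaleApply(X, sx)
  sy <- if (standardizeY) .colScaleFit(y) else
    list(center = numeric(ncol(y)), scale = rep(1, ncol(y)))
  ys <- .colScaleApply(y, sy)

  autoS0 <- sqrt(max(mean(rowSums(Xs * Xs)), .Machine$double.eps))
  if (identical(sigma0, "auto")) sigma0 <- autoS0
  if (optimizeSigma0) {
    # mean negative log marginal likelihood across targets
    nll <- function(logS0) {
      K <- .sqdotGram(Xs, Xs, exp(logS0))
      ch <- tryCatch(chol(K + alpha * diag(nrow(K))), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      a <- backsolve(ch, forwardsolve(t(ch), ys))
      0.5 * mean(colSums(ys * a)) + sum(log(diag(ch)))
    }
    starts <- log(autoS0 * c(0.1, 1, 10))
    fits <- lapply(starts, function(s)
      stats::optim(s, nll, method = "L-BFGS-B",
                   lower = log(autoS0 * 1e-3), upper = log(autoS0 * 1e3)))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    sigma0 <- exp(best$par)
  }

  K <- .sqdotGram(Xs, Xs, sigma0)
  ch <- tryCatch(chol(K + alpha * diag(nrow(K))), error = function(e)
    .stopCond("shapecompConditioningError",
              "kernel matrix not positive definite; increase alpha"))
  dual <- backsolve(ch, forwardsolve(t(ch), ys))
  new("GPRModel", Xtrain = Xs, dual = as.matrix(dual),
      sigma0 = sigma0, alpha = alpha,
      xCenter = sx$center, xScale = sx$scale,
      yCenter = sy$center, yScale = sy$scale,
      targetNames = targetNames)
}

#' Predict from a GPR model
#'
#' @param object a \linkS4class{GPRModel}.
#' @param X n x p feature matrix on the original (unstandardized) scale.
#' @param ... unused.
#' @return n x T matrix of posterior-mean predictions in target units.
#' @export
setMethod("predict", "GPRModel", function(object, X, ...) {
  Xs <- .colScaleApply(as.matrix(X), list(center = object@xCenter,
                                          scale = object@xScale))
  Ks <- .sqdotGram(Xs, object@Xtrain, object@sigma0)
  out <- Ks %*% object@dual
  out <- sweep(sweep(out, 2, object@yScale, "*"), 2, object@yCenter, "+")
  colnames(out) <- object@targetNames
  out
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit sex-stratified regression models
#'
#' Independent models per sex (the shape-to-composition map differs between
#' strata); scaling statistics never leak across strata or from test data.
#'
#' @param X n x p feature matrix.
#' @param y n x T target matrix.
#' @param sex character/factor vector of \code{"male"} / \code{"female"}.
#' @param kind \code{"gpr"} or \code{"ols"}.
#' @param ... passed to \code{\link{fitGPR}} / \code{\link{fitOLS}}.
#' @return named list of fitted models, one per stratum present.
#' @export
fitStratified <- function(X, y, sex, kind = c("gpr", "ols"), ...) {
  kind <- match.arg(kind)
  X <- as.matrix(X); y <- as.matrix(y)
  sex <- as.character(sex)
  out <- list()
  for (s in unique(sex)) {
    idx <- which(sex == s)
    if (length(idx) < 2L)
      .stopCond("shapecompStratumError",
                sprintf("stratum '%s' has %d record(s); need >= 2", s, length(idx)))
    out[[s]] <- if (kind == "gpr")
      fitGPR(X[idx, , drop = FALSE], y[idx, , drop = FALSE], ...)
    else fitOLS(X[idx, , drop = FALSE], y[idx, , drop = FALSE], ...)
  }
  out
}

#' Predict with sex-stratified models
#'
#' @param models result of \code{\link{fitStratified}}.
#' @param X n x p feature matrix.
#' @param sex stratum labels aligned with rows of X.
#' @return n x T prediction matrix.
#' @export
predictStratified <- function(models, X, sex) {
  X <- as.matrix(X); sex <- as.character(sex)
  tn <- models[[1]]@targetNames
  out <- matrix(NA_real_, nrow(X), length(tn), dimnames = list(NULL, tn))
  for (s in unique(sex)) {
    if (is.null(models[[s]]))
      .stopCond("shapecompStratumError", sprintf("no model for stratum '%s'", s))
    idx <- which(sex == s)
    out[idx, ] <- predict(models[[s]], X[idx, , drop = FALSE])
  }
  out
}

#' Per-layer GPR feature search over an autoencoder
#'
#' Fits sex-stratified GPR from every feature layer of the autoencoder
#' (layer 0, the full-resolution convolution, through the bottleneck) to the
#' composition targets, scoring test RMSE per layer; reports the full table,
#' the bottleneck row and the argmin-RMSE layer per sex.
#'
#' @param model trained \linkS4class{MeshAutoencoder}.
#' @param trainMeshes,testMeshes lists of \linkS4class{TopoMesh}.
#' @param trainRec,testRec data.frames with height, weight, age, sex and the
#'   target columns of \code{\link{compositionTargets}}.
#' @param targets target column names (default all ten).
#' @param ... passed to \code{\link{fitGPR}}.
#' @return list: \code{table} (data.frame layer / sex / target / rmse),
#'   \code{bestLayer} (named per sex), \code{bottleneckLayer}.
#' @export
layerSearch <- function(model, trainMeshes, trainRec, testMeshes, testRec,
                        targets = compositionTargets(), ...) {
  nL <- model@config$nLevels
  feats <- function(meshes, layer) t(vapply(meshes, function(m)
    extractFeatures(model, m, layer), extractFeatures(model, meshes[[1]], layer)))
  demo <- function(rec) cbind(height = rec$height, weight = rec$weight, age = rec$age)
  ytr <- as.matrix(trainRec[, targets, drop = FALSE])
  yte <- as.matrix(testRec[, targets, drop = FALSE])
  rows <- list()
  for (layer in 0:nL) {
    Xtr <- cbind(feats(trainMeshes, layer), demo(trainRec))
    Xte <- cbind(feats(testMeshes, layer), demo(testRec))
    fit <- fitStratified(Xtr, ytr, trainRec$sex, kind = "gpr",
                         targetNames = targets, ...)
    pred <- predictStratified(fit, Xte, testRec$sex)
    for (s in unique(as.character(testRec$sex))) {
      idx <- testRec$sex == s
      for (tg in targets)
        rows[[length(rows) + 1L]] <- data.frame(
          layer = layer, sex = s, target = tg,
          rmse = rmse(pred[idx, tg], yte[idx, tg]))
    }
  }
  tab <- do.call(rbind, rows)
  agg <- stats::aggregate(rmse ~ layer + sex, tab, mean)
  bestLayer <- vapply(split(agg, agg$sex), function(d)
    d$layer[which.min(d$rmse)], numeric(1))
  list(table = tab, bestLayer = bestLayer, bottleneckLayer = nL)
}
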