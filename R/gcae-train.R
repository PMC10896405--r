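#' Training configuration for the mesh autoencoder
#'
#' Defaults follow the reference schedule: Adam at learning rate 1e-4, batch
#' size 16, 200 pretraining epochs on the pose-varied set and 400 finetuning
#' epochs on the multi-identity set. Scaled-down runs pass smaller values.
#'
#' @param lr Adam learning rate.
#' @param batchSize meshes per gradient step.
#' @param pretrainEpochs,finetuneEpochs epoch counts (>= 0).
#' @param seed RNG seed controlling batch shuffling.
#' @return a list with class \code{"aeTrainConfig"}.
#' @export
trainConfig <- function(lr = 1e-4, batchSize = 16L, pretrainEpochs = 200L,
                        finetuneEpochs = 400L, seed = 1L) {
  stopifnot(lr > 0, batchSize >= 1, pretrainEpochs >= 0, finetuneEpochs >= 0)
  structure(list(lr = lr, batchSize = as.integer(batchSize),
                 pretrainEpochs = as.integer(pretrainEpochs),
                 finetuneEpochs = as.integer(finetuneEpochs),
                 seed = as.integer(seed)),
            class = "aeTrainConfig")
}

## MAE loss (mean |coordinate error| in normalized units) and full gradient
## for one mesh. Returns per-layer gradients matching the weights structure.
.aeLossGrad <- function(model, Xn) {
  maps <- .aeForward(model, Xn)
  L <- length(model@layers)
  Yhat <- maps[[L + 1L]]
  R <- Yhat - Xn
  loss <- mean(abs(R))
  G <- sign(R) / length(R)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    lay <- model@layers[[l]]
    if (lay$act) G <- G * .eluDfromPost(maps[[l + 1L]])
    bk <- .convBackward(G, maps[[l]], lay, model@weights[[l]])
    grads[[l]] <- bk[c("dBasis", "dCoeffs", "dBias")]
    G <- bk$dX
  }
  list(loss = loss, grads = grads)
}

.aeLoss <- function(model, Xn) {
  maps <- .aeForward(model, Xn)
  mean(abs(maps[[length(maps)]] - Xn))
}

.zeroLike <- function(weights) lapply(weights, function(w)
  list(basis = lapply(w$basis, function(b) b * 0),
       coeffs = w$coeffs * 0, bias = w$bias * 0))

.adamStep <- function(weights, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    list(w = w - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
  }
  for (l in seq_along(weights)) {
    for (m in seq_along(weights[[l]]$basis)) {
      u <- upd(weights[[l]]$basis[[m]], grads[[l]]$dBasis[[m]],
               state$m[[l]]$basis[[m]], state$v[[l]]$basis[[m]])
      weights[[l]]$basis[[m]] <- u$w
      state$m[[l]]$basis[[m]] <- u$m; state$v[[l]]$basis[[m]] <- u$v
    }
    u <- upd(weights[[l]]$coeffs, grads[[l]]$dCoeffs,
             state$m[[l]]$coeffs, state$v[[l]]$coeffs)
    weights[[l]]$coeffs <- u$w
    state$m[[l]]$coeffs <- u$m; state$v[[l]]$coeffs <- u$v
    u <- upd(weights[[l]]$bias, grads[[l]]$dBias,
             state$m[[l]]$bias, state$v[[l]]$bias)
    weights[[l]]$bias <- u$w
    state$m[[l]]$bias <- u$m; state$v[[l]]$bias <- u$v
  }
  list(weights = weights, state = state)
}

.sumGrads <- function(a, b, wb = 1) {
  for (l in seq_along(a)) {
    for (m in seq_along(a[[l]]$dBasis))
      a[[l]]$dBasis[[m]] <- a[[l]]$dBasis[[m]] + wb * b[[l]]$dBasis[[m]]
    a[[l]]$dCoeffs <- a[[l]]$dCoeffs + wb * b[[l]]$dCoeffs
    a[[l]]$dBias <- a[[l]]$dBias + wb * b[[l]]$dBias
  }
  a
}

.scaleGrads <- function(g, s) {
  for (l in seq_along(g)) {
    g[[l]]$dBasis <- lapply(g[[l]]$dBasis, function(b) b * s)
    g[[l]]$dCoeffs <- g[[l]]$dCoeffs * s
    g[[l]]$dBias <- g[[l]]$dBias * s
  }
  g
}

#' Train a mesh autoencoder with a pretrain/finetune schedule
#'
#' Runs the two-phase schedule: Adam on the MAE reconstruction loss, first on
#' the pretraining set (pose-varied, few identities), then on the finetuning
#' set (multi-identity, single pose). The evaluation set is scored at the end
#' of every epoch as mean \code{\link{vertexMAE}} in mm, and the returned
#' model carries the checkpoint with the lowest evaluation MAE over the
#' finetuning phase (over the pretraining phase if no finetuning is run). A
#' schedule of 0 + 0 epochs returns the initialized model unchanged.
#'
#' @param model an initialized \linkS4class{MeshAutoencoder}.
#' @param pretrain,finetune,evalSet lists of \linkS4class{TopoMesh} on the
#'   model topology; \code{evalSet} must be disjoint from \code{finetune}.
#' @param cfg a \code{\link{trainConfig}}.
#' @return list: \code{model} (best checkpoint), \code{history} (data.frame
#'   phase / epoch / trainLoss / evalMAE), \code{bestEvalMAE}.
#' @export
trainAutoencoder <- function(model, pretrain, finetune, evalSet, cfg = trainConfig()) {
  stopifnot(inherits(cfg, "aeTrainConfig"))
  for (m in c(pretrain, finetune, evalSet)) .checkMeshTopology(model, m)
  normAll <- function(set) lapply(set, function(m) .aeNormalize(model, m@vertices))
  Xpre <- normAll(pretrain); Xfin <- normAll(finetune)

  evalMAE <- function(w) {
    mtmp <- model; mtmp@weights <- w
    if (!length(evalSet)) return(NA_real_)
    mean(vapply(evalSet, function(ms)
      vertexMAE(ms, reconstructMesh(mtmp, ms)), numeric(1)))
  }

  weights <- model@weights
  state <- list(m = .zeroLike(weights), v = .zeroLike(weights))
  t <- 0L
  hist <- list()
  best <- list(weights = weights, mae = Inf)
  set.seed(cfg$seed)

  runPhase <- function(phase, Xset, epochs) {
    if (!length(Xset) || epochs == 0L) return(invisible())
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(Xset))
      epLoss <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / cfg$batchSize))) {
        gsum <- NULL; lsum <- 0
        mcur <- model; mcur@weights <- weights
        for (i in bs) {
          lg <- .aeLossGrad(mcur, Xset[[i]])
          if (!is.finite(lg$loss))
            .stopCond("shapecompTrainingError",
                      sprintf("non-finite loss in %s epoch %d", phase, ep))
          gsum <- if (is.null(gsum)) lg$grads else .sumGrads(gsum, lg$grads)
          lsum <- lsum + lg$loss
        }
        gsum <- .scaleGrads(gsum, 1 / length(bs))
        t <<- t + 1L
        st <- .adamStep(weights, gsum, state, cfg$lr, t)
        weights <<- st$weights; state <<- st$state
        epLoss <- epLoss + lsum
      }
      em <- evalMAE(weights)
      hist[[length(hist) + 1L]] <<- data.frame(
        phase = phase, epoch = ep, trainLoss = epLoss / length(Xset), evalMAE = em)
      track <- (phase == "finetune") ||
        (phase == "pretrain" && cfg$finetuneEpochs == 0L)
      if (track && is.finite(em) && em < best$mae)
        best <<- list(weights = weights, mae = em)
    }
  }

  runPhase("pretrain", Xpre, cfg$pretrainEpochs)
  runPhase("finetune", Xfin, cfg$finetuneEpochs)

  if (is.finite(best$mae)) model@weights <- best$weights else model@weights <- weights
  list(model = model,
       history = if (length(hist)) do.call(rbind, hist) else
         data.frame(phase = character(), epoch = integer(),
                    trainLoss = numeric(), evalMAE = numeric()),
       bestEvalMAE = if (is.finite(best$mae)) best$mae else NA_real_)
}

#' Save / load an autoencoder checkpoint
#'
#' Single-file archive carrying weights, config and topology id.
#'
#' @param model a \linkS4class{MeshAutoencoder}.
#' @param path file path (.rds).
#' @export
saveAutoencoder <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname saveAutoencoder
#' @export
loadAutoencoder <- function(path) readRDS(path)
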