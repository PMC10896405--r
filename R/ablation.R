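## Feature builders for the model permutations. All permutations see the
## demographics triple appended, matching the regression convention; the
## baseline sees only the demographics.
.permFeatures <- function(kindSrc, meshes, rec, pcaModel = NULL,
                          aeModel = NULL, layer = NULL) {
  demo <- cbind(height = rec$height, weight = rec$weight, age = rec$age)
  shape <- switch(kindSrc,
    none = NULL,
    pca = t(vapply(meshes, function(m) shapeEncode(pcaModel, m),
                   numeric(pcaModel@d))),
    mesh = t(vapply(meshes, function(m) flattenVertices(m@vertices),
                    numeric(3L * nVertices(meshes[[1]])))),
    ae = t(vapply(meshes, function(m) extractFeatures(aeModel, m, layer),
                  extractFeatures(aeModel, meshes[[1]], layer))))
  if (is.null(shape)) demo else cbind(shape, demo)
}

#' Run the model-permutation ablation harness
#'
#' Trains and evaluates every pipeline permutation on identical subject-level
#' splits: a demographics-only GPR baseline (height/weight/age), PCA + OLS
#' (the fully linear pipeline and the 100% reference for normalized RMSE),
#' PCA + GPR, GPR on raw mesh coordinates, and GPR from every autoencoder
#' feature layer. Accuracy (per-target RMSE, normalized RMSE, R^2) is scored
#' on the first scan of each test subject; test-retest precision (%CV and
#' repeat RMSE over the same-day duplicate pairs) is scored per permutation
#' with the autoencoder row using bottleneck features, so linear and deep
#' precision rows have matched parameter counts.
#'
#' @param cohort a \linkS4class{ShapeCohort} with finetune and test splits
#'   (test subjects carry duplicate scans).
#' @param pcaModel fitted \linkS4class{PCAShapeModel}.
#' @param aeModel optional trained \linkS4class{MeshAutoencoder}; omit to run
#'   only the linear/mesh permutations.
#' @param targets target columns (default all ten).
#' @param gprArgs list of extra arguments to \code{\link{fitGPR}}.
#' @return list: \code{accuracy} and \code{precision} tidy data.frames
#'   (permutation / sex / target / metric / value).
#' @export
runAblation <- function(cohort, pcaModel, aeModel = NULL,
                        targets = compositionTargets(), gprArgs = list()) {
  trainRec <- cohortRecords(cohort, split = "finetune", scan = 1L)
  testRec <- cohortRecords(cohort, split = "test", scan = 1L)
  if (length(intersect(trainRec$subject_id, testRec$subject_id)))
    .stopCond("shapecompIntegrityError",
              "subject ids shared across train and test splits")
  trainMeshes <- cohortMeshes(cohort, split = "finetune", scan = 1L)
  testMeshes <- cohortMeshes(cohort, split = "test", scan = 1L)
  retestRec <- cohortRecords(cohort, split = "test", scan = 2L)
  retestMeshes <- cohortMeshes(cohort, split = "test", scan = 2L)
  ytr <- as.matrix(trainRec[, targets, drop = FALSE])
  yte <- as.matrix(testRec[, targets, drop = FALSE])

  nL <- if (!is.null(aeModel)) aeModel@config$nLevels else NULL
  perms <- list(
    Baseline_HWA_GPR = list(src = "none", kind = "gpr"),
    PCA_OLS = list(src = "pca", kind = "ols"),
    PCA_GPR = list(src = "pca", kind = "gpr"),
    Mesh_GPR = list(src = "mesh", kind = "gpr"))
  if (!is.null(aeModel)) for (l in 0:nL)
    perms[[sprintf("AE_GPR_layer%d", l)]] <-
      list(src = "ae", kind = "gpr", layer = l)

  fitPerm <- function(p) {
    Xtr <- .permFeatures(p$src, trainMeshes, trainRec, pcaModel, aeModel, p$layer)
    args <- c(list(X = Xtr, y = ytr, sex = trainRec$sex, kind = p$kind,
                   targetNames = targets),
              if (p$kind == "gpr") gprArgs)
    do.call(fitStratified, args)
  }
  predPerm <- function(fit, p, meshes, rec)
    predictStratified(fit, .permFeatures(p$src, meshes, rec, pcaModel,
                                         aeModel, p$layer), rec$sex)

  acc <- list(); prec <- list()
  fits <- lapply(perms, fitPerm)
  predsTest <- mapply(function(f, p) predPerm(f, p, testMeshes, testRec),
                      fits, perms, SIMPLIFY = FALSE)
  baseRMSE <- list()
  for (s in unique(testRec$sex)) for (tg in targets) {
    idx <- testRec$sex == s
    baseRMSE[[paste(s, tg)]] <- rmse(predsTest$PCA_OLS[idx, tg], yte[idx, tg])
  }
  for (pn in names(perms)) {
    pred <- predsTest[[pn]]
    for (s in unique(testRec$sex)) {
      idx <- testRec$sex == s
      for (tg in targets) {
        r <- rmse(pred[idx, tg], yte[idx, tg])
        acc[[length(acc) + 1L]] <- data.frame(
          permutation = pn, sex = s, target = tg,
          metric = c("rmse", "normalized_rmse", "r_squared"),
          value = c(r, normalizedRMSE(r, baseRMSE[[paste(s, tg)]]),
                    rSquared(pred[idx, tg], yte[idx, tg])))
      }
    }
  }

  # precision rows: deep permutation pinned to the bottleneck layer
  precPerms <- perms[c("Baseline_HWA_GPR", "PCA_OLS", "PCA_GPR", "Mesh_GPR")]
  precFits <- fits[names(precPerms)]
  if (!is.null(aeModel)) {
    precPerms$AE_GPR_bottleneck <- list(src = "ae", kind = "gpr", layer = nL)
    precFits$AE_GPR_bottleneck <- fits[[sprintf("AE_GPR_layer%d", nL)]]
  }
  stopifnot(identical(testRec$subject_id, retestRec$subject_id))
  for (pn in names(precPerms)) {
    p <- precPerms[[pn]]
    p1 <- predPerm(precFits[[pn]], p, testMeshes, testRec)
    p2 <- predPerm(precFits[[pn]], p, retestMeshes, retestRec)
    for (s in unique(testRec$sex)) {
      idx <- testRec$sex == s
      for (tg in targets) {
        pr <- precisionPairs(testRec$subject_id[idx], p1[idx, tg], p2[idx, tg])
        cv <- if (mean(c(pr$m1, pr$m2)) > 0) cvPercent(pr) else NA_real_
        prec[[length(prec) + 1L]] <- data.frame(
          permutation = pn, sex = s, target = tg,
          metric = c("cv_percent", "repeat_rmse"),
          value = c(cv, repeatRMSE(pr)))
      }
    }
  }
  list(accuracy = do.call(rbind, acc), precision = do.call(rbind, prec))
}

#' Data-withholding ablation for autoencoder training
#'
#' Retrains the autoencoder with named partitions excluded (the pose-varied
#' \code{"pretrain"} set, or the finetuning partitions \code{"ensembleA"} /
#' \code{"ensembleB"}) and reports the evaluation-set reconstruction MAE of
#' each condition against the all-data run, all from the same initialization
#' seed.
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @param conditions list of character vectors; each vector names the
#'   partitions withheld in one condition (an empty vector withholds nothing).
#' @param channelPlan,bottleneckChannels,M autoencoder size (see
#'   \code{\link{newMeshAutoencoder}}).
#' @param cfg a \code{\link{trainConfig}}.
#' @return data.frame: condition / evalMAE / deltaMAE (vs the all-data run).
#' @export
withholdExperiment <- function(cohort, conditions,
                               channelPlan = c(8L, 12L), bottleneckChannels = 4L,
                               M = 4L, cfg = trainConfig()) {
  cd <- as.data.frame(colData(cohort))
  known <- unique(cd$group)
  for (cond in conditions) {
    bad <- setdiff(cond, known)
    if (length(bad))
      .stopCond("shapecompArgumentError",
                paste0("unknown partition(s): ", paste(bad, collapse = ", "),
                       " (available: ", paste(known, collapse = ", "), ")"))
  }
  tmpl <- cohortTemplate(cohort)
  evalMeshes <- cohortMeshes(cohort, split = "eval", scan = 1L)
  runOne <- function(withheld) {
    sel <- function(split) {
      idx <- .cohortSel(cohort, split = split)
      idx <- idx[!(cd$group[idx] %in% withheld)]
      lapply(idx, function(j) cohortMesh(cohort, j))
    }
    model <- newMeshAutoencoder(tmpl, channelPlan = channelPlan,
                                bottleneckChannels = bottleneckChannels,
                                M = M, seed = cfg$seed)
    fit <- trainAutoencoder(model, sel("pretrain"), sel("finetune"),
                            evalMeshes, cfg)
    fit$bestEvalMAE
  }
  allMAE <- runOne(character())
  rows <- lapply(conditions, function(cond) data.frame(
    condition = if (length(cond)) paste(cond, collapse = "+") else "none",
    evalMAE = runOne(cond)))
  out <- do.call(rbind, rows)
  out$deltaMAE <- out$evalMAE - allMAE
  out
}
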