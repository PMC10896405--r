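test_that("the template is deterministic, valid, and distinct across resolutions", {
  t1 <- makeTemplate(0); t2 <- makeTemplate(0)
  expect_identical(t1@vertices, t2@vertices)
  expect_identical(t1@topologyId, t2@topologyId)
  expect_true(validObject(t1))
  expect_true(nVertices(t1) >= 200 && nVertices(t1) <= 3000)
  expect_false(makeTemplate(1)@topologyId == t1@topologyId)
})

test_that("zero latents and zero noise reproduce the template exactly", {
  cfg <- synthConfig(seed = 3, demoVariation = FALSE, vertexNoiseSD = 0)
  gen <- synthGenerator(cfg)
  V <- shapecomp:::.subjectMesh(gen, z = numeric(cfg$latentDim), sex = "male",
                                heightCM = 170, noiseSD = 0)
  expect_equal(V, gen$template@vertices, tolerance = 1e-12)
})

test_that("noiseless duplicate scans give zero %CV", {
  cfg <- synthConfig(seed = 4, nPretrainIdentities = 0, nFinetune = 0,
                     nEval = 0, nTest = 5, retestNoiseSD = 0, vertexNoiseSD = 0)
  coh <- generateCohort(cfg)
  m1 <- cohortMeshes(coh, split = "test", scan = 1)
  m2 <- cohortMeshes(coh, split = "test", scan = 2)
  d <- vapply(seq_along(m1), function(i) vertexMAE(m1[[i]], m2[[i]]), numeric(1))
  expect_identical(max(d), 0)
  pr <- precisionPairs(letters[1:5],
                       vapply(m1, function(m) mean(m@vertices), numeric(1)) + 100,
                       vapply(m2, function(m) mean(m@vertices), numeric(1)) + 100)
  expect_identical(cvPercent(pr), 0)
})

test_that("increasing a latent increases fat mass across a grid (monotone map)", {
  gen <- synthGenerator(synthConfig(seed = 5))
  expect_true(checkMonotoneMap(gen))
  grid <- seq(-3, 3, length.out = 20)
  vals <- vapply(grid, function(g) {
    z <- numeric(gen$cfg$latentDim); z[1] <- g
    shapecomp:::.evalTargetMap(gen$targetMap$male, z, 75)["total_fat"]
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("cohorts have the four roles, disjoint subjects, and seeded determinism", {
  cfg <- synthConfig(seed = 6, nPretrainIdentities = 2, framesPerIdentity = 3,
                     nFinetune = 4, nEval = 2, nTest = 3)
  coh <- generateCohort(cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(coh))
  expect_setequal(unique(cd$split), c("pretrain", "finetune", "eval", "test"))
  expect_identical(sum(cd$split == "pretrain"), 6L)
  expect_identical(sum(cd$split == "test"), 6L)   # duplicates
  bySplit <- split(cd$subject_id, cd$split)
  for (a in names(bySplit)) for (b in setdiff(names(bySplit), a))
    expect_length(intersect(bySplit[[a]], bySplit[[b]]), 0)
  coh2 <- generateCohort(cfg)
  expect_identical(SummarizedExperiment::assay(coh, "coords"),
                   SummarizedExperiment::assay(coh2, "coords"))
  # physical plausibility of records
  tg <- setdiff(compositionTargets(), "percent_fat")
  expect_true(all(as.matrix(cd[, tg]) >= 0))
  expect_true(all(cd$percent_fat >= 0 & cd$percent_fat <= 100))
})

test_that("on-disk layout round-trips and regenerates from its manifest", {
  cfg <- synthConfig(seed = 7, nPretrainIdentities = 1, framesPerIdentity = 2,
                     nFinetune = 3, nEval = 1, nTest = 2)
  dir <- file.path(tempdir(), "cohort_rt")
  unlink(dir, recursive = TRUE)
  coh <- generateCohort(cfg, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("records.csv", "pairs.csv",
                                               "manifest.yaml", "template.ply")))))
  expect_true(all(file.exists(file.path(dir, "splits",
                                        c("pretrain.txt", "finetune.txt",
                                          "eval.txt", "test.txt")))))
  expect_error(generateCohort(cfg, dir = dir), class = "shapecompValueError")

  back <- readCohortDir(dir)
  expect_equal(SummarizedExperiment::assay(back, "coords"),
               SummarizedExperiment::assay(coh, "coords"), tolerance = 1e-6)

  regen <- regenerateCohort(file.path(dir, "manifest.yaml"))
  expect_identical(SummarizedExperiment::assay(regen, "coords"),
                   SummarizedExperiment::assay(coh, "coords"))

  # byte-identical CSVs under the same seed
  dir2 <- file.path(tempdir(), "cohort_rt2")
  unlink(dir2, recursive = TRUE)
  generateCohort(cfg, dir = dir2)
  expect_identical(readLines(file.path(dir, "records.csv")),
                   readLines(file.path(dir2, "records.csv")))
})

test_that("a noiseless linear cohort is recovered exactly by PCA at d = k", {
  k <- 4L
  cfg <- synthConfig(seed = 8, nPretrainIdentities = 0, nFinetune = 30,
                     nEval = 0, nTest = 0, latentDim = k, nLinearModes = k,
                     nQuadraticModes = 0, vertexNoiseSD = 0,
                     demoVariation = FALSE)
  coh <- generateCohort(cfg)
  meshes <- cohortMeshes(coh, split = "finetune")
  model <- fitPCAShape(meshes, d = k)
  maes <- vapply(meshes, function(m)
    vertexMAE(m, shapeDecode(model, shapeEncode(model, m))), numeric(1))
  expect_lt(max(maes), 1e-6)
})

test_that("OLS on true latents recovers linear coefficients within 3 SE", {
  cfg <- synthConfig(seed = 9, nPretrainIdentities = 0, nFinetune = 500,
                     nEval = 0, nTest = 0, nQuadraticModes = 0)
  coh <- generateCohort(cfg)
  gt <- S4Vectors::metadata(coh)$groundTruth
  rec <- cohortRecords(coh, split = "finetune")
  Z <- gt$z[rec$subject_id, ]
  for (sex in c("male", "female")) {
    idx <- rec$sex == sex
    fit <- stats::lm(rec$total_fat[idx] ~ Z[idx, ] + rec$weight[idx])
    est <- coef(summary(fit))
    truth <- c(gt$targetMap[[sex]]$B["total_fat", ],
               gt$targetMap[[sex]]$dW["total_fat"])
    got <- est[-1, "Estimate"]; se <- est[-1, "Std. Error"]
    expect_true(all(abs(got - truth) <= 3 * se))
  }
})
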