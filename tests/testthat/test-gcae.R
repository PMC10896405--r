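tinyAE <- function(seed = 2, tmpl = makeTemplate(0)) {
  newMeshAutoencoder(tmpl, channelPlan = c(6L, 8L), bottleneckChannels = 3L,
                     M = 3L, seed = seed)
}

test_that("the identity kernel restricts the input to retained vertices", {
  adj <- cycleAdj(8)
  lev <- levelFromAdj(adj, radius = 1, stride = 1)
  tr <- shapecomp:::.tripletsOf(lev)
  x <- matrix(rnorm(16), 8, 2)
  coeffs <- matrix(as.numeric(tr$tj == tr$ti), ncol = 1)
  y <- vcConv(x, lev, basis = list(diag(2)), coeffs = coeffs, bias = c(0, 0))
  expect_equal(y, x)
  # zero input propagates only the bias
  y0 <- vcConv(x * 0, lev, basis = list(diag(2)),
               coeffs = matrix(rnorm(nrow(coeffs)), ncol = 1), bias = c(2, -1))
  expect_equal(y0, matrix(rep(c(2, -1), each = 8), 8))
})

test_that("vcConv equals the dense triple-loop oracle on random small graphs", {
  set.seed(31)
  for (trial in 1:50) {
    n <- sample(5:20, 1)
    # random connected-ish graph: cycle plus chords
    adj <- cycleAdj(n)
    for (e in seq_len(sample(0:4, 1))) {
      ij <- sample(n, 2)
      adj[[ij[1]]] <- sort(unique(c(adj[[ij[1]]], ij[2])))
      adj[[ij[2]]] <- sort(unique(c(adj[[ij[2]]], ij[1])))
    }
    lev <- levelFromAdj(adj, radius = sample(1:2, 1), stride = sample(1:2, 1))
    M <- sample(1:3, 1); inC <- sample(1:4, 1); outC <- sample(1:4, 1)
    x <- matrix(rnorm(n * inC), n, inC)
    basis <- lapply(seq_len(M), function(m) matrix(rnorm(outC * inC), outC, inC))
    nb <- lev@neighborhoods
    coeffs <- matrix(rnorm(sum(lengths(nb)) * M), ncol = M)
    bias <- rnorm(outC)
    expect_equal(vcConv(x, lev, basis, coeffs, bias),
                 vcConvOracle(x, nb, basis, coeffs, bias), tolerance = 1e-6)
  }
})

test_that("latent sizes follow bottleneck-vertices times channels", {
  ae <- tinyAE()
  nB <- rev(ae@hierarchy@levelSizes)[1]
  expect_identical(latentSize(ae), nB * 3L)
  expect_length(shapeEncode(ae, makeTemplate(0)), nB * 3L)
  # layer-0 features have level-0 count x first channel-plan entry
  f0 <- extractFeatures(ae, makeTemplate(0), 0)
  expect_length(f0, nVertices(makeTemplate(0)) * 6L)
  # additivity over all layers
  tot <- sum(vapply(0:ae@config$nLevels, function(l)
    length(extractFeatures(ae, makeTemplate(0), l)), numeric(1)))
  sizes <- ae@hierarchy@levelSizes
  expect_identical(tot, sum(c(sizes[1], sizes[-1]) *
                            c(6, 8, 3)))
  expect_error(extractFeatures(ae, makeTemplate(0), 7),
               class = "shapecompIndexError")
})

test_that("encoding is deterministic and decoding honors the shape contract", {
  ae <- tinyAE()
  m <- randomMesh(makeTemplate(0), sd = 5, seed = 8)
  expect_identical(shapeEncode(ae, m), shapeEncode(ae, m))
  out <- shapeDecode(ae, shapeEncode(ae, m))
  expect_identical(nVertices(out), nVertices(m))
  expect_true(all(is.finite(out@vertices)))
  expect_identical(out@topologyId, m@topologyId)
  expect_error(shapeDecode(ae, numeric(5)), class = "shapecompDimensionError")
  expect_error(shapeEncode(ae, sphereMesh(4, 6)), class = "shapecompTopologyError")
})

test_that("encoder and decoder parameter counts mirror up to bias differences", {
  ae <- tinyAE()
  enc <- aeParameterCount(ae, "encoder")
  dec <- aeParameterCount(ae, "decoder")
  nEnc <- shapecomp:::.nEncoderLayers(ae)
  encBias <- sum(vapply(ae@weights[seq_len(nEnc)], function(w)
    length(w$bias), numeric(1)))
  decBias <- sum(vapply(ae@weights[(nEnc + 1):length(ae@weights)], function(w)
    length(w$bias), numeric(1)))
  expect_identical(enc - encBias, dec - decBias)
})

test_that("analytic gradients match finite differences on sampled weights", {
  ae <- tinyAE(seed = 4)
  Xn <- shapecomp:::.aeNormalize(ae, randomMesh(makeTemplate(0), sd = 10,
                                                seed = 5)@vertices)
  lg <- shapecomp:::.aeLossGrad(ae, Xn)
  set.seed(99)
  numGrad <- function(l, kind, m, i) {
    eps <- 1e-5
    poke <- function(delta) {
      a2 <- ae
      if (kind == "basis") a2@weights[[l]]$basis[[m]][i] <-
          a2@weights[[l]]$basis[[m]][i] + delta
      else if (kind == "coeffs") a2@weights[[l]]$coeffs[i] <-
          a2@weights[[l]]$coeffs[i] + delta
      else a2@weights[[l]]$bias[i] <- a2@weights[[l]]$bias[i] + delta
      shapecomp:::.aeLoss(a2, Xn)
    }
    (poke(eps) - poke(-eps)) / (2 * eps)
  }
  for (t in 1:10) {
    l <- sample(length(ae@layers), 1)
    kind <- sample(c("basis", "coeffs", "bias"), 1)
    m <- sample(ae@config$M, 1)
    i <- switch(kind,
      basis = sample(length(ae@weights[[l]]$basis[[m]]), 1),
      coeffs = sample(length(ae@weights[[l]]$coeffs), 1),
      bias = sample(length(ae@weights[[l]]$bias), 1))
    g <- switch(kind,
      basis = lg$grads[[l]]$dBasis[[m]][i],
      coeffs = lg$grads[[l]]$dCoeffs[i],
      bias = lg$grads[[l]]$dBias[i])
    nd <- numGrad(l, kind, m, i)
    expect_lt(abs(g - nd) / max(abs(nd), 1e-6), 1e-4)
  }
})

test_that("a zero-epoch schedule returns the initialized model unchanged", {
  ae <- tinyAE()
  tmpl <- makeTemplate(0)
  fit <- trainAutoencoder(ae, list(tmpl), list(tmpl), list(tmpl),
                          trainConfig(pretrainEpochs = 0, finetuneEpochs = 0))
  expect_identical(fit$model@weights, ae@weights)
  expect_identical(nrow(fit$history), 0L)
})

test_that("overfitting a single mesh contracts reconstruction error well below the diameter", {
  tmpl <- makeTemplate(0)
  ae <- tinyAE(seed = 6)
  fit <- trainAutoencoder(ae, list(), list(tmpl), list(tmpl),
                          trainConfig(lr = 3e-3, batchSize = 1,
                                      pretrainEpochs = 0, finetuneEpochs = 150,
                                      seed = 3))
  expect_lt(fit$bestEvalMAE, 0.05 * shapecomp:::meshDiameter(tmpl))
})

test_that("training reduces evaluation MAE on a small cohort", {
  cfg <- synthConfig(seed = 13, nPretrainIdentities = 0, nFinetune = 20,
                     nEval = 8, nTest = 0)
  coh <- generateCohort(cfg)
  ae <- tinyAE(seed = 13, tmpl = cohortTemplate(coh))
  fit <- trainAutoencoder(ae, list(), cohortMeshes(coh, split = "finetune"),
                          cohortMeshes(coh, split = "eval"),
                          trainConfig(lr = 2e-3, batchSize = 8,
                                      pretrainEpochs = 0, finetuneEpochs = 12,
                                      seed = 13))
  em <- fit$history$evalMAE
  expect_lt(em[length(em)], em[1])
  expect_lte(fit$bestEvalMAE, min(em))
})
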