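test_that("feature assembly appends the demographic triple in fixed order", {
  expect_identical(assembleFeatures(numeric(), 170, 70, 40), c(170, 70, 40))
  expect_length(assembleFeatures(rnorm(301), 170, 70, 40), 304)
  expect_error(assembleFeatures(1:3, NA, 70, 40), class = "shapecompRecordError")
})

test_that("constant training columns scale to zero instead of dividing by zero", {
  X <- cbind(a = rnorm(10), b = rep(5, 10))
  sc <- shapecomp:::.colScaleFit(X, "column")
  Xs <- shapecomp:::.colScaleApply(X, sc)
  expect_true(all(Xs[, "b"] == 0))
})

test_that("fitOLS solves exact, overdetermined and underdetermined systems", {
  m <- fitOLS(diag(2), c(1, 2), intercept = FALSE)
  expect_equal(as.numeric(m@coef[-1, 1]), c(1, 2), tolerance = 1e-10)

  set.seed(21)
  X <- matrix(rnorm(150), 50, 3); y <- X %*% c(1, -2, 0.5) + rnorm(50)
  m <- fitOLS(X, y)
  oracle <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(as.numeric(m@coef), as.numeric(oracle), tolerance = 1e-8)

  # p > n: residuals ~ 0 and smaller norm than sampled alternative solutions
  X <- matrix(rnorm(5 * 12), 5, 12); y <- rnorm(5)
  m <- fitOLS(X, y, intercept = FALSE)
  beta <- as.numeric(m@coef[-1, 1])
  expect_lt(max(abs(X %*% beta - y)), 1e-8)
  for (s in 1:5) {
    null <- MASS::Null(t(X))
    alt <- beta + null %*% rnorm(ncol(null))
    expect_lte(sum(beta^2), sum(alt^2) + 1e-10)
  }
  expect_error(fitOLS(matrix(c(1, NA), 1), 1), class = "shapecompDataError")
})

test_that("the squared dot-product kernel matches its degree-2 feature map", {
  expect_identical(sqdotKernel(0, 0, 1), 1)
  expect_identical(sqdotKernel(c(1, 0), c(0, 1), 1), 1)
  expect_error(sqdotKernel(1:3, 1:2), class = "shapecompDimensionError")
  phi <- function(x, s0) c(s0^2, sqrt(2) * s0 * x, as.numeric(outer(x, x)))
  set.seed(8)
  for (trial in 1:20) {
    p <- sample(1:6, 1); s0 <- runif(1, 0.1, 3)
    x <- rnorm(p); z <- rnorm(p)
    expect_equal(sqdotKernel(x, z, s0), sum(phi(x, s0) * phi(z, s0)),
                 tolerance = 1e-9)
  }
})

test_that("GPR interpolates a single point as alpha vanishes", {
  x <- matrix(c(1, 2), 1); y <- 3.7
  g <- fitGPR(x, y, alpha = 1e-12, standardizeX = "none", standardizeY = FALSE)
  expect_equal(as.numeric(predict(g, x)), y, tolerance = 1e-6)
})

test_that("GPR posterior mean matches direct solve and kernel ridge oracles", {
  set.seed(22)
  X <- matrix(rnorm(5 * 3), 5); y <- rnorm(5)
  s0 <- 1.4; al <- 1e-3
  g <- fitGPR(X, y, sigma0 = s0, alpha = al, standardizeX = "none",
              standardizeY = FALSE)
  Xs <- matrix(rnorm(9), 3)
  K <- (s0^2 + X %*% t(X))^2
  direct <- (s0^2 + Xs %*% t(X))^2 %*% solve(K + al * diag(5), y)
  expect_equal(as.numeric(predict(g, Xs)), as.numeric(direct), tolerance = 1e-8)

  # kernel ridge in the explicit degree-2 feature space
  phi <- function(M) t(apply(M, 1, function(x)
    c(s0^2, sqrt(2) * s0 * x, as.numeric(outer(x, x)))))
  P <- phi(X)
  ridge <- phi(Xs) %*% solve(crossprod(P) + al * diag(ncol(P)), crossprod(P, y))
  expect_equal(as.numeric(predict(g, Xs)), as.numeric(ridge), tolerance = 1e-8)
})

test_that("GPR agrees with an independent GP implementation (kernlab)", {
  skip_if_not_installed("kernlab")
  set.seed(23)
  X <- matrix(rnorm(30 * 4), 30); y <- as.numeric(X %*% rnorm(4))^2 / 4 + rnorm(30, sd = 0.1)
  al <- 0.05
  g <- fitGPR(X, y, sigma0 = 1, alpha = al, standardizeX = "none",
              standardizeY = FALSE)
  ref <- kernlab::gausspr(X, y, kernel = "polydot",
                          kpar = list(degree = 2, scale = 1, offset = 1),
                          var = al, scaled = FALSE, fit = FALSE)
  Xs <- matrix(rnorm(5 * 4), 5)
  expect_equal(as.numeric(predict(g, Xs)),
               as.numeric(kernlab::predict(ref, Xs)), tolerance = 1e-6)
})

test_that("stratified fits are per-sex, order-invariant, and leak-free", {
  set.seed(24)
  n <- 80
  sex <- rep(c("male", "female"), n / 2)
  X <- matrix(rnorm(n * 3), n)
  # planted map differs by sex
  y <- ifelse(sex == "male", 2 * X[, 1] + X[, 2]^2, -1.5 * X[, 1] + 3)
  y <- matrix(y + rnorm(n, sd = 0.05), dimnames = list(NULL, "t"))

  one <- fitStratified(X[sex == "male", ], y[sex == "male", , drop = FALSE],
                       sex[sex == "male"], kind = "gpr")
  expect_named(one, "male")
  expect_error(fitStratified(X[1, , drop = FALSE], y[1, , drop = FALSE],
                             "male", kind = "gpr"),
               class = "shapecompStratumError")

  fit <- fitStratified(X, y, sex, kind = "gpr")
  perm <- sample(n)
  fit2 <- fitStratified(X[perm, ], y[perm, , drop = FALSE], sex[perm], kind = "gpr")
  Xnew <- matrix(rnorm(30), 10)
  sexNew <- rep(c("male", "female"), 5)
  expect_equal(predictStratified(fit, Xnew, sexNew),
               predictStratified(fit2, Xnew, sexNew), tolerance = 1e-9)

  # stratified beats a pooled model when the map differs by sex
  pooled <- fitGPR(X, y)
  Xte <- matrix(rnorm(200 * 3), 200)
  sexTe <- rep(c("male", "female"), 100)
  yTe <- ifelse(sexTe == "male", 2 * Xte[, 1] + Xte[, 2]^2, -1.5 * Xte[, 1] + 3)
  expect_lt(rmse(predictStratified(fit, Xte, sexTe)[, 1], yTe),
            rmse(predict(pooled, Xte)[, 1], yTe))
})

test_that("GPR beats OLS on a quadratic map but matches it on a linear map", {
  set.seed(25)
  n <- 300; p <- 4
  X <- matrix(rnorm(n * p), n); Xte <- matrix(rnorm(n * p), n)
  quad <- function(M) rowSums((M + 1.5)^2) + M %*% rep(0.5, p)
  lin <- function(M) M %*% c(2, -1, 0.5, 1) + 3
  for (case in c("quad", "lin")) {
    f <- if (case == "quad") quad else lin
    y <- f(X) + rnorm(n, sd = 0.3); yte <- f(Xte) + rnorm(n, sd = 0.3)
    eG <- rmse(predict(fitGPR(X, y), Xte)[, 1], yte)
    eO <- rmse(predict(fitOLS(X, y), Xte)[, 1], yte)
    if (case == "quad") expect_lt(eG, eO) else
      expect_lt(abs(eG - eO) / eO, 0.10)
  }
})

test_that("layer search covers every feature layer and finds informative ones", {
  cfg <- synthConfig(seed = 31, nPretrainIdentities = 0, nFinetune = 40,
                     nEval = 0, nTest = 15)
  coh <- generateCohort(cfg)
  ae <- newMeshAutoencoder(cohortTemplate(coh), channelPlan = c(4L, 6L),
                           bottleneckChannels = 2L, M = 2L, seed = 31)
  res <- layerSearch(ae, cohortMeshes(coh, split = "finetune"),
                     cohortRecords(coh, split = "finetune"),
                     cohortMeshes(coh, split = "test"),
                     cohortRecords(coh, split = "test"))
  nLayers <- ae@config$nLevels + 1L   # raw-input-level conv through bottleneck
  expect_setequal(unique(res$table$layer), 0:(nLayers - 1L))
  expect_identical(res$bottleneckLayer, ae@config$nLevels)
  expect_true(all(res$bestLayer %in% 0:(nLayers - 1L)))
  expect_identical(sort(unique(res$table$target)), sort(compositionTargets()))
})
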