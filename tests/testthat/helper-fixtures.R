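# Fixtures built in code; nothing is stored on disk.

# Small UV-sphere mesh for cheap geometric tests.
sphereMesh <- function(rings = 4L, segs = 6L, radius = 1) {
  theta <- pi * seq_len(rings) / (rings + 1L)
  phi <- 2 * pi * (seq_len(segs) - 1L) / segs
  v <- rbind(c(0, 0, 1),
             do.call(rbind, lapply(theta, function(th)
               cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th)))),
             c(0, 0, -1)) * radius
  idx <- function(r, s) 1L + (r - 1L) * segs + ((s - 1L) %% segs) + 1L
  f <- list()
  for (s in seq_len(segs)) f[[length(f) + 1L]] <- c(1L, idx(1, s), idx(1, s + 1))
  for (r in seq_len(rings - 1L)) for (s in seq_len(segs)) {
    a <- idx(r, s); b <- idx(r, s + 1); cc <- idx(r + 1, s); d <- idx(r + 1, s + 1)
    f[[length(f) + 1L]] <- c(a, cc, b); f[[length(f) + 1L]] <- c(b, cc, d)
  }
  bot <- nrow(v)
  for (s in seq_len(segs)) f[[length(f) + 1L]] <- c(bot, idx(rings, s + 1), idx(rings, s))
  TopoMesh(v, do.call(rbind, f))
}

# Random mesh on a given topology.
randomMesh <- function(template, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  TopoMesh(template@vertices + matrix(rnorm(length(template@vertices), sd = sd),
                                      ncol = 3),
           template@faces, topologyId = template@topologyId)
}

# Independent BFS distance oracle on an adjacency list (plain queue walk).
bfsDistOracle <- function(adj, start) {
  d <- rep(Inf, length(adj)); d[start] <- 0
  q <- start
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (u in adj[[v]]) if (d[u] > d[v] + 1) { d[u] <- d[v] + 1; q <- c(q, u) }
  }
  d
}

# Independent greedy stride-cover oracle: lowest-index unmarked vertex wins,
# marks everything closer than `stride` hops.
strideCoverOracle <- function(adj, stride) {
  marked <- logical(length(adj)); kept <- integer()
  for (v in seq_along(adj)) {
    if (marked[v]) next
    kept <- c(kept, v)
    marked[bfsDistOracle(adj, v) < stride] <- TRUE
  }
  kept
}

# Cycle graph adjacency C_n.
cycleAdj <- function(n) lapply(seq_len(n), function(i)
  sort(c((i %% n) + 1L, ((i - 2L) %% n) + 1L)))

# Dense triple-loop oracle for the spatially varying convolution.
vcConvOracle <- function(x, neighborhoods, basis, coeffs, bias) {
  nChild <- length(neighborhoods)
  out <- matrix(rep(bias, each = nChild), nChild)
  t <- 0L
  for (i in seq_len(nChild)) for (j in neighborhoods[[i]]) {
    t <- t + 1L
    K <- 0
    for (m in seq_along(basis)) K <- K + coeffs[t, m] * basis[[m]]
    out[i, ] <- out[i, ] + as.numeric(K %*% x[j, ])
  }
  out
}

# A GraphLevel built directly from an adjacency list (stride-1 or stride-2).
levelFromAdj <- function(adj, radius = 1L, stride = 1L) {
  shapecomp:::.buildLevel(adj, as.integer(radius), as.integer(stride))
}

# Explicit degree-2 polynomial feature map of the squared dot-product kernel.
phiVec <- function(x, s0) c(s0^2, sqrt(2) * s0 * x, as.numeric(outer(x, x)))

# Cached nonlinear ablation runs for the multi-seed qualitative checks
# (shared between the property tests and the acceptance tests).
.ablationCache <- new.env(parent = emptyenv())
nonlinearAblation <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.ablationCache[[key]])) return(.ablationCache[[key]])
  cfg <- synthConfig(seed = seed, nFinetune = 600L, nEval = 0L, nTest = 200L,
                     nPretrainIdentities = 0L)
  coh <- generateCohort(cfg)
  pca <- fitPCAShape(cohortMeshes(coh, split = "finetune"), d = 300L)
  res <- runAblation(coh, pca)
  .ablationCache[[key]] <- res
  res
}

meanRMSE <- function(res, perm, targets = compositionTargets()) {
  a <- res$accuracy
  x <- a[a$permutation == perm & a$metric == "rmse" & a$target %in% targets, ]
  mean(x$value)
}

precValue <- function(res, perm, target, metric) {
  p <- res$precision
  mean(p$value[p$permutation == perm & p$target == target & p$metric == metric])
}
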