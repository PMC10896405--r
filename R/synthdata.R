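#' Deterministic humanoid-like template mesh
#'
#' A closed UV-sphere tessellation deformed to body-like proportions
#' (elongated axis, elliptical cross-section, waist/shoulder/head profile),
#' about 1700 mm tall. Each resolution gives a distinct fixed topology of
#' 226 to ~3000 vertices; every synthetic subject shares the template's
#' triangulation, mirroring topology-standardized optical scans.
#'
#' @param resolution nonnegative integer; 0 gives 226 vertices, each step adds
#'   rings/segments (capped so the count stays below 3000).
#' @return a \linkS4class{TopoMesh} in mm.
#' @export
makeTemplate <- function(resolution = 0L) {
  stopifnot(resolution >= 0)
  rings <- min(14L + 4L * resolution, 40L)
  segs <- min(16L + 8L * resolution, 72L)
  theta <- pi * seq_len(rings) / (rings + 1L)
  phi <- 2 * pi * (seq_len(segs) - 1L) / segs
  v <- rbind(c(0, 0, 1),
             do.call(rbind, lapply(theta, function(th)
               cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th)))),
             c(0, 0, -1))
  idx <- function(r, s) 1L + (r - 1L) * segs + ((s - 1L) %% segs) + 1L
  faces <- list()
  for (s in seq_len(segs)) faces[[length(faces) + 1L]] <- c(1L, idx(1, s), idx(1, s + 1))
  for (r in seq_len(rings - 1L)) for (s in seq_len(segs)) {
    a <- idx(r, s); b <- idx(r, s + 1); cc <- idx(r + 1, s); d <- idx(r + 1, s + 1)
    faces[[length(faces) + 1L]] <- c(a, cc, b)
    faces[[length(faces) + 1L]] <- c(b, cc, d)
  }
  bot <- nrow(v)
  for (s in seq_len(segs))
    faces[[length(faces) + 1L]] <- c(bot, idx(rings, s + 1), idx(rings, s))
  f <- do.call(rbind, faces)

  # humanoid radial profile along the body axis z in [-1, 1]
  z <- v[, 3]
  p <- 0.20 +
    0.10 * exp(-((z - 0.05) / 0.45)^2) +      # torso/belly
    0.05 * exp(-((z + 0.55) / 0.30)^2) -      # hips/legs
    0.09 * exp(-((z - 0.62) / 0.10)^2) +      # neck pinch
    0.06 * exp(-((z - 0.85) / 0.10)^2)        # head
  vertices <- cbind(850 * v[, 1] * p * 1.10,
                    850 * v[, 2] * p * 0.82,
                    850 * z)
  TopoMesh(vertices, f)
}

#' Synthetic cohort configuration
#'
#' Counts mirror the study design roles scaled to desk size: a small
#' pose-varied pretraining set (few identities, many frames), a
#' multi-identity single-pose finetuning set, an evaluation split for epoch
#' selection, and a test set with same-day duplicate scans for precision
#' analysis. Shape is driven by \code{latentDim} standard-normal latents
#' through smooth linear modes plus torso-concentrated quadratic bulge modes
#' (the planted nonlinearity); composition targets are monotone quadratic in
#' the latents with per-variable DXA-scale noise.
#'
#' @param seed integer; generation is fully determined by it.
#' @param resolution template resolution (see \code{\link{makeTemplate}}).
#' @param nPretrainIdentities,framesPerIdentity pose-varied pretraining role.
#' @param nFinetune,nEval,nTest subject counts for the single-pose roles.
#' @param latentDim latent shape dimensions k.
#' @param nLinearModes number of linear displacement modes (<= latentDim).
#' @param nQuadraticModes latents that additionally drive quadratic torso
#'   bulges (<= latentDim).
#' @param demoVariation with FALSE, stature scaling and the sex offset field
#'   are suppressed so mesh variation comes from the latent modes alone
#'   (useful for exact linear-recovery checks).
#' @param vertexNoiseSD per-vertex scan noise, mm.
#' @param retestNoiseSD fresh vertex noise of the same-day duplicate scan, mm.
#' @param targetNoiseSD named per-target noise SDs in target units.
#' @return list with class \code{"synthConfig"}.
#' @export
synthConfig <- function(seed = 1L, resolution = 0L,
                        nPretrainIdentities = 6L, framesPerIdentity = 20L,
                        nFinetune = 600L, nEval = 80L, nTest = 200L,
                        latentDim = 6L, nLinearModes = 6L, nQuadraticModes = 2L,
                        demoVariation = TRUE,
                        vertexNoiseSD = 2, retestNoiseSD = 2,
                        targetNoiseSD = NULL) {
  if (is.null(targetNoiseSD))
    targetNoiseSD <- c(total_fat = 0.5, total_lean = 0.6, visceral_fat = 0.03,
                       percent_fat = 0.8, trunk_fat = 0.3, trunk_lean = 0.35,
                       arm_fat = 0.05, arm_lean = 0.07, leg_fat = 0.10,
                       leg_lean = 0.12)
  stopifnot(nLinearModes <= latentDim, nQuadraticModes <= latentDim,
            vertexNoiseSD >= 0, retestNoiseSD >= 0, all(targetNoiseSD >= 0),
            all(c(nPretrainIdentities, framesPerIdentity, nFinetune,
                  nEval, nTest) >= 0))
  structure(list(seed = as.integer(seed), resolution = as.integer(resolution),
                 nPretrainIdentities = as.integer(nPretrainIdentities),
                 framesPerIdentity = as.integer(framesPerIdentity),
                 nFinetune = as.integer(nFinetune), nEval = as.integer(nEval),
                 nTest = as.integer(nTest), latentDim = as.integer(latentDim),
                 nLinearModes = as.integer(nLinearModes),
                 nQuadraticModes = as.integer(nQuadraticModes),
                 demoVariation = isTRUE(demoVariation),
                 vertexNoiseSD = vertexNoiseSD, retestNoiseSD = retestNoiseSD,
                 targetNoiseSD = targetNoiseSD),
            class = "synthConfig")
}

## Smooth displacement fields over the template. Mode 1 is always the girth
## mode (radial expansion weighted along the axis) so that latent 1 is the
## size axis weight correlates with; remaining modes are seeded random smooth
## fields. Quadratic bulge modes are radial fields concentrated on the torso
## band, emulating under-modeled abdominal shape detail.
.makeModes <- function(template, cfg) {
  V <- template@vertices
  zn <- V[, 3] / max(abs(V[, 3]))
  radial <- cbind(V[, 1], V[, 2], 0)
  rn <- sqrt(rowSums(radial^2)); rn[rn < 1e-9] <- 1
  radialU <- radial / rn

  girth <- radialU * (18 * exp(-((zn - 0.0) / 0.6)^2))
  linear <- list(girth)
  if (cfg$nLinearModes > 1L) for (m in 2:cfg$nLinearModes) {
    w <- stats::rnorm(3); ph <- stats::runif(1, 0, 2 * pi)
    fld <- sin((V %*% w) / 400 + ph)
    dirw <- stats::rnorm(3); dirw <- dirw / sqrt(sum(dirw^2))
    linear[[m]] <- 10 * as.numeric(fld) *
      (0.6 * radialU + 0.4 * matrix(dirw, nrow(V), 3, byrow = TRUE))
  }
  quad <- lapply(seq_len(cfg$nQuadraticModes), function(q) {
    band <- exp(-((zn + 0.05 - 0.10 * (q - 1)) / 0.22)^2)
    ph <- stats::runif(1, 0, 2 * pi)
    lobe <- 1 + 0.5 * cos(atan2(V[, 2], V[, 1]) * q + ph)
    radialU * (6 * band * lobe)
  })
  sexOffset <- radialU * (4 * exp(-((zn - 0.45) / 0.25)^2) -
                          4 * exp(-((zn + 0.35) / 0.25)^2))
  list(linear = linear, quad = quad, sexOffset = sexOffset)
}

## Per-sex monotone quadratic target maps: y_t = a_t + dW_t * weight
## + sum_k B[t,k] z_k + sum_k C[t,k] (z_k + 3)^2 (+ noise). B, C >= 0 and
## (z + 3) > 0 over the sampled range, so first and second partials in every
## shape coordinate are nonnegative. The quadratic terms span all latents —
## the shape-to-composition relation is nonlinear in the shape coordinates
## themselves, not only in the planted bulge directions — so a linear head on
## shape features cannot represent it. With nQuadraticModes = 0 the map is
## linear (the linear-limit cohort).
.makeTargetMap <- function(cfg) {
  tg <- compositionTargets()
  scl <- c(total_fat = 1, total_lean = 1.2, visceral_fat = 0.045,
           percent_fat = 0, trunk_fat = 0.5, trunk_lean = 0.6,
           arm_fat = 0.08, arm_lean = 0.12, leg_fat = 0.18, leg_lean = 0.25)
  one <- function() {
    k <- cfg$latentDim; q <- if (cfg$nQuadraticModes > 0) k else 0L
    B <- matrix(stats::runif(length(tg) * k, 0.2, 1.2), length(tg), k,
                dimnames = list(tg, NULL))
    C <- matrix(stats::runif(length(tg) * max(1, q), 0.15, 0.55), length(tg),
                max(1, q), dimnames = list(tg, NULL))
    if (q == 0) C <- C[, 0, drop = FALSE]
    a <- c(total_fat = 3, total_lean = 28, visceral_fat = 0.12,
           percent_fat = 0, trunk_fat = 1.5, trunk_lean = 16,
           arm_fat = 0.3, arm_lean = 2.2, leg_fat = 1.0, leg_lean = 6)
    dW <- c(total_fat = 0.16, total_lean = 0.38, visceral_fat = 0.006,
            percent_fat = 0, trunk_fat = 0.08, trunk_lean = 0.22,
            arm_fat = 0.012, arm_lean = 0.035, leg_fat = 0.028, leg_lean = 0.09)
    list(a = a, dW = dW, B = B * scl[tg], C = C * scl[tg])
  }
  list(male = one(), female = one())
}

## Evaluate the noiseless ground-truth map for one subject.
.evalTargetMap <- function(map, z, weight) {
  q <- ncol(map$C)
  y <- map$a + map$dW * weight + as.numeric(map$B %*% z) +
    if (q > 0) as.numeric(map$C %*% (z[seq_len(q)] + 3)^2) else 0
  y["percent_fat"] <- min(100, max(0, 100 * y["total_fat"] / weight))
  y
}

## Smooth pose deformation for the pretraining role: a forward lean of the
## upper body and a lateral leg sweep, both smoothly weighted along the axis.
.poseMesh <- function(V, lean, sweep2) {
  H <- max(abs(V[, 3]))
  zn <- V[, 3] / H
  # upper-body forward lean: smoothly weighted rotation in the (y, z) plane
  # about a pivot at 0.15 H
  a1 <- lean / (1 + exp(-(zn - 0.15) / 0.12))
  z0 <- 0.15 * H
  y2 <- V[, 2] * cos(a1) - (V[, 3] - z0) * sin(a1)
  z2 <- z0 + V[, 2] * sin(a1) + (V[, 3] - z0) * cos(a1)
  # lower-body lateral sweep: weighted rotation in the (x, z) plane about -0.25 H
  a2 <- sweep2 / (1 + exp((zn + 0.25) / 0.12))
  z1 <- -0.25 * H
  x3 <- V[, 1] * cos(a2) - (z2 - z1) * sin(a2)
  z3 <- z1 + V[, 1] * sin(a2) + (z2 - z1) * cos(a2)
  cbind(x3, y2, z3)
}

.subjectMesh <- function(gen, z, sex, heightCM, noiseSD) {
  V <- gen$template@vertices
  if (gen$cfg$demoVariation) {
    V <- V * (heightCM * 10 / 1700)             # stature scaling
    V <- V + gen$modes$sexOffset * if (sex == "male") 1 else -1
  }
  for (k in seq_along(gen$modes$linear)) V <- V + z[k] * gen$modes$linear[[k]]
  for (q in seq_along(gen$modes$quad)) V <- V + (z[q]^2) * gen$modes$quad[[q]]
  if (noiseSD > 0) V <- V + matrix(stats::rnorm(length(V), sd = noiseSD), nrow(V))
  V
}

#' Sample one synthetic subject
#'
#' Draws latents, sex, demographics, the subject's mesh (template + linear
#' modes + quadratic torso bulges + scan noise), an optional same-day
#' duplicate scan with fresh noise, and the ten noisy composition targets
#' from the monotone quadratic ground-truth map. Mass targets are
#' rejection-resampled if noise drives them negative.
#'
#' @param gen generator state from \code{\link{synthGenerator}}.
#' @param subjectId identifier string.
#' @param duplicate also generate a second scan.
#' @return list: \code{record} (one-row data.frame), \code{meshes} (list of
#'   vertex matrices), \code{z} (latent vector).
#' @export
sampleSubject <- function(gen, subjectId, duplicate = FALSE) {
  cfg <- gen$cfg
  z <- stats::rnorm(cfg$latentDim)
  sex <- if (stats::runif(1) < 0.5) "male" else "female"
  heightCM <- stats::rnorm(1, if (sex == "male") 178 else 164,
                           if (sex == "male") 7 else 6.5)
  heightCM <- min(max(heightCM, 140), 210)
  bmi <- 24 + 2.4 * z[1] + 1.1 * (if (cfg$latentDim > 1) z[2] else 0) +
    stats::rnorm(1, sd = 1.3)
  bmi <- min(max(bmi, 16), 45)
  weight <- round(bmi * (heightCM / 100)^2, 1)
  age <- round(stats::runif(1, 18, 80))
  map <- gen$targetMap[[sex]]
  yTrue <- .evalTargetMap(map, z, weight)
  tg <- compositionTargets()
  resamples <- 0L
  repeat {
    y <- yTrue + stats::rnorm(length(tg), sd = cfg$targetNoiseSD[tg])
    names(y) <- tg
    y["percent_fat"] <- min(100, max(0, yTrue["percent_fat"] +
                                       stats::rnorm(1, sd = cfg$targetNoiseSD["percent_fat"])))
    if (all(y[setdiff(tg, "percent_fat")] >= 0) || resamples >= 100L) break
    resamples <- resamples + 1L
  }
  y[setdiff(tg, "percent_fat")] <- pmax(y[setdiff(tg, "percent_fat")], 0)
  meshes <- list(.subjectMesh(gen, z, sex, heightCM, cfg$vertexNoiseSD))
  if (duplicate)
    meshes[[2]] <- .subjectMesh(gen, z, sex, heightCM, cfg$retestNoiseSD)
  rec <- data.frame(subject_id = subjectId, sex = sex, height = heightCM,
                    weight = weight, age = age, resamples = resamples)
  for (t in tg) rec[[t]] <- unname(y[t])
  list(record = rec, meshes = meshes, z = z)
}

#' Initialize the synthetic generator state
#'
#' Builds the template, the shape modes and the per-sex target maps from the
#' config seed. Splitting generator construction from sampling keeps the
#' ground truth fixed while subjects are drawn.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return list: template, modes, targetMap, cfg.
#' @export
synthGenerator <- function(cfg) {
  stopifnot(inherits(cfg, "synthConfig"))
  set.seed(cfg$seed)
  template <- makeTemplate(cfg$resolution)
  modes <- .makeModes(template, cfg)
  targetMap <- .makeTargetMap(cfg)
  list(template = template, modes = modes, targetMap = targetMap, cfg = cfg)
}

#' Check monotonicity of the ground-truth composition map
#'
#' Evaluates each target along a grid in every shape coordinate (others held
#' at 0) and verifies nondecreasing values and nondecreasing increments —
#' the monotone first- and second-derivative construction.
#'
#' @param gen generator state from \code{\link{synthGenerator}}.
#' @param gridN grid points over [-3, 3].
#' @return TRUE (invisibly) or an error describing the violation.
#' @export
checkMonotoneMap <- function(gen, gridN = 20L) {
  grid <- seq(-3, 3, length.out = gridN)
  tg <- setdiff(compositionTargets(), "percent_fat")
  for (sex in names(gen$targetMap)) {
    map <- gen$targetMap[[sex]]
    for (k in seq_len(gen$cfg$latentDim)) {
      vals <- vapply(grid, function(g) {
        z <- numeric(gen$cfg$latentDim); z[k] <- g
        .evalTargetMap(map, z, weight = 75)[tg]
      }, numeric(length(tg)))
      d1 <- t(diff(t(vals)))
      if (any(d1 < -1e-9))
        stop("ground-truth map not monotone in latent ", k, " (", sex, ")")
      if (ncol(d1) > 1 && any(t(diff(t(d1))) < -1e-9))
        stop("ground-truth map has decreasing increments in latent ", k, " (", sex, ")")
    }
  }
  invisible(TRUE)
}
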