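#' Construct a ShapeCohort
#'
#' @param coords 3N x nScans numeric matrix of flattened vertex coordinates
#'   (vertex-major), one column per scan.
#' @param colData data.frame/DataFrame of per-scan annotations (subject_id,
#'   sex, height, weight, age, scan, split, and the composition targets).
#' @param template the shared \linkS4class{TopoMesh} template.
#' @param cfg generator config, kept in metadata for regeneration.
#' @param groundTruth list of ground-truth objects (latents, target maps).
#' @return a \linkS4class{ShapeCohort}.
#' @export
ShapeCohort <- function(coords, colData, template, cfg = NULL, groundTruth = NULL) {
  se <- SummarizedExperiment(assays = list(coords = as.matrix(coords)),
                             colData = S4Vectors::DataFrame(colData))
  obj <- new("ShapeCohort", se)
  metadata(obj) <- list(template = template, cfg = cfg, groundTruth = groundTruth)
  validObject(obj)
  obj
}

#' Cohort accessors
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @param split optional split filter (\code{"pretrain"}, \code{"finetune"},
#'   \code{"eval"}, \code{"test"}).
#' @param scan optional scan-index filter (1 or 2).
#' @name cohortAccessors
NULL

#' @rdname cohortAccessors
#' @export
cohortTemplate <- function(cohort) metadata(cohort)$template

.cohortSel <- function(cohort, split = NULL, scan = NULL) {
  cd <- colData(cohort)
  keep <- rep(TRUE, nrow(cd))
  if (!is.null(split)) keep <- keep & cd$split %in% split
  if (!is.null(scan)) keep <- keep & cd$scan %in% scan
  which(keep)
}

#' @rdname cohortAccessors
#' @param j scan (column) index.
#' @export
cohortMesh <- function(cohort, j) {
  tmpl <- cohortTemplate(cohort)
  TopoMesh(unflattenVertices(assay(cohort, "coords")[, j]), tmpl@faces,
           topologyId = tmpl@topologyId)
}

#' @rdname cohortAccessors
#' @export
cohortMeshes <- function(cohort, split = NULL, scan = 1L) {
  idx <- .cohortSel(cohort, split, scan)
  lapply(idx, function(j) cohortMesh(cohort, j))
}

#' @rdname cohortAccessors
#' @export
cohortRecords <- function(cohort, split = NULL, scan = 1L) {
  idx <- .cohortSel(cohort, split, scan)
  as.data.frame(colData(cohort)[idx, , drop = FALSE])
}

#' Generate a synthetic cohort
#'
#' Draws the full study-design roles from one seed: a pose-varied pretraining
#' set (few identities, smooth limb-angle curves across frames), single-pose
#' finetuning and evaluation sets, and a test set with same-day duplicate
#' scans. Split membership is disjoint at the subject level. Finetuning
#' subjects are tagged into two named partitions (ensembleA / ensembleB) so
#' data-withholding experiments have named subsets to exclude. When \code{dir}
#' is given, the dataset is also materialized on disk (PLY meshes, records
#' and pairs CSVs, split lists, a YAML manifest with config + checksum, and a
#' ground-truth archive).
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param dir optional output directory.
#' @param force overwrite a non-empty directory.
#' @return a \linkS4class{ShapeCohort} (invisibly when writing to disk).
#' @export
generateCohort <- function(cfg, dir = NULL, force = FALSE) {
  gen <- synthGenerator(cfg)
  n <- nVertices(gen$template)
  cols <- list(); recs <- list(); zs <- list()
  addScan <- function(V, rec) {
    cols[[length(cols) + 1L]] <<- flattenVertices(V)
    recs[[length(recs) + 1L]] <<- rec
  }

  # pretraining role: few identities, pose varied along smooth angle curves
  for (i in seq_len(cfg$nPretrainIdentities)) {
    s <- sampleSubject(gen, sprintf("pre%03d", i))
    phase <- stats::runif(2, 0, 2 * pi)
    base <- s$meshes[[1]]
    for (f in seq_len(cfg$framesPerIdentity)) {
      u <- 2 * pi * f / cfg$framesPerIdentity
      V <- .poseMesh(base, lean = 0.45 * sin(u + phase[1]),
                     sweep2 = 0.30 * sin(2 * u + phase[2]))
      rec <- s$record
      rec$scan <- f; rec$split <- "pretrain"; rec$group <- "pretrain"
      addScan(V, rec)
    }
    zs[[s$record$subject_id]] <- s$z
  }

  roleOf <- c(finetune = "nFinetune", eval = "nEval", test = "nTest")
  for (role in names(roleOf)) {
    nRole <- cfg[[roleOf[role]]]
    for (i in seq_len(nRole)) {
      sid <- sprintf("%s%04d", substr(role, 1, 2), i)
      s <- sampleSubject(gen, sid, duplicate = (role == "test"))
      for (sc in seq_along(s$meshes)) {
        rec <- s$record
        rec$scan <- sc; rec$split <- role
        rec$group <- if (role == "finetune")
          c("ensembleA", "ensembleB")[1L + (i %% 2L)] else role
        addScan(s$meshes[[sc]], rec)
      }
      zs[[sid]] <- s$z
    }
  }

  coords <- do.call(cbind, cols)
  cd <- do.call(rbind, recs)
  rownames(cd) <- NULL
  colnames(coords) <- sprintf("%s_s%d", cd$subject_id, cd$scan)
  zmat <- do.call(rbind, zs)
  cohort <- ShapeCohort(coords, cd, gen$template, cfg = cfg,
                        groundTruth = list(z = zmat, targetMap = gen$targetMap,
                                           modes = gen$modes))
  if (!is.null(dir)) {
    writeCohortDir(cohort, dir, force = force)
    return(invisible(cohort))
  }
  cohort
}

.cohortChecksum <- function(cohort) {
  x <- assay(cohort, "coords")
  sprintf("%.6f/%.6f/%d", sum(x) / length(x), sum(abs(x)) / length(x), length(x))
}

#' Write / read a cohort directory
#'
#' Layout: \code{meshes/*.ply} (ascii), \code{template.ply},
#' \code{records.csv}, \code{pairs.csv} (duplicate-scan listing),
#' \code{splits/*.txt}, \code{manifest.yaml} (config + seed + checksum) and
#' \code{ground_truth/} CSVs (latents and per-sex target-map coefficients).
#'
#' @param cohort a \linkS4class{ShapeCohort}.
#' @param dir directory path.
#' @param force overwrite a non-empty directory.
#' @export
writeCohortDir <- function(cohort, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    .stopCond("shapecompValueError",
              paste0("output directory not empty (use force = TRUE): ", dir))
  dir.create(file.path(dir, "meshes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "splits"), showWarnings = FALSE)
  dir.create(file.path(dir, "ground_truth"), showWarnings = FALSE)
  tmpl <- cohortTemplate(cohort)
  writeMesh(tmpl, file.path(dir, "template.ply"))
  cd <- as.data.frame(colData(cohort))
  for (j in seq_len(ncol(cohort)))
    writeMesh(cohortMesh(cohort, j),
              file.path(dir, "meshes", paste0(colnames(cohort)[j], ".ply")))
  cd$mesh_file <- file.path("meshes", paste0(colnames(cohort), ".ply"))
  utils::write.csv(cd, file.path(dir, "records.csv"), row.names = FALSE)
  test1 <- cd[cd$split == "test" & cd$scan == 1L, ]
  test2 <- cd[cd$split == "test" & cd$scan == 2L, ]
  pairs <- merge(test1[, c("subject_id", "mesh_file")],
                 test2[, c("subject_id", "mesh_file")],
                 by = "subject_id", suffixes = c("_scan1", "_scan2"))
  utils::write.csv(pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  for (sp in unique(cd$split))
    writeLines(sort(unique(cd$subject_id[cd$split == sp])),
               file.path(dir, "splits", paste0(sp, ".txt")))
  gt <- metadata(cohort)$groundTruth
  if (!is.null(gt)) {
    z <- data.frame(subject_id = rownames(gt$z), gt$z)
    colnames(z) <- c("subject_id", paste0("z", seq_len(ncol(gt$z))))
    utils::write.csv(z, file.path(dir, "ground_truth", "latents.csv"),
                     row.names = FALSE)
    for (sex in names(gt$targetMap)) {
      m <- gt$targetMap[[sex]]
      df <- data.frame(target = names(m$a), a = m$a, dW = m$dW,
                       m$B, m$C, check.names = FALSE)
      colnames(df) <- c("target", "a", "dW",
                        paste0("B", seq_len(ncol(m$B))),
                        if (ncol(m$C)) paste0("C", seq_len(ncol(m$C))))
      utils::write.csv(df, file.path(dir, "ground_truth",
                                     paste0("map_", sex, ".csv")),
                       row.names = FALSE)
    }
  }
  cfg <- metadata(cohort)$cfg
  manifest <- list(config = lapply(unclass(cfg), function(x)
                     if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
                   n_scans = ncol(cohort),
                   n_subjects = length(unique(cd$subject_id)),
                   checksum = .cohortChecksum(cohort))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname writeCohortDir
#' @export
readCohortDir <- function(dir) {
  cd <- utils::read.csv(file.path(dir, "records.csv"))
  tmpl <- readMesh(file.path(dir, "template.ply"))
  coords <- vapply(cd$mesh_file, function(f)
    flattenVertices(readMesh(file.path(dir, f),
                             expectedTopology = tmpl@topologyId)@vertices),
    numeric(3L * nVertices(tmpl)))
  colnames(coords) <- sprintf("%s_s%d", cd$subject_id, cd$scan)
  cd$mesh_file <- NULL
  ShapeCohort(coords, cd, tmpl)
}

#' Regenerate a cohort from its manifest and verify the checksum
#'
#' @param manifestPath path to \code{manifest.yaml}.
#' @return the regenerated \linkS4class{ShapeCohort}; errors if the stored
#'   checksum does not match.
#' @export
regenerateCohort <- function(manifestPath) {
  man <- yaml::read_yaml(manifestPath)
  cfgl <- man$config
  cfgl$targetNoiseSD <- unlist(cfgl$targetNoiseSD)
  cfg <- do.call(synthConfig, cfgl)
  cohort <- generateCohort(cfg)
  if (!identical(.cohortChecksum(cohort), man$checksum))
    .stopCond("shapecompValueError",
              "regenerated cohort does not match the manifest checksum")
  cohort
}
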