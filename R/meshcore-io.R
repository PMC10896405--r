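## Error helpers: typed conditions so callers can distinguish topology errors,
## parse errors, etc. from generic failures.
.stopCond <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "shapecompError", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## Deterministic token for a triangulation: vertex/face counts folded with the
## face index list so meshes from different templates never silently mix.
.topoToken <- function(vertices, faces) {
  h <- 0
  if (length(faces)) {
    idx <- as.numeric(t(faces))
    m <- 2147483629
    for (chunk in split(idx, ceiling(seq_along(idx) / 4096))) {
      h <- (h * 31 + sum(chunk * (seq_along(chunk) %% 97 + 1))) %% m
    }
  }
  sprintf("topo-%dv-%df-%.0f", nrow(vertices), nrow(faces), h)
}

#' Construct a TopoMesh
#'
#' @param vertices numeric N x 3 matrix (mm).
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @param topologyId optional token naming the triangulation; derived
#'   deterministically from the face list when omitted, so two meshes built on
#'   the same template agree and meshes on different templates do not.
#' @return a \linkS4class{TopoMesh}.
#' @export
TopoMesh <- function(vertices, faces, topologyId = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = NULL)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (is.null(topologyId)) topologyId <- .topoToken(vertices, faces)
  new("TopoMesh", vertices = vertices, faces = faces, topologyId = topologyId)
}

#' Read a mesh from OBJ or PLY
#'
#' Supports Wavefront OBJ (ascii) and PLY in both ascii and binary
#' little-endian encodings. Face rows must be triangles.
#'
#' @param path file path.
#' @param fmt \code{"auto"} (by extension), \code{"obj"} or \code{"ply"}.
#' @param topologyId optional token to stamp on the mesh; when
#'   \code{expectedTopology} is given the mesh's derived token must match it.
#' @param expectedTopology optional topology token to validate against.
#' @return a \linkS4class{TopoMesh}.
#' @export
readMesh <- function(path, fmt = c("auto", "obj", "ply"),
                     topologyId = NULL, expectedTopology = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path))
    .stopCond("shapecompParseError", paste0("mesh file not found: ", path))
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply"))
      .stopCond("shapecompParseError",
                paste0("cannot infer mesh format from extension '", ext, "'"))
    fmt <- ext
  }
  mesh <- if (fmt == "obj") .readOBJ(path) else .readPLY(path)
  mesh <- TopoMesh(mesh$vertices, mesh$faces, topologyId = topologyId)
  if (!is.null(expectedTopology) && mesh@topologyId != expectedTopology)
    .stopCond("shapecompTopologyError",
              sprintf("topology mismatch: %s has '%s', expected '%s'",
                      path, mesh@topologyId, expectedTopology))
  mesh
}

#' Write a mesh to OBJ or PLY
#'
#' @param mesh a \linkS4class{TopoMesh}.
#' @param path output path.
#' @param fmt \code{"auto"}, \code{"obj"} or \code{"ply"}.
#' @param binary for PLY, write binary little-endian instead of ascii.
#'   Coordinates are stored as float64 so write-then-read round-trips to
#'   better than 1e-6 mm.
#' @return \code{path}, invisibly.
#' @export
writeMesh <- function(mesh, path, fmt = c("auto", "obj", "ply"), binary = FALSE) {
  stopifnot(is(mesh, "TopoMesh"))
  fmt <- match.arg(fmt)
  if (fmt == "auto") fmt <- tolower(tools::file_ext(path))
  if (fmt == "obj") .writeOBJ(mesh, path) else if (fmt == "ply")
    .writePLY(mesh, path, binary = binary)
  else .stopCond("shapecompParseError", paste0("unknown mesh format: ", fmt))
  invisible(path)
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vparts <- list(); fparts <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (startsWith(ln, "v ")) {
      xyz <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]][2:4]))
      if (anyNA(xyz))
        .stopCond("shapecompParseError",
                  sprintf("OBJ parse error at line %d: bad vertex '%s'", k, ln))
      vparts[[length(vparts) + 1L]] <- xyz
    } else if (startsWith(ln, "f ")) {
      toks <- strsplit(ln, "[[:space:]]+")[[1]][-1]
      idx <- suppressWarnings(as.integer(vapply(strsplit(toks, "/"), `[`, "", 1)))
      if (anyNA(idx) || length(idx) != 3L)
        .stopCond("shapecompParseError",
                  sprintf("OBJ parse error at line %d: need triangle face '%s'", k, ln))
      fparts[[length(fparts) + 1L]] <- idx
    }
  }
  list(vertices = do.call(rbind, vparts),
       faces = if (length(fparts)) do.call(rbind, fparts) else
         matrix(integer(), ncol = 3))
}

.writeOBJ <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh@vertices
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh@faces
  if (nrow(f)) writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

.plyTypeInfo <- function(type) {
  switch(type,
    "char" = , "int8" = list(what = "integer", size = 1, signed = TRUE),
    "uchar" = , "uint8" = list(what = "integer", size = 1, signed = FALSE),
    "short" = , "int16" = list(what = "integer", size = 2, signed = TRUE),
    "ushort" = , "uint16" = list(what = "integer", size = 2, signed = FALSE),
    "int" = , "int32" = list(what = "integer", size = 4, signed = TRUE),
    "uint" = , "uint32" = list(what = "integer", size = 4, signed = TRUE),
    "float" = , "float32" = list(what = "numeric", size = 4, signed = TRUE),
    "double" = , "float64" = list(what = "numeric", size = 8, signed = TRUE),
    .stopCond("shapecompParseError", paste0("unsupported PLY type: ", type)))
}

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(); repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) .stopCond("shapecompParseError",
                               "PLY parse error: header ended before end_header")
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
  }
  if (trimws(hdr[1]) != "ply")
    .stopCond("shapecompParseError", "PLY parse error at line 1: missing 'ply' magic")
  fmtLine <- grep("^format ", hdr, value = TRUE)
  if (!length(fmtLine))
    .stopCond("shapecompParseError", "PLY parse error: no format line")
  binary <- grepl("binary_little_endian", fmtLine[1])
  if (!binary && !grepl("ascii", fmtLine[1]))
    .stopCond("shapecompParseError",
              paste0("PLY parse error: unsupported format '", fmtLine[1], "'"))

  # parse element/property declarations in order
  elements <- list(); cur <- NULL
  for (k in seq_along(hdr)) {
    toks <- strsplit(trimws(hdr[k]), "[[:space:]]+")[[1]]
    if (toks[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      if (toks[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[5], list = TRUE, countType = toks[3], valueType = toks[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = toks[3], list = FALSE, type = toks[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex))
    .stopCond("shapecompParseError", "PLY parse error: no vertex element")

  readAscii <- function() {
    vals <- scan(con, what = character(), quiet = TRUE)
    ptr <- 1L
    out <- list()
    for (el in elements) {
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        nv <- length(el$props)
        m <- matrix(as.numeric(vals[ptr + seq_len(el$count * nv) - 1L]),
                    ncol = nv, byrow = TRUE)
        ptr <- ptr + el$count * nv
        out$vertices <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        faces <- matrix(integer(), nrow = el$count, ncol = 3)
        for (i in seq_len(el$count)) {
          cnt <- as.integer(vals[ptr]); ptr <- ptr + 1L
          if (cnt != 3L)
            .stopCond("shapecompParseError",
                      sprintf("PLY parse error: face %d has %d vertices (triangles only)", i, cnt))
          faces[i, ] <- as.integer(vals[ptr + 0:2]); ptr <- ptr + 3L
        }
        out$faces <- faces + 1L
      } else {
        # skip unknown scalar-only elements
        nv <- length(el$props)
        ptr <- ptr + el$count * nv
      }
    }
    out
  }

  readBinaryLE <- function() {
    out <- list()
    for (el in elements) {
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        m <- matrix(0, nrow = el$count, ncol = length(el$props))
        infos <- lapply(el$props, function(p) .plyTypeInfo(p$type))
        same <- length(unique(vapply(el$props, `[[`, "", "type"))) == 1L
        if (same) {
          ti <- infos[[1]]
          raw <- readBin(con, ti$what, n = el$count * length(el$props),
                         size = ti$size, endian = "little", signed = ti$signed)
          m <- matrix(raw, ncol = length(el$props), byrow = TRUE)
        } else {
          for (i in seq_len(el$count)) for (j in seq_along(infos)) {
            ti <- infos[[j]]
            m[i, j] <- readBin(con, ti$what, n = 1, size = ti$size,
                               endian = "little", signed = ti$signed)
          }
        }
        out$vertices <- m[, match(c("x", "y", "z"), pn), drop = FALSE]
      } else if (el$name == "face") {
        p <- el$props[[1]]
        ci <- .plyTypeInfo(p$countType); vi <- .plyTypeInfo(p$valueType)
        faces <- matrix(integer(), nrow = el$count, ncol = 3)
        for (i in seq_len(el$count)) {
          cnt <- readBin(con, ci$what, n = 1, size = ci$size,
                         endian = "little", signed = ci$signed)
          if (cnt != 3L)
            .stopCond("shapecompParseError",
                      sprintf("PLY parse error: face %d has %d vertices (triangles only)", i, cnt))
          faces[i, ] <- readBin(con, vi$what, n = 3, size = vi$size,
                                endian = "little", signed = vi$signed)
        }
        out$faces <- faces + 1L
      }
    }
    out
  }

  res <- if (binary) readBinaryLE() else readAscii()
  if (is.null(res$faces)) res$faces <- matrix(integer(), ncol = 3)
  res
}

.writePLY <- function(mesh, path, binary = FALSE) {
  v <- mesh@vertices; f <- mesh@faces
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  con <- file(path, if (binary) "wb" else "w")
  on.exit(close(con))
  if (binary) {
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(v)), con, size = 8, endian = "little")
    if (nrow(f)) for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    if (nrow(f)) writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
}
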