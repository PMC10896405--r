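test_that("OBJ and PLY round-trips preserve coordinates to 1e-6 mm", {
  tmpl <- sphereMesh(5, 8, radius = 900)
  m <- randomMesh(tmpl, sd = 5, seed = 42)
  for (spec in list(list(ext = "obj"), list(ext = "ply", binary = FALSE),
                    list(ext = "ply", binary = TRUE))) {
    path <- tempfile(fileext = paste0(".", spec$ext))
    writeMesh(m, path, binary = isTRUE(spec$binary))
    m2 <- readMesh(path)
    expect_lt(max(abs(m2@vertices - m@vertices)), 1e-6)
    expect_identical(m2@faces, m@faces)
    expect_identical(m2@topologyId, m@topologyId)  # derived from same faces
  }
})

test_that("a minimal one-triangle OBJ parses and malformed input names the line", {
  p <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), p)
  m <- readMesh(p)
  expect_equal(nVertices(m), 3L)
  expect_equal(nrow(meshFaces(m)), 1L)

  writeLines(c("v 0 0 0", "v 1 0 x", "f 1 2 3"), p)
  expect_error(readMesh(p), "line 2", class = "shapecompParseError")
})

test_that("topology validation distinguishes templates and flags mismatches", {
  a <- sphereMesh(4, 6); b <- sphereMesh(5, 6)
  expect_false(a@topologyId == b@topologyId)
  p <- tempfile(fileext = ".ply")
  writeMesh(a, p)
  expect_error(readMesh(p, expectedTopology = b@topologyId),
               class = "shapecompTopologyError")
  expect_error(vertexMAE(a, b), class = "shapecompTopologyError")
})

test_that("PLY writer agrees with an independent reader (trimesh)", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  m <- randomMesh(sphereMesh(4, 6), sd = 0.2, seed = 7)
  p <- tempfile(fileext = ".ply")
  writeMesh(m, p, binary = TRUE)
  out <- suppressWarnings(system2("python", c("-c", shQuote(paste0(
    "import trimesh, numpy as np; t = trimesh.load('", p,
    "', process=False); print(round(float(np.abs(np.asarray(t.vertices)).sum()), 9));",
    " print(int(np.asarray(t.faces).sum()))"))), stdout = TRUE, stderr = TRUE))
  skip_if(length(out) < 2 || is.na(suppressWarnings(as.numeric(out[1]))),
          "trimesh unavailable")
  expect_equal(as.numeric(out[1]), round(sum(abs(m@vertices)), 9), tolerance = 1e-9)
  expect_equal(as.numeric(out[2]), sum(m@faces - 1L))
})

test_that("vertexMAE matches the per-vertex distance-loop oracle and its axioms", {
  tmpl <- sphereMesh(4, 6)
  a <- randomMesh(tmpl, seed = 1); b <- randomMesh(tmpl, seed = 2)
  loop <- mean(vapply(seq_len(nVertices(a)), function(i)
    sqrt(sum((a@vertices[i, ] - b@vertices[i, ])^2)), numeric(1)))
  expect_equal(vertexMAE(a, b), loop, tolerance = 1e-12)
  expect_identical(vertexMAE(a, a), 0)
  shifted <- TopoMesh(sweep(a@vertices, 2, c(1, 0, 0), "+"), a@faces, a@topologyId)
  expect_equal(vertexMAE(a, shifted), 1, tolerance = 1e-12)
  # symmetry and triangle inequality on random triples
  for (s in 1:5) {
    x <- randomMesh(tmpl, seed = 100 + s); y <- randomMesh(tmpl, seed = 200 + s)
    z <- randomMesh(tmpl, seed = 300 + s)
    expect_equal(vertexMAE(x, y), vertexMAE(y, x))
    expect_lte(vertexMAE(x, z), vertexMAE(x, y) + vertexMAE(y, z) + 1e-12)
  }
})

test_that("stride-2 decimation of the C8 cycle matches the greedy-cover oracle", {
  adj <- cycleAdj(8)
  h <- buildHierarchyGraph(adj, 1, radius = 2, stride = 2)
  expect_identical(h@levelSizes, c(8L, 4L))
  expect_identical(h@levels[[1]]@vertexIds, strideCoverOracle(adj, 2L))
})

test_that("stride 1 retains all vertices (identity sampling)", {
  m <- sphereMesh(4, 6)
  h <- buildHierarchy(m, 1, radius = 1, stride = 1)
  expect_identical(h@levels[[1]]@vertexIds, seq_len(nVertices(m)))
})

test_that("hierarchy on the template is deterministic, decreasing, and covering", {
  tmpl <- makeTemplate(1)  # 434 vertices
  h1 <- buildHierarchy(tmpl, 4)
  h2 <- buildHierarchy(tmpl, 4)
  expect_identical(h1@levels[[2]]@neighborhoods, h2@levels[[2]]@neighborhoods)
  expect_true(all(diff(h1@levelSizes) < 0))
  expect_lt(rev(h1@levelSizes)[1], 30)
  # retained sets match the independent greedy oracle level by level
  adj <- graphAdjacency(tmpl)
  for (l in seq_along(h1@levels)) {
    expect_identical(h1@levels[[l]]@vertexIds, strideCoverOracle(adj, 2L))
    # coverage: union of neighborhoods is the whole parent vertex set
    expect_setequal(unique(unlist(h1@levels[[l]]@neighborhoods)),
                    seq_along(adj))
    adj <- h1@levels[[l]]@childAdjacency
  }
})

test_that("over-deep hierarchies error naming the failing level", {
  adj <- cycleAdj(4)
  expect_error(buildHierarchyGraph(adj, 5, radius = 2, stride = 2),
               "level", class = "shapecompHierarchyError")
})

test_that("hierarchy archive round-trips through its JSON serialization", {
  h <- buildHierarchy(sphereMesh(5, 8), 2)
  p <- tempfile(fileext = ".json")
  saveHierarchy(h, p)
  h2 <- loadHierarchy(p)
  expect_identical(h2@levelSizes, h@levelSizes)
  expect_identical(h2@topologyId, h@topologyId)
  expect_identical(lapply(h2@levels, function(l) l@neighborhoods),
                   lapply(h@levels, function(l) l@neighborhoods))
})
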