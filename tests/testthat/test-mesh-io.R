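test_that("binary STL round-trips the icosphere with expected combinatorics", {
  m <- makeFixture("sphere", size = 100, resolution = 3)$mesh
  expect_equal(nVertices(m), 642L)   # V - E + F = 2 for the icosphere
  expect_equal(nFaces(m), 1280L)
  tmp <- tempfile(fileext = ".stl")
  writeSTL(m, tmp)
  m2 <- readSTL(tmp)
  expect_equal(nVertices(m2), 642L)
  expect_equal(nFaces(m2), 1280L)
  expect_true(isClosed(m2))
  expect_gt(craniocurv:::signedVolume(m2), 0)
  # vertex multisets identical up to re-indexing and float32 quantisation
  v1 <- vertices(m)
  v2 <- vertices(m2)
  nearest <- vapply(seq_len(nrow(v2)), function(i) {
    min(sqrt(rowSums((v1 - matrix(v2[i, ], nrow(v1), 3L, byrow = TRUE))^2)))
  }, numeric(1L))
  expect_lt(max(nearest), 1e-4)
})

test_that("ASCII STL with duplicated corners reads identically to binary", {
  m <- makeFixture("sphere", size = 50, resolution = 2)$mesh
  bin <- tempfile(fileext = ".stl")
  writeSTL(m, bin)
  mb <- readSTL(bin)
  v <- vertices(m)
  f <- faces(m)
  lines <- c("solid fixture")
  for (i in seq_len(nrow(f))) {
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %.9f %.9f %.9f",
                       v[f[i, ], 1L], v[f[i, ], 2L], v[f[i, ], 3L]),
               "  endloop", " endfacet")
  }
  lines <- c(lines, "endsolid fixture")
  asc <- tempfile(fileext = ".stl")
  writeLines(lines, asc)
  ma <- readSTL(asc)
  expect_equal(nVertices(ma), nVertices(mb))
  expect_equal(nFaces(ma), nFaces(mb))
  expect_equal(surfaceArea(ma), surfaceArea(m), tolerance = 1e-6)
})

test_that("orientation repair fixes randomly flipped windings, outward, idempotently", {
  m <- makeFixture("sphere", size = 100, resolution = 3)$mesh
  f <- faces(m)
  set.seed(11)
  flip <- sample(nrow(f), nrow(f) %/% 2L)
  f[flip, ] <- f[flip, c(1L, 3L, 2L)]
  repaired <- cleanMesh(TriangleMesh(vertices(m), f, clean = FALSE))
  vn <- vertexNormals(repaired)
  ctr <- meshCentroid(repaired)
  outwardness <- rowSums(vn * (vertices(repaired) -
    matrix(ctr, nVertices(repaired), 3L, byrow = TRUE)))
  expect_true(all(outwardness > 0))
  twice <- cleanMesh(repaired)
  expect_identical(faces(twice), faces(repaired))
  expect_identical(vertices(twice), vertices(repaired))
})

test_that("unreadable and degenerate STL inputs raise clear errors", {
  bad <- tempfile(fileext = ".stl")
  writeLines("not a mesh at all", bad)
  expect_error(readSTL(bad), "STL")
  expect_error(readSTL(tempfile(fileext = ".stl")), "not found")
  # a single triangle collapses below 4 vertices
  tri <- TriangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      rbind(c(1L, 2L, 3L)), clean = FALSE)
  one <- tempfile(fileext = ".stl")
  writeSTL(tri, one)
  expect_error(readSTL(one), "degenerate")
})

test_that("landmarks snap to the exact surface with recorded distances", {
  m <- sphereFixture(3L, 100)$mesh
  lmj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    glabella = c(0, 0, 100.5),        # 0.5 mm off the sphere, radially
    anterior_fontanelle = c(0, 100, 0),
    rim_left = matrix(c(10, 99, 5, 20, 97, 5), 2L, 3L, byrow = TRUE),
    rim_right = matrix(c(-10, 99, 5, -20, 97, 5), 2L, 3L, byrow = TRUE)
  ), lmj, digits = NA)
  lm <- readLandmarks(lmj, m)
  expect_equal(unname(lm@snapDistances["glabella"]), 0.5, tolerance = 0.05)
  # snapped point is on (a facet of) the sphere
  expect_lt(abs(sqrt(sum(lm@glabella^2)) - 100), 1)
})

test_that("landmark schema and placement violations are named in errors", {
  m <- sphereFixture(3L, 100)$mesh
  incomplete <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    glabella = c(0, 0, 100), anterior_fontanelle = c(0, 100, 0),
    rim_left = matrix(c(10, 99, 5, 20, 97, 5), 2L, 3L, byrow = TRUE)
  ), incomplete, digits = NA)
  expect_error(readLandmarks(incomplete, m), "rim_right")
  far <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    glabella = c(0, 0, 150),          # 50 mm off: a frame mismatch
    anterior_fontanelle = c(0, 100, 0),
    rim_left = matrix(c(10, 99, 5, 20, 97, 5), 2L, 3L, byrow = TRUE),
    rim_right = matrix(c(-10, 99, 5, -20, 97, 5), 2L, 3L, byrow = TRUE)
  ), far, digits = NA)
  expect_error(readLandmarks(far, m), "glabella")
})

test_that("long-format CSV landmarks pass polylines through in order", {
  m <- sphereFixture(3L, 100)$mesh
  ang <- seq(-0.3, 0.3, length.out = 5L)
  rimL <- cbind(100 * sin(ang), 100 * cos(ang) * 0.99, rep(5, 5L))
  d <- rbind(
    data.frame(subject_id = "s1", landmark = "glabella", ordinal = 1,
               x = 0, y = 0, z = 100),
    data.frame(subject_id = "s1", landmark = "anterior_fontanelle",
               ordinal = 1, x = 0, y = 100, z = 0),
    data.frame(subject_id = "s1", landmark = "rim_left",
               ordinal = 1:5, x = rimL[, 1L], y = rimL[, 2L], z = rimL[, 3L]),
    data.frame(subject_id = "s1", landmark = "rim_right",
               ordinal = 1:2, x = c(-10, -20), y = c(99, 97), z = c(5, 5)))
  csv <- tempfile(fileext = ".csv")
  write.csv(d, csv, row.names = FALSE)
  lm <- readLandmarks(csv, m)
  expect_equal(nrow(lm@rimLeft), 5L)
  expect_equal(nrow(lm@rimRight), 2L)
  # order preserved: parameters along the rim increase
  dx <- diff(lm@rimLeft[, 1L])
  expect_true(all(dx > 0))
})

test_that("label tables are validated", {
  good <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = c("a", "b"),
                       clinician_label = c("operative", "conservative")),
            good, row.names = FALSE)
  d <- readLabels(good)
  expect_equal(nrow(d), 2L)
  dup <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = c("a", "a"),
                       clinician_label = c("operative", "operative")),
            dup, row.names = FALSE)
  expect_error(readLabels(dup), "duplicate")
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = "a", clinician_label = "surgery"),
            bad, row.names = FALSE)
  expect_error(readLabels(bad), "conservative")
})
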