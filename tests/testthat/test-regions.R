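test_that("mid-forehead strip respects the generator's true midline", {
  h <- headFixture(0.5, 0.5)
  mask <- segmentMidforehead(h$mesh, h$landmarks, 10)
  # every selected vertex within 5 mm of the true symmetry plane x = 0
  xs <- vertices(h$mesh)[regionVertices(mask), 1L]
  expect_true(all(abs(xs) <= 5 + 1e-9))
  # membership re-check: within axial extent of the glabella-fontanelle axis
  g <- h$landmarks@glabella
  af <- h$landmarks@anteriorFontanelle
  axis <- af - g
  p <- vertices(h$mesh)[regionVertices(mask), , drop = FALSE]
  t <- (p - matrix(g, nrow(p), 3L, byrow = TRUE)) %*% axis / sum(axis^2)
  expect_true(all(t >= 0 & t <= 1))
  # the strip sits on the front of the head, not the antipodal back wall
  expect_true(all(p[, 2L] > 0))
})

test_that("degenerate or empty strip selections raise segmentation errors", {
  h <- headFixture(0.5, 0.5)
  expect_error(segmentMidforehead(h$mesh, h$landmarks, 0), "width")
  expect_error(segmentMidforehead(h$mesh, h$landmarks, -3), "width")
})

test_that("a strip on a sphere recovers the sphere's curvature", {
  sph <- sphereFixture(4L, 100)
  # antipodal landmark pair: the spec's degenerate-but-legal configuration
  lm <- new("LandmarkSet", glabella = c(0, 0, -100),
            anteriorFontanelle = c(0, 0, 100),
            rimLeft = rbind(c(10, 99, 5), c(20, 97, 5)),
            rimRight = rbind(c(-10, 99, 5), c(-20, 97, 5)))
  mask <- segmentMidforehead(sph$mesh, lm, 10)
  fld <- meanCurvature(sph$mesh)
  expect_equal(regionMeanCurvature(fld, mask), sph$h, tolerance = 0.02)
})

test_that("supraorbital band selection is re-checkable and side-symmetric", {
  h <- headFixture(0.5, 0.5)
  rim <- h$landmarks@rimLeft
  mask <- segmentSupraorbital(h$mesh, rim, 10, c(0, 0, 1),
                              "supraorbital_left")
  p <- vertices(h$mesh)[regionVertices(mask), , drop = FALSE]
  pr <- craniocurv:::pointsToPolyline(p, rim)
  expect_true(all(pr$distance <= 10 + 1e-9))
  expect_true(all(pr$param > 0 & pr$param < pr$length))
  # reversed up-hint selects the band below the rim, disjoint from above
  below <- segmentSupraorbital(h$mesh, rim, 10, c(0, 0, -1),
                               "supraorbital_left")
  expect_length(intersect(regionVertices(mask), regionVertices(below)), 0L)
  # bilaterally symmetric head: left and right means within 1 %
  fld <- headField(0.5, 0.5)
  maskR <- segmentSupraorbital(h$mesh, h$landmarks@rimRight, 10, c(0, 0, 1),
                               "supraorbital_right")
  hl <- regionMeanCurvature(fld, mask)
  hr <- regionMeanCurvature(fld, maskR)
  expect_lt(abs(hl - hr), 0.01 * abs((hl + hr) / 2))
})

test_that("a band on a cylinder recovers the cylinder's curvature", {
  cyl <- makeFixture("cylinder", size = 50, resolution = 64)
  # rim: a surface circle segment at z = -20; band extends upward
  ang <- seq(-0.5, 0.5, length.out = 7L)
  rim <- cbind(50 * cos(ang), 50 * sin(ang), -20)
  mask <- segmentSupraorbital(cyl$mesh, rim, 10, c(0, 0, 1),
                              "supraorbital_left")
  fld <- meanCurvature(cyl$mesh)
  expect_equal(regionMeanCurvature(fld, mask), cyl$h, tolerance = 0.03)
})

test_that("masks are deterministic and monotone in width", {
  h <- headFixture(0.5, 0.5)
  m1 <- segmentMidforehead(h$mesh, h$landmarks, 10)
  m2 <- segmentMidforehead(h$mesh, h$landmarks, 10)
  expect_identical(regionVertices(m1), regionVertices(m2))
  expect_identical(regionWeights(m1), regionWeights(m2))
  wide <- segmentMidforehead(h$mesh, h$landmarks, 14)
  expect_true(all(regionVertices(m1) %in% regionVertices(wide)))
  s1 <- segmentSupraorbital(h$mesh, h$landmarks@rimLeft, 10, c(0, 0, 1))
  s2 <- segmentSupraorbital(h$mesh, h$landmarks@rimLeft, 14, c(0, 0, 1))
  expect_true(all(regionVertices(s1) %in% regionVertices(s2)))
})

test_that("region means are exact area-weighted averages", {
  # hand-computable: H = (10, 30) with areas (1, 3) -> 25
  fld <- new("CurvatureField", H = c(10, 30, 99), vertexArea = c(1, 3, 1),
             valid = c(TRUE, TRUE, TRUE), estimator = "cotangent")
  mask <- new("RegionMask", regionName = "midforehead",
              vertexIds = c(1L, 2L), weights = c(1, 3))
  expect_identical(regionMeanCurvature(fld, mask), 25)
  # constant fields are reproduced exactly on any mask
  cf <- new("CurvatureField", H = rep(7.25, 3L), vertexArea = c(2, 5, 1),
            valid = rep(TRUE, 3L), estimator = "cotangent")
  expect_equal(regionMeanCurvature(cf, mask), 7.25, tolerance = 1e-15)
  # all-invalid masked vertices propagate as an error
  bad <- new("CurvatureField", H = c(NA, NA, 1), vertexArea = c(1, 1, 1),
             valid = c(FALSE, FALSE, TRUE), estimator = "cotangent")
  expect_error(regionMeanCurvature(bad, mask), "no valid")
})
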