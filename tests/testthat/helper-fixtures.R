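# Shared fixtures, memoised so expensive meshes are built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

sphereFixture <- function(level = 4L, r = 100) {
  cached(sprintf("sphere_%d_%g", level, r),
         makeFixture("sphere", size = r, resolution = level))
}

headFixture <- function(ridge = 0.5, orb = 0.5) {
  cached(sprintf("head_%g_%g", ridge, orb),
         makeHead(ridgeSharpness = ridge, orbRetrusion = orb))
}

headField <- function(ridge = 0.5, orb = 0.5) {
  cached(sprintf("headfield_%g_%g", ridge, orb),
         meanCurvature(headFixture(ridge, orb)$mesh))
}

# landmark JSON for a mesh, written to a temp file
writeLandmarkJSON <- function(lm, path = tempfile(fileext = ".json")) {
  writeLandmarks(lm, path)
  path
}

# exhaustive minimisation of within-cluster sum of squares over all
# 2-partitions; the exact oracle for kmeans2 at small n
bruteForce2Partition <- function(X) {
  n <- nrow(X)
  best <- Inf
  bestAssign <- NULL
  for (mask in seq_len(2^n - 2L)) {
    a <- as.integer(intToBits(mask))[seq_len(n)]
    if (!any(a == 1L) || !any(a == 0L)) next
    w <- 0
    for (k in 0:1) {
      S <- X[a == k, , drop = FALSE]
      w <- w + sum(scale(S, scale = FALSE)^2)
    }
    if (w < best) {
      best <- w
      bestAssign <- a
    }
  }
  list(inertia = best, assign = bestAssign)
}

# run the three-region segmentation + feature extraction for one generated
# head; the end-to-end path used by monotonicity and symmetry checks
headFeatures <- function(ridge, orb) {
  h <- headFixture(ridge, orb)
  fld <- headField(ridge, orb)
  mid <- segmentMidforehead(h$mesh, h$landmarks, 10)
  sl <- segmentSupraorbital(h$mesh, h$landmarks@rimLeft, 10, c(0, 0, 1),
                            "supraorbital_left")
  sr <- segmentSupraorbital(h$mesh, h$landmarks@rimRight, 10, c(0, 0, 1),
                            "supraorbital_right")
  c(h_mid = regionMeanCurvature(fld, mid),
    h_orb_left = regionMeanCurvature(fld, sl),
    h_orb_right = regionMeanCurvature(fld, sr))
}
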