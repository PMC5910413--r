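#' Analytic-curvature fixture meshes
#'
#' Generates the reference surfaces used to certify the curvature
#' estimators: a subdivided icosphere (H = 1/r everywhere), an open cylinder
#' (H = 1/(2r) away from the rims), a flat triangulated grid (H = 0) and a
#' sphere with an inward Gaussian dent (H < 0 at the dent centre, > 0
#' elsewhere).  All analytic values are returned in 1/m for millimetre
#' meshes, matching [meanCurvature()].
#'
#' @param kind "sphere", "cylinder", "plane" or "dented_sphere".
#' @param size radius in mm (sphere, cylinder, dented_sphere) or half-extent
#'   of the square grid (plane).
#' @param resolution icosphere subdivision level (sphere variants; level 3 =
#'   642 vertices) or grid/angular segment count (cylinder, plane).
#' @param dentDepth,dentWidth dented sphere only: dent depth (mm) and
#'   angular half-width (radians).
#' @return a list with elements `mesh` (a [TriangleMesh-class]), `h` (the
#'   analytic interior mean curvature in 1/m; `NA` for the dented sphere,
#'   whose curvature varies), and for the dented sphere `dentCenter` (unit
#'   direction of the dent axis) and `dentWidth`.
#' @examples
#' cyl <- makeFixture("cylinder", size = 50, resolution = 48)
#' cyl$h  # 10: H = 1/(2r) for r = 0.05 m
#' @export
makeFixture <- function(kind = c("sphere", "cylinder", "plane",
                                 "dented_sphere"),
                        size = 100, resolution = 4,
                        dentDepth = 20, dentWidth = 0.35) {
  kind <- match.arg(kind)
  stopifnot(size > 0)
  switch(kind,
    sphere = {
      mesh <- icosphere(resolution, size)
      list(mesh = mesh, h = 1000 / size)
    },
    cylinder = {
      if (resolution < 8) stop("cylinder needs resolution >= 8 segments")
      mesh <- cylinderMesh(size, height = 4 * size, nTheta = resolution)
      list(mesh = mesh, h = 1000 / (2 * size))
    },
    plane = {
      if (resolution < 2) stop("plane needs resolution >= 2")
      mesh <- planeMesh(size, n = resolution)
      list(mesh = mesh, h = 0)
    },
    dented_sphere = {
      mesh <- icosphere(resolution, size)
      v <- vertices(mesh)
      u <- normalizeRows(v)
      ang <- acos(pmin(pmax(u[, 3L], -1), 1))       # angle from +z pole
      depth <- dentDepth * exp(-(ang / dentWidth)^2 / 2)
      v2 <- v - u * depth
      list(mesh = TriangleMesh(v2, faces(mesh), clean = FALSE),
           h = NA_real_, dentCenter = c(0, 0, 1), dentWidth = dentWidth)
    })
}

# Icosphere: regular icosahedron with `level` rounds of 1-to-4 midpoint
# subdivision, vertices projected to radius r.  level 3 -> 642 vertices /
# 1280 faces.  The vertex set is symmetric under x -> -x, which the head
# generator relies on for bilateral symmetry.
icosphere <- function(level = 3L, r = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- normalizeRows(v)
  for (l in seq_len(level)) {
    sub <- subdivideMidpoint(v, f)
    v <- normalizeRows(sub$vertices)
    f <- sub$faces
  }
  TriangleMesh(v * r, f, clean = TRUE)
}

subdivideMidpoint <- function(v, f) {
  m <- nrow(f)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  uk <- unique(key)
  mid <- match(key, uk)                  # edge -> new-vertex slot
  firsts <- match(uk, key)
  newV <- (v[e[firsts, 1L], , drop = FALSE] +
           v[e[firsts, 2L], , drop = FALSE]) / 2
  off <- nrow(v)
  a <- mid[seq_len(m)] + off             # midpoint of (1,2)
  b <- mid[m + seq_len(m)] + off         # midpoint of (2,3)
  c_ <- mid[2L * m + seq_len(m)] + off   # midpoint of (3,1)
  f2 <- rbind(cbind(f[, 1L], a, c_),
              cbind(a, f[, 2L], b),
              cbind(c_, b, f[, 3L]),
              cbind(a, b, c_))
  list(vertices = rbind(v, newV), faces = f2)
}

# Open cylinder of radius r about the z axis, z in [-height/2, height/2].
cylinderMesh <- function(r, height, nTheta = 48L, nZ = NULL) {
  if (is.null(nZ)) nZ <- max(8L, ceiling(height / (2 * pi * r / nTheta)))
  theta <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  z <- seq(-height / 2, height / 2, length.out = nZ + 1L)
  grid <- expand.grid(t = seq_len(nTheta), k = seq_len(nZ + 1L))
  v <- cbind(r * cos(theta[grid$t]), r * sin(theta[grid$t]), z[grid$k])
  id <- function(t, k) (k - 1L) * nTheta + ((t - 1L) %% nTheta) + 1L
  f <- NULL
  tt <- seq_len(nTheta)
  fl <- vector("list", nZ)
  for (k in seq_len(nZ)) {
    a <- id(tt, k); b <- id(tt + 1L, k)
    c_ <- id(tt + 1L, k + 1L); d <- id(tt, k + 1L)
    fl[[k]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  f <- do.call(rbind, fl)
  TriangleMesh(v, f, clean = TRUE)
}

# Square grid in the z = 0 plane, half-extent `half`, (n+1)^2 vertices.
planeMesh <- function(half, n = 20L) {
  s <- seq(-half, half, length.out = n + 1L)
  grid <- expand.grid(i = seq_len(n + 1L), j = seq_len(n + 1L))
  v <- cbind(s[grid$i], s[grid$j], 0)
  id <- function(i, j) (j - 1L) * (n + 1L) + i
  fl <- vector("list", n)
  ii <- seq_len(n)
  for (j in seq_len(n)) {
    a <- id(ii, j); b <- id(ii + 1L, j)
    c_ <- id(ii + 1L, j + 1L); d <- id(ii, j + 1L)
    fl[[j]] <- rbind(cbind(a, b, c_), cbind(a, c_, d))
  }
  TriangleMesh(v, do.call(rbind, fl), clean = TRUE)
}
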