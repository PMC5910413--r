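# Row-wise vector helpers shared by the mesh, curvature and region code.
# All operate on n x 3 matrices without copying into lists.

rowCross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

rowDot <- function(a, b) rowSums(a * b)

rowNorm <- function(a) sqrt(rowSums(a * a))

normalizeRows <- function(a) {
  len <- rowNorm(a)
  len[len == 0] <- 1
  a / len
}

# Closest point on each triangle (rows of p1/p2/p3) to a single query point.
# Ericson's region-based algorithm, vectorised over triangles.  Returns the
# closest-point matrix; used for landmark snapping.
closestPointOnTriangles <- function(q, p1, p2, p3) {
  m <- nrow(p1)
  qm <- matrix(q, m, 3L, byrow = TRUE)
  ab <- p2 - p1; ac <- p3 - p1; ap <- qm - p1
  d1 <- rowDot(ab, ap); d2 <- rowDot(ac, ap)
  bp <- qm - p2
  d3 <- rowDot(ab, bp); d4 <- rowDot(ac, bp)
  cp <- qm - p3
  d5 <- rowDot(ab, cp); d6 <- rowDot(ac, cp)

  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  out <- matrix(NA_real_, m, 3L)
  done <- rep(FALSE, m)

  setPts <- function(idx, pts) {
    out[idx, ] <<- pts
    done[idx] <<- TRUE
  }

  idx <- !done & d1 <= 0 & d2 <= 0                      # vertex A
  if (any(idx)) setPts(idx, p1[idx, , drop = FALSE])
  idx <- !done & d3 >= 0 & d4 <= d3                     # vertex B
  if (any(idx)) setPts(idx, p2[idx, , drop = FALSE])
  idx <- !done & d6 >= 0 & d5 <= d6                     # vertex C
  if (any(idx)) setPts(idx, p3[idx, , drop = FALSE])
  idx <- !done & vc <= 0 & d1 >= 0 & d3 <= 0            # edge AB
  if (any(idx)) {
    t <- d1[idx] / (d1[idx] - d3[idx])
    setPts(idx, p1[idx, , drop = FALSE] + t * ab[idx, , drop = FALSE])
  }
  idx <- !done & vb <= 0 & d2 >= 0 & d6 <= 0            # edge AC
  if (any(idx)) {
    t <- d2[idx] / (d2[idx] - d6[idx])
    setPts(idx, p1[idx, , drop = FALSE] + t * ac[idx, , drop = FALSE])
  }
  idx <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge BC
  if (any(idx)) {
    t <- (d4[idx] - d3[idx]) / ((d4[idx] - d3[idx]) + (d5[idx] - d6[idx]))
    setPts(idx, p2[idx, , drop = FALSE] +
             t * (p3[idx, , drop = FALSE] - p2[idx, , drop = FALSE]))
  }
  idx <- !done                                           # interior
  if (any(idx)) {
    denom <- va[idx] + vb[idx] + vc[idx]
    v <- vb[idx] / denom; w <- vc[idx] / denom
    setPts(idx, p1[idx, , drop = FALSE] + v * ab[idx, , drop = FALSE] +
             w * ac[idx, , drop = FALSE])
  }
  out
}

# Nearest point on the mesh surface to a query point; brute force over faces.
projectPointToMesh <- function(mesh, q) {
  f <- mesh@faces
  cand <- closestPointOnTriangles(q,
    mesh@vertices[f[, 1L], , drop = FALSE],
    mesh@vertices[f[, 2L], , drop = FALSE],
    mesh@vertices[f[, 3L], , drop = FALSE])
  d2 <- rowSums((cand - matrix(q, nrow(cand), 3L, byrow = TRUE))^2)
  i <- which.min(d2)
  list(point = cand[i, ], distance = sqrt(d2[i]))
}

# Distance from points to a polyline, with closest points and the arc-length
# parameter of the projection.  `pts` n x 3, `poly` k x 3 (k >= 2).
pointsToPolyline <- function(pts, poly) {
  n <- nrow(pts); k <- nrow(poly)
  segLen <- rowNorm(poly[-1L, , drop = FALSE] - poly[-k, , drop = FALSE])
  cum0 <- c(0, cumsum(segLen))
  best <- rep(Inf, n)
  bestPt <- matrix(NA_real_, n, 3L)
  bestS <- rep(NA_real_, n)
  for (s in seq_len(k - 1L)) {
    a <- poly[s, ]; b <- poly[s + 1L, ]
    ab <- b - a
    ab2 <- sum(ab * ab)
    if (ab2 == 0) next
    t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L] +
          (pts[, 3L] - a[3L]) * ab[3L]) / ab2
    t <- pmin(pmax(t, 0), 1)
    proj <- cbind(a[1L] + t * ab[1L], a[2L] + t * ab[2L], a[3L] + t * ab[3L])
    d <- sqrt(rowSums((pts - proj)^2))
    upd <- d < best
    if (any(upd)) {
      best[upd] <- d[upd]
      bestPt[upd, ] <- proj[upd, , drop = FALSE]
      bestS[upd] <- cum0[s] + t[upd] * segLen[s]
    }
  }
  list(distance = best, point = bestPt, param = bestS,
       length = cum0[k])
}
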