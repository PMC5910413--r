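#' Construct a TriangleMesh
#'
#' Builds a [TriangleMesh-class] from raw vertex and face arrays, computing
#' face normals.  Use `clean = TRUE` (the default) to merge duplicate
#' vertices, drop degenerate faces and repair orientation; raw construction
#' is only appropriate for meshes already known to be clean and consistently
#' oriented.
#'
#' @param vertices numeric n x 3 matrix of coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param clean logical; run [cleanMesh()] on the result.
#' @return a [TriangleMesh-class].
#' @examples
#' octa <- TriangleMesh(
#'   rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)),
#'   rbind(c(1,3,5), c(3,2,5), c(2,4,5), c(4,1,5),
#'         c(3,1,6), c(2,3,6), c(4,2,6), c(1,4,6)))
#' nVertices(octa)
#' @export
TriangleMesh <- function(vertices, faces, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  mesh <- new("TriangleMesh", vertices = vertices, faces = faces,
              faceNormals = computeFaceNormals(vertices, faces))
  if (clean) cleanMesh(mesh) else mesh
}

computeFaceNormals <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(matrix(numeric(), 0L, 3L))
  p1 <- vertices[faces[, 1L], , drop = FALSE]
  p2 <- vertices[faces[, 2L], , drop = FALSE]
  p3 <- vertices[faces[, 3L], , drop = FALSE]
  normalizeRows(rowCross(p2 - p1, p3 - p1))
}

#' @rdname TriangleMesh
#' @param object,mesh a [TriangleMesh-class].
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' @rdname TriangleMesh
#' @export
nFaces <- function(mesh) nrow(mesh@faces)

#' @rdname TriangleMesh
#' @export
vertices <- function(mesh) mesh@vertices

#' @rdname TriangleMesh
#' @export
faces <- function(mesh) mesh@faces

#' @rdname TriangleMesh
#' @export
faceNormals <- function(mesh) mesh@faceNormals

faceAreas <- function(mesh) {
  p1 <- mesh@vertices[mesh@faces[, 1L], , drop = FALSE]
  p2 <- mesh@vertices[mesh@faces[, 2L], , drop = FALSE]
  p3 <- mesh@vertices[mesh@faces[, 3L], , drop = FALSE]
  0.5 * rowNorm(rowCross(p2 - p1, p3 - p1))
}

#' @rdname TriangleMesh
#' @export
surfaceArea <- function(mesh) sum(faceAreas(mesh))

#' @rdname TriangleMesh
#' @export
meshCentroid <- function(mesh) colMeans(mesh@vertices)

# Undirected edge table: one row per undirected edge with the number of
# incident faces; boundary edges have count 1.
edgeTable <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  cnt <- table(key)
  first <- !duplicated(key)
  data.frame(v1 = pmin(e[first, 1L], e[first, 2L]),
             v2 = pmax(e[first, 1L], e[first, 2L]),
             count = as.integer(cnt[key[first]]))
}

#' @rdname TriangleMesh
#' @export
isClosed <- function(mesh) all(edgeTable(mesh@faces)$count == 2L)

#' @rdname TriangleMesh
#' @export
boundaryVertices <- function(mesh) {
  et <- edgeTable(mesh@faces)
  b <- et$count == 1L
  sort(unique(c(et$v1[b], et$v2[b])))
}

# Signed volume of a closed oriented surface (divergence theorem); positive
# when the orientation is outward.
signedVolume <- function(mesh) {
  p1 <- mesh@vertices[mesh@faces[, 1L], , drop = FALSE]
  p2 <- mesh@vertices[mesh@faces[, 2L], , drop = FALSE]
  p3 <- mesh@vertices[mesh@faces[, 3L], , drop = FALSE]
  sum(rowDot(p1, rowCross(p2, p3))) / 6
}

#' Clean and orient a triangle mesh
#'
#' Merges vertices closer than `tol` (default 1e-6 mm, far below scanner
#' precision; this removes STL triangle-soup duplication only), drops
#' zero-area and repeated-index faces, removes unreferenced vertices, makes
#' the face winding consistent across each connected component by
#' breadth-first propagation, and finally orients the whole mesh outward:
#' by the sign of the enclosed volume when the mesh is closed, otherwise by
#' majority vote of face normals against the direction from the mesh
#' centroid.  Idempotent.
#'
#' @param mesh a [TriangleMesh-class].
#' @param tol vertex-merge tolerance in mm.
#' @return the cleaned, consistently outward-oriented mesh.
#' @export
cleanMesh <- function(mesh, tol = 1e-6) {
  v <- mesh@vertices
  f <- mesh@faces

  # merge duplicate vertices on a tol grid
  key <- paste(round(v[, 1L] / tol), round(v[, 2L] / tol), round(v[, 3L] / tol))
  uid <- match(key, key)
  keep <- sort(unique(uid))
  remap <- integer(nrow(v))
  remap[keep] <- seq_along(keep)
  v <- v[keep, , drop = FALSE]
  f <- matrix(remap[uid[f]], ncol = 3L)

  # drop degenerate faces
  ok <- f[, 1L] != f[, 2L] & f[, 2L] != f[, 3L] & f[, 1L] != f[, 3L]
  f <- f[ok, , drop = FALSE]
  if (nrow(f) > 0L) {
    p1 <- v[f[, 1L], , drop = FALSE]
    p2 <- v[f[, 2L], , drop = FALSE]
    p3 <- v[f[, 3L], , drop = FALSE]
    area2 <- rowNorm(rowCross(p2 - p1, p3 - p1))
    f <- f[area2 > .Machine$double.eps * 100, , drop = FALSE]
  }

  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  remap2 <- integer(nrow(v))
  remap2[used] <- seq_along(used)
  v <- v[used, , drop = FALSE]
  f <- matrix(remap2[f], ncol = 3L)

  if (nrow(v) < 4L)
    stop("degenerate input: fewer than 4 vertices after cleaning")

  f <- orientFacesConsistently(f)

  mesh2 <- new("TriangleMesh", vertices = v, faces = f,
               faceNormals = computeFaceNormals(v, f))
  orientOutward(mesh2)
}

# Propagate a consistent winding over each connected component: two faces
# sharing an edge are consistent when they traverse it in opposite directions.
orientFacesConsistently <- function(f) {
  m <- nrow(f)
  if (m == 0L) return(f)
  he <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  heFace <- rep.int(seq_len(m), 3L)
  key <- paste(pmin(he[, 1L], he[, 2L]), pmax(he[, 1L], he[, 2L]))
  byEdge <- split(seq_len(3L * m), key)

  # adjacency: for each face, (neighbour face, same-direction flag)
  adj <- vector("list", m)
  for (ids in byEdge) {
    if (length(ids) != 2L) next  # boundary or non-manifold: skip
    f1 <- heFace[ids[1L]]; f2 <- heFace[ids[2L]]
    same <- he[ids[1L], 1L] == he[ids[2L], 1L]  # same direction => inconsistent
    adj[[f1]] <- c(adj[[f1]], f2, same)
    adj[[f2]] <- c(adj[[f2]], f1, same)
  }

  flip <- rep(NA, m)
  for (root in seq_len(m)) {
    if (!is.na(flip[root])) next
    flip[root] <- FALSE
    queue <- root
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      a <- adj[[cur]]
      if (is.null(a)) next
      nb <- a[seq(1L, length(a), by = 2L)]
      same <- as.logical(a[seq(2L, length(a), by = 2L)])
      want <- xor(flip[cur], same)
      newIdx <- is.na(flip[nb])
      if (any(newIdx)) {
        flip[nb[newIdx]] <- want[newIdx]
        queue <- c(queue, nb[newIdx])
      }
    }
  }
  doFlip <- which(flip)
  if (length(doFlip)) f[doFlip, ] <- f[doFlip, c(1L, 3L, 2L), drop = FALSE]
  f
}

# Global outward orientation: signed volume for closed meshes, centroid
# majority vote for open ones.
orientOutward <- function(mesh) {
  outward <- if (isClosed(mesh)) {
    signedVolume(mesh) > 0
  } else {
    ctr <- meshCentroid(mesh)
    fc <- (mesh@vertices[mesh@faces[, 1L], , drop = FALSE] +
           mesh@vertices[mesh@faces[, 2L], , drop = FALSE] +
           mesh@vertices[mesh@faces[, 3L], , drop = FALSE]) / 3
    off <- fc - matrix(ctr, nrow(fc), 3L, byrow = TRUE)
    # flat meshes (all offsets in-plane) have no defined outward side;
    # the >= keeps orientation repair idempotent there
    mean(sign(rowDot(mesh@faceNormals, off))) >= 0
  }
  if (!outward) {
    f <- mesh@faces[, c(1L, 3L, 2L), drop = FALSE]
    mesh <- new("TriangleMesh", vertices = mesh@vertices, faces = f,
                faceNormals = computeFaceNormals(mesh@vertices, f))
  }
  mesh
}

#' Per-vertex normals
#'
#' Area-weighted average of incident face normals, normalised to unit length.
#'
#' @param mesh a [TriangleMesh-class].
#' @return numeric n x 3 matrix of unit vertex normals.
#' @export
vertexNormals <- function(mesh) {
  fa <- faceAreas(mesh)
  wfn <- mesh@faceNormals * fa
  idx <- as.vector(mesh@faces)
  contrib <- rbind(wfn, wfn, wfn)
  g <- factor(idx, levels = seq_len(nVertices(mesh)))
  acc <- rowsum(contrib, g)
  normalizeRows(acc)
}

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nVertices(object), nFaces(object)))
  cat(sprintf("  surface area: %.1f mm^2; %s\n", surfaceArea(object),
              if (isClosed(object)) sprintf("closed, volume %.1f mm^3",
                                            signedVolume(object))
              else "open (has boundary)"))
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet\n")
  cat(sprintf("  glabella:            (%.1f, %.1f, %.1f) mm\n",
              object@glabella[1L], object@glabella[2L], object@glabella[3L]))
  cat(sprintf("  anterior fontanelle: (%.1f, %.1f, %.1f) mm\n",
              object@anteriorFontanelle[1L], object@anteriorFontanelle[2L],
              object@anteriorFontanelle[3L]))
  cat(sprintf("  rim polylines: left %d pts, right %d pts\n",
              nrow(object@rimLeft), nrow(object@rimRight)))
})

setMethod("show", "CurvatureField", function(object) {
  h <- object@H[object@valid]
  cat(sprintf("CurvatureField (%s): %d vertices, %d valid\n",
              object@estimator, length(object@H), sum(object@valid)))
  if (length(h))
    cat(sprintf("  H [1/m]: median %.2f, IQR [%.2f, %.2f]\n",
                stats::median(h), stats::quantile(h, 0.25),
                stats::quantile(h, 0.75)))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask '%s': %d vertices, total area %.1f mm^2\n",
              object@regionName, length(object@vertexIds),
              sum(object@weights)))
})
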