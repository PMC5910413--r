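#' Read an STL surface mesh
#'
#' Reads binary or ASCII STL (auto-detected), then cleans the triangle soup:
#' corner coordinates duplicated across facets are merged within 1e-6 mm,
#' degenerate facets are dropped, and the winding is repaired to a consistent
#' outward orientation.  STL files carry no units; coordinates are assumed to
#' be millimetres, the convention of CT bone reconstructions and
#' stereophotogrammetry exports.
#'
#' @param path path to an `.stl` file.
#' @param verbose log vertex/face counts to `message()`.
#' @return a cleaned [TriangleMesh-class].
#' @seealso [writeSTL()], [cleanMesh()]
#' @export
readSTL <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  tri <- if (isBinarySTL(path)) readSTLBinary(path) else readSTLAscii(path)
  if (nrow(tri) == 0L) stop("not a readable STL file (no facets): ", path)
  nTri <- nrow(tri) / 3L
  v <- tri
  f <- matrix(seq_len(nrow(tri)), ncol = 3L, byrow = TRUE)
  mesh <- tryCatch(
    cleanMesh(new("TriangleMesh", vertices = v, faces = f,
                  faceNormals = computeFaceNormals(v, f))),
    error = function(e) stop("degenerate STL mesh '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (verbose)
    message(sprintf("read %s: %d facets -> %d vertices, %d faces",
                    basename(path), nTri, nVertices(mesh), nFaces(mesh)))
  mesh
}

# A file is binary STL when the facet count in the 84-byte header matches the
# file size, or when it does not start with a plausible ASCII "solid" body.
isBinarySTL <- function(path) {
  sz <- file.size(path)
  if (sz < 84) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (!is.na(n) && n >= 0 && sz == 84 + 50 * as.numeric(n)) return(TRUE)
  txt <- rawToChar(header[header != as.raw(0L)])
  !grepl("^\\s*solid", txt)
}

readSTLBinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (is.na(n) || n <= 0) stop("unreadable binary STL: ", path)
  rec <- readBin(con, "raw", n * 50L)
  if (length(rec) < n * 50L) stop("truncated binary STL: ", path)
  rec <- matrix(rec, nrow = 50L)
  # bytes 13..48 of each record are the 9 vertex floats
  vraw <- as.raw(rec[13:48, ])
  vals <- readBin(vraw, "numeric", n * 9L, size = 4L, endian = "little")
  coords <- matrix(vals, ncol = 3L, byrow = TRUE)  # 3n rows
  coords
}

readSTLAscii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("unreadable ASCII STL: ", path)
  toks <- strsplit(trimws(vl), "\\s+")
  coords <- t(vapply(toks, function(x) as.numeric(x[2:4]), numeric(3L)))
  if (any(!is.finite(coords))) stop("non-numeric vertex in ASCII STL: ", path)
  coords
}

#' Write a binary STL file
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSTL <- function(mesh, path) {
  f <- mesh@faces
  v <- mesh@vertices
  n <- nrow(f)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  fn <- mesh@faceNormals
  tri <- cbind(fn,
               v[f[, 1L], , drop = FALSE],
               v[f[, 2L], , drop = FALSE],
               v[f[, 3L], , drop = FALSE])
  for (i in seq_len(n)) {
    writeBin(as.numeric(tri[i, ]), con, size = 4L, endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}

#' Export a mesh with a per-vertex scalar as ASCII PLY
#'
#' Writes the mesh with the scalar both as a `quality` vertex property and as
#' a blue-white-red colour map (negative-zero-positive), for visual QC of
#' curvature fields in any PLY viewer.
#'
#' @param mesh a [TriangleMesh-class].
#' @param scalar numeric per-vertex values (e.g. `curvatures(field)`); NA
#'   rendered grey.
#' @param path output `.ply` path.
#' @param limit colour saturation at `+/- limit`; default the 98th percentile
#'   of `|scalar|`.
#' @return `path`, invisibly.
#' @export
writePLY <- function(mesh, scalar, path, limit = NULL) {
  n <- nVertices(mesh)
  stopifnot(length(scalar) == n)
  if (is.null(limit))
    limit <- stats::quantile(abs(scalar), 0.98, na.rm = TRUE)
  if (!is.finite(limit) || limit == 0) limit <- 1
  t <- pmin(pmax(scalar / limit, -1), 1)
  r <- ifelse(t >= 0, 255, round(255 * (1 + t)))
  b <- ifelse(t <= 0, 255, round(255 * (1 - t)))
  g <- round(255 * (1 - abs(t)))
  r[is.na(t)] <- 128; g[is.na(t)] <- 128; b[is.na(t)] <- 128
  q <- ifelse(is.na(scalar), 0, scalar)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "property float quality",
               sprintf("element face %d", nFaces(mesh)),
               "property list uchar int vertex_indices", "end_header"), con)
  v <- mesh@vertices
  writeLines(sprintf("%.6f %.6f %.6f %d %d %d %.6f",
                     v[, 1L], v[, 2L], v[, 3L], r, g, b, q), con)
  f <- mesh@faces - 1L
  writeLines(sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' Read subject landmarks and snap them to the mesh surface
#'
#' Accepts JSON (`{"glabella": [x,y,z], "anterior_fontanelle": [x,y,z],
#' "rim_left": [[...], ...], "rim_right": [[...], ...]}`) or long-format CSV
#' with columns `landmark, ordinal, x, y, z` (a `subject_id` column is
#' allowed and ignored).  Every point is snapped to its exact nearest point
#' on the mesh surface (point-to-triangle projection, not nearest vertex);
#' the original snap distances are recorded on the returned object.  A point
#' more than `maxSnap` mm from the surface aborts with an error naming the
#' landmark, which catches coordinate-frame mismatches.
#'
#' @param path JSON or CSV landmark file.
#' @param mesh the subject's [TriangleMesh-class].
#' @param maxSnap maximum tolerated point-to-surface distance (mm).
#' @return a [LandmarkSet-class] with `snapDistances` filled in.
#' @export
readLandmarks <- function(path, mesh, maxSnap = 10) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    parseLandmarkJSON(path)
  } else {
    parseLandmarkCSV(path)
  }
  required <- c("glabella", "anterior_fontanelle", "rim_left", "rim_right")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("landmark file ", path, " is missing required landmark(s): ",
         paste(missing, collapse = ", "))
  snapAll <- function(pts, label) {
    pts <- matrix(pts, ncol = 3L)
    out <- matrix(NA_real_, nrow(pts), 3L)
    d <- numeric(nrow(pts))
    for (i in seq_len(nrow(pts))) {
      pr <- projectPointToMesh(mesh, pts[i, ])
      if (pr$distance > maxSnap)
        stop(sprintf(
          "landmark '%s' (point %d) is %.1f mm from the mesh surface (limit %g mm)",
          label, i, pr$distance, maxSnap))
      out[i, ] <- pr$point
      d[i] <- pr$distance
    }
    list(points = out, dist = d)
  }
  g <- snapAll(raw$glabella, "glabella")
  af <- snapAll(raw$anterior_fontanelle, "anterior_fontanelle")
  rl <- snapAll(raw$rim_left, "rim_left")
  rr <- snapAll(raw$rim_right, "rim_right")
  dists <- c(glabella = g$dist, anterior_fontanelle = af$dist,
             rim_left = rl$dist, rim_right = rr$dist)
  new("LandmarkSet", glabella = as.numeric(g$points[1L, ]),
      anteriorFontanelle = as.numeric(af$points[1L, ]),
      rimLeft = rl$points, rimRight = rr$points,
      snapDistances = dists)
}

parseLandmarkJSON <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  lapply(x, function(p) {
    p <- if (is.matrix(p)) p else matrix(as.numeric(p), ncol = 3L, byrow = TRUE)
    storage.mode(p) <- "double"
    p
  })
}

parseLandmarkCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("landmark", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns landmark,[ordinal,]x,y,z: ", path)
  if (!"ordinal" %in% names(d)) d$ordinal <- seq_len(nrow(d))
  out <- lapply(split(d, d$landmark), function(g) {
    g <- g[order(g$ordinal), ]
    as.matrix(g[, c("x", "y", "z")])
  })
  lapply(out, function(m) { dimnames(m) <- NULL; m })
}

#' Write landmarks as JSON
#'
#' @param lm a [LandmarkSet-class].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(lm, path) {
  jsonlite::write_json(list(
    glabella = lm@glabella,
    anterior_fontanelle = lm@anteriorFontanelle,
    rim_left = lm@rimLeft,
    rim_right = lm@rimRight
  ), path, digits = NA)
  invisible(path)
}

#' Read the clinician label table
#'
#' CSV with columns `subject_id` and `clinician_label`; labels must be
#' "conservative" or "operative" and subject ids unique.
#'
#' @param path CSV path.
#' @return data.frame with character columns `subject_id`, `clinician_label`.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "clinician_label") %in% names(d)))
    stop("label CSV must have columns subject_id,clinician_label: ", path)
  d$subject_id <- as.character(d$subject_id)
  if (anyDuplicated(d$subject_id))
    stop("duplicate subject_id in label table: ",
         paste(unique(d$subject_id[duplicated(d$subject_id)]), collapse = ", "))
  bad <- setdiff(unique(d$clinician_label), c("conservative", "operative"))
  if (length(bad))
    stop("clinician_label must be 'conservative' or 'operative'; found: ",
         paste(bad, collapse = ", "))
  d[, c("subject_id", "clinician_label")]
}

#' Export a curvature field as CSV
#'
#' One row per vertex: `vertex_id,H_m_inv,area_mm2,valid`.
#'
#' @param field a [CurvatureField-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCurvatureCSV <- function(field, path) {
  utils::write.csv(data.frame(
    vertex_id = seq_along(field@H),
    H_m_inv = field@H,
    area_mm2 = field@vertexArea,
    valid = field@valid
  ), path, row.names = FALSE)
  invisible(path)
}
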