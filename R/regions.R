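#' Segment the mid-forehead vertical strip
#'
#' The strip runs over the metopic suture line from the glabella to the
#' anterior fontanelle.  On the mesh it is realised as a slab: vertices
#' within `width/2` of the midline plane (the plane through glabella,
#' anterior fontanelle and the mesh centroid) whose scalar projection onto
#' the glabella-to-fontanelle axis lies within the axis extent, and which
#' face the strip (on the glabella/fontanelle side of the head, not the
#' antipodal back wall crossed by the same slab).  The default 10 mm is the
#' conventional full strip width.  Weights are mixed-Voronoi vertex areas,
#' so region means are tessellation-independent.
#'
#' @param mesh a cleaned [TriangleMesh-class].
#' @param lm a [LandmarkSet-class] with surface-snapped landmarks.
#' @param width full strip width in mm (> 0).
#' @return a [RegionMask-class] named "midforehead".
#' @export
segmentMidforehead <- function(mesh, lm, width = 10) {
  if (width <= 0)
    stop("mid-forehead segmentation failed: width must be > 0 (got ",
         width, ")")
  g <- lm@glabella
  af <- lm@anteriorFontanelle
  ctr <- meshCentroid(mesh)
  axis <- af - g
  axisLen <- sqrt(sum(axis^2))
  # midline plane through g, af and the centroid
  nrm <- c((af - g)[2L] * (ctr - g)[3L] - (af - g)[3L] * (ctr - g)[2L],
           (af - g)[3L] * (ctr - g)[1L] - (af - g)[1L] * (ctr - g)[3L],
           (af - g)[1L] * (ctr - g)[2L] - (af - g)[2L] * (ctr - g)[1L])
  nlen <- sqrt(sum(nrm^2))
  if (nlen < 1e-6 * axisLen^2) {
    # centroid collinear with the landmark axis (e.g. antipodal landmarks on
    # a sphere): any plane containing the axis is a valid midline plane
    ref <- if (abs(axis[1L]) < 0.9 * axisLen) c(1, 0, 0) else c(0, 1, 0)
    nrm <- c(axis[2L] * ref[3L] - axis[3L] * ref[2L],
             axis[3L] * ref[1L] - axis[1L] * ref[3L],
             axis[1L] * ref[2L] - axis[2L] * ref[1L])
    nlen <- sqrt(sum(nrm^2))
  }
  nrm <- nrm / nlen
  v <- mesh@vertices
  rel <- v - matrix(g, nrow(v), 3L, byrow = TRUE)
  planeDist <- abs(rel %*% nrm)
  t <- (rel %*% axis) / axisLen
  # half-space test: keep the strip on the landmark side of the head
  mid <- (g + af) / 2
  side <- if (sqrt(sum((mid - ctr)^2)) < 1e-6 * axisLen) {
    rep(1, nrow(v))  # landmarks antipodal about the centroid: no back wall
  } else {
    rowDot(v - matrix(ctr, nrow(v), 3L, byrow = TRUE),
           matrix(mid - ctr, nrow(v), 3L, byrow = TRUE))
  }
  sel <- which(planeDist <= width / 2 & t >= 0 & t <= axisLen & side > 0)
  if (length(sel) == 0L)
    stop(sprintf(paste0(
      "mid-forehead segmentation selected no vertices (width %g mm, ",
      "glabella-fontanelle axis %.1f mm)"), width, axisLen))
  A <- mixedVoronoiAreas(mesh)
  new("RegionMask", regionName = "midforehead",
      vertexIds = as.integer(sel), weights = A[sel])
}

#' Segment a supraorbital band above the orbital rim
#'
#' Selects vertices within `width` mm of the rim polyline whose displacement
#' from the nearest rim point has a positive component along `upHint`
#' ("above" the rim), and whose projection parameter lies within the
#' polyline's arc length (the band does not run past the rim ends).
#'
#' @param mesh a cleaned [TriangleMesh-class].
#' @param rim k x 3 polyline on the surface (k >= 2), e.g. `rimLeft(lm)`.
#' @param width band depth above the rim in mm (> 0; default 10).
#' @param upHint length-3 direction towards the top of the head.
#' @param regionName mask label, "supraorbital_left" or "supraorbital_right".
#' @return a [RegionMask-class].
#' @export
segmentSupraorbital <- function(mesh, rim, width = 10,
                                upHint = c(0, 0, 1),
                                regionName = "supraorbital_left") {
  if (width <= 0)
    stop("supraorbital segmentation failed: width must be > 0")
  rim <- matrix(rim, ncol = 3L)
  if (nrow(rim) < 2L)
    stop("supraorbital segmentation needs a rim polyline of >= 2 points")
  upHint <- upHint / sqrt(sum(upHint^2))
  v <- mesh@vertices
  pp <- pointsToPolyline(v, rim)
  disp <- v - pp$point
  above <- rowDot(disp, matrix(upHint, nrow(v), 3L, byrow = TRUE)) > 0
  inSpan <- pp$param > 1e-9 & pp$param < pp$length - 1e-9
  sel <- which(pp$distance <= width & above & inSpan)
  if (length(sel) == 0L)
    stop(sprintf(paste0(
      "supraorbital segmentation selected no vertices (width %g mm, rim ",
      "length %.1f mm)"), width, pp$length))
  A <- mixedVoronoiAreas(mesh)
  new("RegionMask", regionName = regionName,
      vertexIds = as.integer(sel), weights = A[sel])
}

#' Area-weighted region mean curvature
#'
#' \eqn{\bar H = \sum_i w_i H_i / \sum_i w_i} over the valid masked
#' vertices, with mixed-Voronoi areas as weights.
#'
#' @param field a [CurvatureField-class].
#' @param mask a [RegionMask-class] on the same mesh.
#' @return the region mean curvature in 1/m.
#' @export
regionMeanCurvature <- function(field, mask) {
  ids <- mask@vertexIds
  ok <- field@valid[ids]
  if (!any(ok))
    stop("region '", mask@regionName,
         "' contains no valid curvature vertices")
  w <- mask@weights[ok]
  h <- field@H[ids[ok]]
  sum(w * h) / sum(w)
}

#' @rdname RegionMask-class
#' @param mask a [RegionMask-class].
#' @export
regionVertices <- function(mask) mask@vertexIds

#' @rdname RegionMask-class
#' @export
regionWeights <- function(mask) mask@weights

#' Export region masks as CSV
#'
#' Long format `subject_id,region,vertex_id,weight`, one row per masked
#' vertex across the supplied masks.
#'
#' @param masks list of [RegionMask-class].
#' @param subjectId subject identifier for the output rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRegionCSV <- function(masks, subjectId, path) {
  rows <- do.call(rbind, lapply(masks, function(m) data.frame(
    subject_id = subjectId, region = m@regionName,
    vertex_id = m@vertexIds, weight = m@weights)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
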