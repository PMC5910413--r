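#' @import methods
NULL

#' Indexed triangle surface mesh
#'
#' Container for an oriented triangle mesh in millimetre coordinates: an
#' `n x 3` vertex matrix, an `m x 3` integer face matrix (1-based, counter-
#' clockwise when seen from outside), and derived unit face normals.
#' Meshes produced by [readSTL()] or [cleanMesh()] are cleaned (duplicate
#' vertices merged, degenerate faces dropped) and consistently oriented with
#' normals pointing away from the surface interior.
#'
#' @slot vertices numeric matrix, one row per vertex (x, y, z in mm).
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot faceNormals numeric matrix of unit outward face normals.
#'
#' @seealso [TriangleMesh()], [readSTL()], [meanCurvature()]
#' @export
setClass("TriangleMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    faceNormals = "matrix"
  )
)

setValidity("TriangleMesh", function(object) {
  v <- object@vertices; f <- object@faces; fn <- object@faceNormals
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 3L)
    msg <- c(msg, "'vertices' must be a numeric n x 3 matrix")
  if (!is.numeric(f) || ncol(f) != 3L)
    msg <- c(msg, "'faces' must be an integer m x 3 matrix")
  else {
    if (nrow(f) > 0L && (min(f) < 1L || max(f) > nrow(v)))
      msg <- c(msg, "face indices out of range [1, nVertices]")
    if (nrow(f) > 0L &&
        any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
      msg <- c(msg, "degenerate faces (repeated vertex index) present")
  }
  if (nrow(fn) != nrow(f) || ncol(fn) != 3L)
    msg <- c(msg, "'faceNormals' must match 'faces' row for row")
  if (length(msg)) msg else TRUE
})

#' Anatomical landmark set
#'
#' The four landmarks anchoring region segmentation: the glabella (midline
#' prominence between the eyebrows), the anterior fontanelle, and the left and
#' right superior orbital rim polylines (each at least two points, ordered
#' lateral to medial or vice versa).  All coordinates are in the same
#' millimetre frame as the mesh; [readLandmarks()] snaps each point onto the
#' mesh surface and refuses points more than 10 mm away.
#'
#' @slot glabella numeric length-3 point (mm).
#' @slot anteriorFontanelle numeric length-3 point (mm).
#' @slot rimLeft,rimRight numeric k x 3 polyline matrices (k >= 2).
#' @slot snapDistances numeric vector of original point-to-surface distances
#'   recorded at load time (mm); empty if the set was built directly.
#' @export
setClass("LandmarkSet",
  representation(
    glabella = "numeric",
    anteriorFontanelle = "numeric",
    rimLeft = "matrix",
    rimRight = "matrix",
    snapDistances = "numeric"
  ),
  prototype(snapDistances = numeric())
)

setValidity("LandmarkSet", function(object) {
  msg <- character()
  if (length(object@glabella) != 3L || length(object@anteriorFontanelle) != 3L)
    msg <- c(msg, "glabella and anteriorFontanelle must be length-3 points")
  if (ncol(object@rimLeft) != 3L || nrow(object@rimLeft) < 2L)
    msg <- c(msg, "rimLeft must be a k x 3 matrix with k >= 2")
  if (ncol(object@rimRight) != 3L || nrow(object@rimRight) < 2L)
    msg <- c(msg, "rimRight must be a k x 3 matrix with k >= 2")
  if (length(object@glabella) == 3L &&
      isTRUE(all.equal(object@glabella, object@anteriorFontanelle)))
    msg <- c(msg, "glabella and anteriorFontanelle coincide")
  if (length(msg)) msg else TRUE
})

#' Per-vertex signed mean curvature field
#'
#' Signed mean curvature H (in 1/m) at every mesh vertex together with the
#' mixed-Voronoi vertex area (mm^2) used as the averaging weight, and a
#' validity flag which is FALSE on boundary vertices (incomplete one-rings)
#' and on vertices whose mixed area degenerated to zero.  The sign convention
#' is convex-positive with respect to the outward normal: a ridge carries
#' H > 0, a retruded (scooped) area H < 0.
#'
#' @slot H numeric per-vertex mean curvature (1/m); NA on invalid vertices.
#' @slot vertexArea numeric per-vertex mixed-Voronoi area (mm^2).
#' @slot valid logical per-vertex flag.
#' @slot estimator character, "cotangent" or "quadric".
#' @export
setClass("CurvatureField",
  representation(
    H = "numeric",
    vertexArea = "numeric",
    valid = "logical",
    estimator = "character"
  )
)

setValidity("CurvatureField", function(object) {
  msg <- character()
  n <- length(object@H)
  if (length(object@vertexArea) != n || length(object@valid) != n)
    msg <- c(msg, "H, vertexArea and valid must have equal length")
  if (any(!is.finite(object@H[object@valid])))
    msg <- c(msg, "H must be finite on all valid vertices")
  if (any(object@vertexArea < 0))
    msg <- c(msg, "vertex areas must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Anatomical region mask
#'
#' A subset of mesh vertices realising one of the three regions of interest
#' (mid-forehead strip, left/right supraorbital band), with per-vertex
#' mixed-Voronoi areas as averaging weights.
#'
#' @slot regionName one of "midforehead", "supraorbital_left",
#'   "supraorbital_right".
#' @slot vertexIds integer vertex indices into the mesh.
#' @slot weights numeric per-vertex areas (mm^2), parallel to `vertexIds`.
#' @export
setClass("RegionMask",
  representation(
    regionName = "character",
    vertexIds = "integer",
    weights = "numeric"
  )
)

setValidity("RegionMask", function(object) {
  msg <- character()
  if (!object@regionName %in%
      c("midforehead", "supraorbital_left", "supraorbital_right"))
    msg <- c(msg, "unknown regionName")
  if (length(object@vertexIds) == 0L)
    msg <- c(msg, "region mask is empty")
  if (length(object@weights) != length(object@vertexIds))
    msg <- c(msg, "weights and vertexIds must be parallel")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Two-cluster severity partition
#'
#' Result of [kmeans2()]: per-subject assignment to the "mild" or "severe"
#' phenotype cluster, cluster centroids in feature space (1/m), and the total
#' within-cluster sum of squares of the retained solution.  The severe cluster
#' is by definition the one with the larger mid-forehead centroid (ties broken
#' towards the smaller supraorbital centroid).
#'
#' @slot assignments named character vector (subject_id -> "mild"/"severe").
#' @slot centroids numeric matrix with rows "mild" and "severe".
#' @slot inertia total within-cluster sum of squares.
#' @slot featureSet "pooled" (h_mid, h_orb) or "three_region".
#' @export
setClass("ClusterResult",
  representation(
    assignments = "character",
    centroids = "matrix",
    inertia = "numeric",
    featureSet = "character"
  )
)

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (is.null(names(object@assignments)))
    msg <- c(msg, "assignments must be named by subject_id")
  if (!all(object@assignments %in% c("mild", "severe")))
    msg <- c(msg, "assignments must be 'mild' or 'severe'")
  if (!identical(rownames(object@centroids), c("mild", "severe")))
    msg <- c(msg, "centroids must have rows 'mild' and 'severe'")
  if (length(object@inertia) != 1L || object@inertia < 0)
    msg <- c(msg, "inertia must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Cluster-versus-clinician agreement report
#'
#' Cross-tabulation of the k-means severity assignment against the clinician
#' treatment label, mapping severe <-> operative and mild <-> conservative.
#'
#' @slot agreementFraction proportion of concordant subjects in [0, 1].
#' @slot nDiscordant number of discordant subjects.
#' @slot discordantIds their subject ids.
#' @slot contingency 2 x 2 table, cluster x clinician label.
#' @export
setClass("AgreementReport",
  representation(
    agreementFraction = "numeric",
    nDiscordant = "numeric",
    discordantIds = "character",
    contingency = "table"
  )
)

setValidity("AgreementReport", function(object) {
  n <- sum(object@contingency)
  ok <- isTRUE(all.equal(object@agreementFraction,
                         1 - object@nDiscordant / n))
  if (!ok) "agreementFraction must equal 1 - nDiscordant/n" else TRUE
})
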