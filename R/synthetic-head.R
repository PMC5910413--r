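#' Parametric synthetic head with severity dials
#'
#' Generates a head-like closed surface for end-to-end pipeline testing: a
#' subdivided-icosphere ellipsoid (infant-head scale by default) deformed by
#' (a) a midline frontal ridge whose amplitude grows and cross-sectional
#' width shrinks as `ridgeSharpness` rises from 0 to 1, emulating the keel
#' of trigonocephaly, and (b) bilateral supraorbital scoops whose depth
#' grows with `orbRetrusion`, emulating lateral orbital rim retrusion.  The
#' generator also emits ground-truth landmarks (glabella, anterior
#' fontanelle, rim polylines evaluated on the deformed surface) and
#' ground-truth region membership, so segmentation can be certified against
#' known geometry.  Deformations are bilaterally symmetric (x -> -x) and the
#' mesh vertex set is too, so left/right features match exactly at zero
#' noise.  The generator targets qualitative fidelity — ridge, retrusion,
#' symmetry — not anatomical realism or absolute clinical curvature values.
#'
#' @param semiAxes ellipsoid semi-axes (x lateral, y anterior, z vertical)
#'   in mm.
#' @param ridgeSharpness midline ridge dial in [0, 1].
#' @param orbRetrusion supraorbital scoop dial in [0, 1].
#' @param meshResolution icosphere subdivision level (4 = 2562 vertices).
#' @param noiseSd vertex jitter SD along the normal, mm.
#' @param seed RNG seed for the jitter; generation is bit-reproducible
#'   given the seed and leaves the global RNG state untouched.
#' @return list with `mesh` (a [TriangleMesh-class]), `landmarks` (a
#'   [LandmarkSet-class]), `truth` (list: `midforehead`,
#'   `supraorbital_left`, `supraorbital_right` vertex-id vectors and
#'   `symmetryPlane = list(point, normal)`), and `params` (the call
#'   parameters).
#' @examples
#' head <- makeHead(ridgeSharpness = 0.8, orbRetrusion = 0.8)
#' head$mesh
#' @export
makeHead <- function(semiAxes = c(65, 80, 75), ridgeSharpness = 0.5,
                     orbRetrusion = 0.5, meshResolution = 4L,
                     noiseSd = 0, seed = 0L) {
  stopifnot(length(semiAxes) == 3L, all(semiAxes > 0),
            ridgeSharpness >= 0, ridgeSharpness <= 1,
            orbRetrusion >= 0, orbRetrusion <= 1,
            noiseSd >= 0)
  base <- icosphere(meshResolution, 1)
  u <- vertices(base)                       # unit directions
  p <- u * matrix(semiAxes, nrow(u), 3L, byrow = TRUE)

  d <- headDisplacement(u, ridgeSharpness, orbRetrusion, semiAxes)
  nrm <- ellipsoidNormals(u, semiAxes)
  p <- p + nrm * d

  if (noiseSd > 0) {
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
      assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(as.integer(seed))
    p <- p + nrm * stats::rnorm(nrow(p), 0, noiseSd)
  }

  mesh <- TriangleMesh(p, faces(base), clean = FALSE)

  surf <- function(udir) {
    udir <- udir / sqrt(sum(udir^2))
    um <- matrix(udir, 1L, 3L)
    udir * semiAxes +
      as.numeric(ellipsoidNormals(um, semiAxes)) *
        headDisplacement(um, ridgeSharpness, orbRetrusion, semiAxes)
  }
  uG <- c(0, 0.99, 0.141)                      # glabella: low frontal midline
  uF <- c(0, 0.25, 0.968)                      # anterior fontanelle: crown
  rimT <- seq(0.22, 0.52, length.out = 5L)     # rim polylines, lateral sweep
  rimPts <- function(side) {
    t(vapply(rimT, function(cx) {
      surf(c(side * cx, sqrt(pmax(1 - cx^2 - rimCz()^2, 0.05)), rimCz()))
    }, numeric(3L)))
  }
  lm <- new("LandmarkSet",
            glabella = surf(uG),
            anteriorFontanelle = surf(uF),
            rimLeft = rimPts(+1), rimRight = rimPts(-1))

  gl <- lm@glabella; af <- lm@anteriorFontanelle
  axis <- af - gl
  tpar <- as.numeric((p - matrix(gl, nrow(p), 3L, byrow = TRUE)) %*% axis) /
    sum(axis^2)
  truthMid <- which(abs(p[, 1L]) <= 5 & tpar >= 0 & tpar <= 1 & p[, 2L] > 0)
  rimL <- lm@rimLeft; rimR <- lm@rimRight
  truthBand <- function(rim) {
    pr <- pointsToPolyline(p, rim)
    above <- (p[, 3L] - pr$point[, 3L]) > 0
    which(pr$distance <= 10 & above &
          pr$param > 1e-9 & pr$param < pr$length - 1e-9)
  }
  truth <- list(midforehead = truthMid,
                supraorbital_left = truthBand(rimL),
                supraorbital_right = truthBand(rimR),
                symmetryPlane = list(point = c(0, 0, 0),
                                     normal = c(1, 0, 0)))
  list(mesh = mesh, landmarks = lm, truth = truth,
       params = list(semiAxes = semiAxes, ridgeSharpness = ridgeSharpness,
                     orbRetrusion = orbRetrusion,
                     meshResolution = meshResolution, noiseSd = noiseSd,
                     seed = seed))
}

# z-level (unit sphere) of the rim polylines and the scoop centres; the
# scoop sits just above the rim so the 10 mm band above the rim covers it.
rimCz <- function() 0.08
scoopCz <- function() 0.22

# Outward displacement (mm) applied along the ellipsoid normal at each unit
# direction: positive Gaussian ridge along the frontal midline, negative
# Gaussian scoops over the supraorbital areas.  Window functions are smooth
# so no spurious curvature is introduced at region edges.
headDisplacement <- function(u, ridgeSharpness, orbRetrusion, semiAxes) {
  ux <- u[, 1L]; uy <- u[, 2L]; uz <- u[, 3L]
  front <- pmax(uy, 0)^2                        # frontal window, smooth at 0

  # ridge: amplitude 1..4 mm, lateral sigma 14..6 mm (in x-arc length)
  ampR <- (1 + 3 * ridgeSharpness)
  sigR <- (14 - 8 * ridgeSharpness) / semiAxes[1L]
  zWin <- exp(-((uz - 0.45) / 0.45)^4)          # glabella-to-crown extent
  ridge <- ampR * exp(-(ux / sigR)^2 / 2) * front * zWin

  # scoops: depth 0..7 mm, radius ~12 mm, centred above each rim
  ampS <- 7 * orbRetrusion
  sigS <- 12 / mean(semiAxes[c(1L, 3L)])
  scoop <- -ampS * front *
    (exp(-((ux - 0.37)^2 + (uz - scoopCz())^2) / (2 * sigS^2)) +
     exp(-((ux + 0.37)^2 + (uz - scoopCz())^2) / (2 * sigS^2)))

  ridge + scoop
}

# Unit outward normals of the ellipsoid at unit directions u.
ellipsoidNormals <- function(u, semiAxes) {
  n <- u / matrix(semiAxes, nrow(u), 3L, byrow = TRUE)
  normalizeRows(n)
}
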