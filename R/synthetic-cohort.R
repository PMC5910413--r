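#' Simulate a feature-level cohort from group summary statistics
#'
#' Draws per-subject `(h_mid, h_orb)` feature pairs for a two-group cohort
#' from bivariate normal distributions with the given group means, SDs and
#' between-feature correlation `rho`.  Defaults are the published severe /
#' mild cluster summaries of the 43-subject reference cohort (16 severe:
#' mid-forehead 38.6 +/- 7.1, supraorbital -6.7 +/- 4.7 1/m; 27 mild:
#' 28.0 +/- 4.9, 10.6 +/- 5.5 1/m) with `rho = 0` — the between-feature
#' correlation is not constrained by the published summaries, so
#' independence is the default and `rho` is exposed.  Left/right
#' supraorbital values are split as `h_orb +/- delta` with a small seeded
#' perturbation, so their mean is exactly `h_orb`.  Bit-reproducible given
#' `seed`; leaves the global RNG state untouched.
#'
#' @param nSevere,nMild group sizes.
#' @param severeMean,mildMean length-2 `(h_mid, h_orb)` group means (1/m).
#' @param severeSd,mildSd length-2 group SDs (1/m).
#' @param rho between-feature correlation, in [-1, 1].
#' @param sideSd SD of the left/right split perturbation (1/m).
#' @param seed integer RNG seed.
#' @return feature table (see [buildFeatures()] for columns) with an extra
#'   `true_group` column ("severe"/"mild") and a matching clinician-style
#'   `clinician_label` column ("operative"/"conservative") for agreement
#'   scoring.
#' @examples
#' coh <- simulateCohort(seed = 1)
#' table(coh$true_group)
#' @export
simulateCohort <- function(nSevere = 16L, nMild = 27L,
                           severeMean = c(38.6, -6.7),
                           severeSd = c(7.1, 4.7),
                           mildMean = c(28.0, 10.6),
                           mildSd = c(4.9, 5.5),
                           rho = 0, sideSd = 0.5, seed = 0L) {
  stopifnot(nSevere >= 2L, nMild >= 2L, all(severeSd >= 0), all(mildSd >= 0),
            abs(rho) <= 1, sideSd >= 0)
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(as.integer(seed))

  drawGroup <- function(n, mu, sd, group) {
    Sigma <- matrix(c(sd[1L]^2, rho * sd[1L] * sd[2L],
                      rho * sd[1L] * sd[2L], sd[2L]^2), 2L, 2L)
    X <- if (all(sd == 0)) matrix(mu, n, 2L, byrow = TRUE)
         else MASS::mvrnorm(n, mu, Sigma)
    X <- matrix(X, ncol = 2L)
    delta <- stats::rnorm(n, 0, sideSd)
    data.frame(h_mid = X[, 1L], h_orb = X[, 2L],
               h_orb_left = X[, 2L] + delta, h_orb_right = X[, 2L] - delta,
               true_group = group)
  }
  d <- rbind(drawGroup(nSevere, severeMean, severeSd, "severe"),
             drawGroup(nMild, mildMean, mildSd, "mild"))
  data.frame(
    subject_id = sprintf("S%03d", seq_len(nrow(d))),
    source = "synthetic",
    h_mid = d$h_mid, h_orb_left = d$h_orb_left,
    h_orb_right = d$h_orb_right, h_orb = d$h_orb,
    ok = TRUE, note = "",
    true_group = d$true_group,
    clinician_label = ifelse(d$true_group == "severe",
                             "operative", "conservative"))
}

#' Agreement of a clustering with the generating group labels
#'
#' Convenience wrapper for simulation studies: scores a [kmeans2()] result
#' against the `true_group` column of a simulated cohort (severe cluster
#' matched to severe group).
#'
#' @param result a [ClusterResult-class].
#' @param cohort a [simulateCohort()] table.
#' @return fraction of subjects assigned to their generating group.
#' @export
trueGroupAgreement <- function(result, cohort) {
  ids <- names(result@assignments)
  truth <- cohort$true_group[match(ids, cohort$subject_id)]
  if (any(is.na(truth))) stop("cohort lacks true_group for some subjects")
  mean(result@assignments == truth)
}
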