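#' Assemble per-subject curvature feature vectors
#'
#' Takes one entry per subject, each a list with elements `field` (a
#' [CurvatureField-class]) and `masks` (a named list with `midforehead`,
#' `supraorbital_left`, `supraorbital_right` [RegionMask-class] objects),
#' and returns one feature row per subject: the mid-forehead region mean
#' `h_mid`, the per-side supraorbital means, and their average `h_orb` (the
#' paired supraorbital bands are reported as a single pooled value, with the
#' per-side values retained).  A subject whose regions fail to yield a
#' feature is kept in the table with `ok = FALSE` and the failure message in
#' `note`, so one bad scan never aborts a batch; downstream statistics drop
#' such rows.
#'
#' @param subjects named list (names are subject ids) of
#'   `list(field =, masks =)` entries; an optional `source` element
#'   ("ct", "stereo" or "synthetic") is carried through.
#' @return data.frame with columns `subject_id`, `source`, `h_mid`,
#'   `h_orb_left`, `h_orb_right`, `h_orb`, `ok`, `note`.
#' @export
buildFeatures <- function(subjects) {
  ids <- names(subjects)
  if (is.null(ids) || any(ids == ""))
    stop("'subjects' must be a named list keyed by subject_id")
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- lapply(ids, function(id) {
    s <- subjects[[id]]
    src <- if (is.null(s$source)) "synthetic" else s$source
    res <- tryCatch({
      hm <- regionMeanCurvature(s$field, s$masks$midforehead)
      hl <- regionMeanCurvature(s$field, s$masks$supraorbital_left)
      hr <- regionMeanCurvature(s$field, s$masks$supraorbital_right)
      data.frame(subject_id = id, source = src, h_mid = hm,
                 h_orb_left = hl, h_orb_right = hr, h_orb = (hl + hr) / 2,
                 ok = TRUE, note = "")
    }, error = function(e) {
      data.frame(subject_id = id, source = src, h_mid = NA_real_,
                 h_orb_left = NA_real_, h_orb_right = NA_real_,
                 h_orb = NA_real_, ok = FALSE, note = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group summary statistics and group differences
#'
#' Joins the feature table to the clinician label table and reports, per
#' group, n and the mean and standard deviation (n - 1 denominator) of
#' `h_mid` and `h_orb`, plus the operative-minus-conservative differences of
#' the two group means.  Subjects flagged `ok = FALSE` are excluded.
#'
#' @param features output of [buildFeatures()] or [simulateCohort()].
#' @param labels data.frame with `subject_id`, `clinician_label`
#'   ("conservative"/"operative"), e.g. from [readLabels()].
#' @return list with `groups` (data.frame: group, n, h_mid_mean, h_mid_sd,
#'   h_orb_mean, h_orb_sd) and `differences` (named numeric: `h_mid`,
#'   `h_orb`, operative minus conservative).
#' @export
groupSummary <- function(features, labels) {
  d <- joinLabels(features, labels)
  out <- lapply(split(d, d$clinician_label), function(g) {
    if (nrow(g) < 2L)
      stop("group '", g$clinician_label[1L],
           "' has fewer than 2 subjects; summary statistics undefined")
    data.frame(group = g$clinician_label[1L], n = nrow(g),
               h_mid_mean = mean(g$h_mid), h_mid_sd = stats::sd(g$h_mid),
               h_orb_mean = mean(g$h_orb), h_orb_sd = stats::sd(g$h_orb))
  })
  groups <- do.call(rbind, out)
  rownames(groups) <- NULL
  op <- groups[groups$group == "operative", ]
  co <- groups[groups$group == "conservative", ]
  if (nrow(op) == 0L || nrow(co) == 0L)
    stop("both an operative and a conservative group are required")
  list(groups = groups,
       differences = c(h_mid = op$h_mid_mean - co$h_mid_mean,
                       h_orb = op$h_orb_mean - co$h_orb_mean))
}

joinLabels <- function(features, labels) {
  feat <- features
  if (!is.null(feat$ok)) feat <- feat[feat$ok, , drop = FALSE]
  miss <- setdiff(feat$subject_id, labels$subject_id)
  if (length(miss))
    stop("unlabeled subject(s): ", paste(miss, collapse = ", "))
  feat$clinician_label <-
    labels$clinician_label[match(feat$subject_id, labels$subject_id)]
  feat
}

#' Group differences from a published-style summary table
#'
#' Computes the first-row-minus-second-row differences of the two feature
#' means from a summary-statistics table of the shape returned by
#' [referenceCohortStats()] (columns `group`, `n`, `h_mid_mean`, `h_mid_sd`,
#' `h_orb_mean`, `h_orb_sd`), for a chosen pair of groups.
#'
#' @param stats a summary-statistics data.frame.
#' @param groupA,groupB group names; the result is A minus B.
#' @return named numeric `c(h_mid =, h_orb =)`.
#' @examples
#' ref <- referenceCohortStats()
#' summaryDifferences(ref, "surgical", "non_surgical")
#' # h_mid 11.3, h_orb -16.1: the operated children have a sharper midline
#' # ridge and retruded (concave) supraorbital rims
#' @export
summaryDifferences <- function(stats, groupA, groupB) {
  a <- stats[stats$group == groupA, ]
  b <- stats[stats$group == groupB, ]
  if (nrow(a) != 1L || nrow(b) != 1L)
    stop("groups not found (or not unique) in summary table: ",
         groupA, ", ", groupB)
  c(h_mid = a$h_mid_mean - b$h_mid_mean,
    h_orb = a$h_orb_mean - b$h_orb_mean)
}

#' Reference cohort summary statistics
#'
#' The published group-level mean curvature summaries (mean, SD in 1/m) for
#' a 43-subject metopic cohort: surgically and conservatively treated groups
#' and the corresponding severe/mild k-means cluster analogues.  These are
#' the parameters the cohort simulator draws from and the arithmetic anchor
#' for the group-difference computation.
#'
#' @return data.frame with columns `group`, `n`, `h_mid_mean`, `h_mid_sd`,
#'   `h_orb_mean`, `h_orb_sd`.
#' @export
referenceCohortStats <- function() {
  path <- system.file("extdata", "reference_cohort_stats.csv",
                      package = "craniocurv", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d
}

#' Welch two-sample comparison of a feature between label groups
#'
#' Welch's unequal-variance two-sample t-test (two-sided) on the named
#' feature between the operative and conservative groups; chosen over
#' Student's t because the groups have unequal sizes and spreads.  Set
#' `varEqual = TRUE` for the pooled-variance variant.  When both groups are
#' constant with equal means the statistic is undefined; the function then
#' returns t = 0, p = 1 with a warning rather than failing.
#'
#' @param features feature table (see [buildFeatures()]).
#' @param labels clinician label table.
#' @param feature column to test, "h_mid" or "h_orb".
#' @param varEqual use the pooled-variance Student test instead.
#' @return list with `statistic` (t, operative minus conservative), `df`,
#'   `p.value`, `feature`.
#' @export
welchTest <- function(features, labels, feature = c("h_mid", "h_orb"),
                      varEqual = FALSE) {
  feature <- match.arg(feature)
  d <- joinLabels(features, labels)
  x <- d[[feature]][d$clinician_label == "operative"]
  y <- d[[feature]][d$clinician_label == "conservative"]
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need n >= 2 for a two-sample test")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("zero variance in both groups with equal means; p = 1")
      return(list(statistic = 0, df = NA_real_, p.value = 1,
                  feature = feature))
    }
    stop("zero variance in both groups with unequal means; ",
         "test statistic unbounded")
  }
  tt <- stats::t.test(x, y, var.equal = varEqual)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, feature = feature)
}

#' Export a feature table as CSV
#'
#' @param features feature table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(features, path) {
  cols <- intersect(c("subject_id", "source", "h_mid", "h_orb_left",
                      "h_orb_right", "h_orb", "ok", "note", "true_group"),
                    names(features))
  utils::write.csv(features[, cols], path, row.names = FALSE)
  invisible(path)
}
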