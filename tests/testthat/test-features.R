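makeSubject <- function(ridge = 0.5, orb = 0.5) {
  h <- headFixture(ridge, orb)
  fld <- headField(ridge, orb)
  list(field = fld, masks = list(
    midforehead = segmentMidforehead(h$mesh, h$landmarks, 10),
    supraorbital_left = segmentSupraorbital(
      h$mesh, h$landmarks@rimLeft, 10, c(0, 0, 1), "supraorbital_left"),
    supraorbital_right = segmentSupraorbital(
      h$mesh, h$landmarks@rimRight, 10, c(0, 0, 1), "supraorbital_right")))
}

test_that("feature rows pool the supraorbital sides by averaging", {
  subj <- makeSubject()
  feat <- buildFeatures(list(p1 = subj, p2 = subj))
  expect_equal(nrow(feat), 2L)
  expect_equal(feat$h_orb, (feat$h_orb_left + feat$h_orb_right) / 2)
  # bilateral symmetry of the generator carries into the features
  expect_lt(abs(feat$h_orb_left[1L] - feat$h_orb_right[1L]),
            0.01 * abs(feat$h_orb[1L]))
  expect_error(buildFeatures(setNames(list(subj, subj), c("x", "x"))),
               "duplicate")
})

test_that("a failed segmentation flags the subject without killing the batch", {
  good <- makeSubject()
  bad <- good
  # mask referencing only invalid vertices triggers the propagation error
  bad$field@valid[] <- FALSE
  bad$field@H[] <- NA_real_
  feat <- buildFeatures(list(ok1 = good, broken = bad))
  expect_true(feat$ok[feat$subject_id == "ok1"])
  expect_false(feat$ok[feat$subject_id == "broken"])
  expect_match(feat$note[feat$subject_id == "broken"], "valid")
  # flagged row is excluded from downstream statistics
  labels <- data.frame(subject_id = c("ok1", "broken"),
                       clinician_label = c("operative", "operative"))
  expect_error(groupSummary(feat, labels), "fewer than 2|conservative")
})

test_that("group summaries match hand-computed means, sds and differences", {
  feat <- data.frame(subject_id = c("a", "b", "c", "d"),
                     h_mid = c(1, 3, 5, 7), h_orb = c(1, 3, 5, 7),
                     ok = TRUE)
  labels <- data.frame(subject_id = c("a", "b", "c", "d"),
                       clinician_label = c("operative", "operative",
                                           "conservative", "conservative"))
  s <- groupSummary(feat, labels)
  op <- s$groups[s$groups$group == "operative", ]
  co <- s$groups[s$groups$group == "conservative", ]
  expect_equal(op$h_mid_mean, 2)
  expect_equal(co$h_mid_mean, 6)
  expect_equal(op$h_mid_sd, sqrt(2))   # n-1 denominator
  expect_equal(co$h_mid_sd, sqrt(2))
  expect_equal(unname(s$differences["h_mid"]), -4)

  # permutation invariance in subject order
  perm <- feat[c(3, 1, 4, 2), ]
  s2 <- groupSummary(perm, labels)
  expect_equal(s2$groups[order(s2$groups$group), ],
               s$groups[order(s$groups$group), ], ignore_attr = TRUE)

  # antisymmetry under wholesale label swap
  swapped <- labels
  swapped$clinician_label <- ifelse(labels$clinician_label == "operative",
                                    "conservative", "operative")
  s3 <- groupSummary(feat, swapped)
  expect_equal(unname(s3$differences), -unname(s$differences))

  # identical constant groups: zero differences exactly
  cf <- data.frame(subject_id = c("a", "b", "c", "d"),
                   h_mid = 5, h_orb = -2, ok = TRUE)
  s4 <- groupSummary(cf, labels)
  expect_identical(unname(s4$differences), c(0, 0))
})

test_that("summary-table differences reproduce the published arithmetic", {
  ref <- referenceCohortStats()
  d <- summaryDifferences(ref, "surgical", "non_surgical")
  expect_equal(unname(d["h_mid"]), 11.3)
  expect_equal(unname(d["h_orb"]), -16.1)
  expect_error(summaryDifferences(ref, "surgical", "nope"), "not found")
})

test_that("welchTest agrees with the hand-computed Welch formula", {
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7, 23.2,
         17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 23.9, 13.3)
  feat <- data.frame(subject_id = sprintf("s%02d", seq_along(c(x, y))),
                     h_mid = c(x, y), h_orb = c(x, y), ok = TRUE)
  labels <- data.frame(subject_id = feat$subject_id,
                       clinician_label = rep(c("operative", "conservative"),
                                             c(length(x), length(y))))
  got <- welchTest(feat, labels, "h_mid")
  # independent implementation of Welch's statistic, df and p
  se2 <- var(x) / length(x) + var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                 (var(y) / length(y))^2 / (length(y) - 1))
  p <- 2 * pt(-abs(tstat), df)
  expect_equal(got$statistic, tstat, tolerance = 1e-10)
  expect_equal(got$df, df, tolerance = 1e-10)
  expect_equal(got$p.value, p, tolerance = 1e-10)
})

test_that("welchTest handles identical and degenerate groups", {
  v <- c(1, 2, 3)
  feat <- data.frame(subject_id = sprintf("s%d", 1:6),
                     h_mid = c(v, v), h_orb = c(v, v), ok = TRUE)
  labels <- data.frame(subject_id = feat$subject_id,
                       clinician_label = rep(c("operative", "conservative"),
                                             each = 3L))
  got <- welchTest(feat, labels, "h_mid")
  expect_equal(got$statistic, 0)
  expect_equal(got$p.value, 1)

  const <- data.frame(subject_id = sprintf("s%d", 1:6),
                      h_mid = 4, h_orb = 4, ok = TRUE)
  expect_warning(res <- welchTest(const, labels, "h_mid"), "zero variance")
  expect_equal(res$p.value, 1)

  small <- feat[c(1, 4, 5), ]
  expect_error(welchTest(small, labels, "h_mid"), "n >= 2")
})
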