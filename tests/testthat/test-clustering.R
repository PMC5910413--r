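test_that("perfectly separated pairs cluster with the expected centroids", {
  feat <- data.frame(subject_id = c("a", "b", "c", "d"),
                     h_mid = c(28, 28, 39, 39),
                     h_orb = c(10, 11, -6, -5))
  res <- kmeans2(feat, seed = 0L, nRestarts = 10L)
  a <- assignments(res)
  expect_identical(unname(a[c("a", "b")]), c("mild", "mild"))
  expect_identical(unname(a[c("c", "d")]), c("severe", "severe"))
  expect_equal(centroids(res)["mild", ], c(h_mid = 28, h_orb = 10.5))
  expect_equal(centroids(res)["severe", ], c(h_mid = 39, h_orb = -5.5))
})

test_that("kmeans2 matches exhaustive 2-partition minimisation at n = 6", {
  for (s in 1:20) {
    set.seed(1000 + s)
    X <- cbind(rnorm(6L, 33, 7), rnorm(6L, 2, 8))
    feat <- data.frame(subject_id = sprintf("p%d", 1:6),
                       h_mid = X[, 1L], h_orb = X[, 2L])
    res <- kmeans2(feat, seed = s, nRestarts = 50L)
    oracle <- bruteForce2Partition(X)
    expect_equal(inertia(res), oracle$inertia, tolerance = 1e-9)
    # identical partition, not just identical objective
    lab <- assignments(res)[sprintf("p%d", 1:6)]
    sameSide <- outer(lab, lab, "==")
    oracleSide <- outer(oracle$assign, oracle$assign, "==")
    expect_identical(unname(sameSide), unname(oracleSide))
  }
})

test_that("kmeans2 is invariant to subject order and point duplication", {
  coh <- simulateCohort(seed = 3L)
  res <- kmeans2(coh, seed = 0L)
  perm <- coh[sample(nrow(coh)), ]
  res2 <- kmeans2(perm, seed = 0L)
  expect_identical(assignments(res2)[names(assignments(res))],
                   assignments(res))
  expect_equal(centroids(res2), centroids(res))

  dup <- rbind(coh, transform(coh, subject_id = paste0(subject_id, "_dup")))
  res3 <- kmeans2(dup, seed = 0L)
  expect_equal(centroids(res3), centroids(res), tolerance = 1e-9)
  expect_equal(sum(assignments(res3) == "severe"),
               2L * sum(assignments(res) == "severe"))
})

test_that("restart selection is monotone in the objective", {
  coh <- simulateCohort(seed = 9L)
  # the first restart of the 50-start stream equals the single-start run
  one <- kmeans2(coh, seed = 4L, nRestarts = 1L)
  many <- kmeans2(coh, seed = 4L, nRestarts = 50L)
  expect_lte(inertia(many), inertia(one))
  # and the selected optimum matches an independent implementation
  ref <- stats::kmeans(as.matrix(coh[, c("h_mid", "h_orb")]), centers = 2L,
                       nstart = 50L, iter.max = 300L)
  expect_equal(inertia(many), ref$tot.withinss, tolerance = 1e-8)
})

test_that("three-region feature space is exposed", {
  coh <- simulateCohort(seed = 5L)
  res <- kmeans2(coh, featureSet = "three_region", seed = 0L)
  expect_identical(colnames(centroids(res)),
                   c("h_mid", "h_orb_left", "h_orb_right"))
  expect_gt(trueGroupAgreement(res, coh), 0.9)
})

test_that("degenerate clustering inputs raise input errors", {
  one <- data.frame(subject_id = "a", h_mid = 1, h_orb = 1)
  expect_error(kmeans2(one), "at least 2")
  flat <- data.frame(subject_id = c("a", "b", "c"), h_mid = 5, h_orb = 5)
  expect_error(kmeans2(flat), "identical")
})

test_that("agreement maps severe to operative and counts discordances", {
  ids <- sprintf("s%02d", 1:10)
  res <- new("ClusterResult",
             assignments = setNames(rep(c("severe", "mild"), each = 5L), ids),
             centroids = rbind(mild = c(h_mid = 28, h_orb = 10),
                               severe = c(h_mid = 39, h_orb = -6)),
             inertia = 1, featureSet = "pooled")
  labels <- data.frame(subject_id = ids,
                       clinician_label = rep(c("operative", "conservative"),
                                             each = 5L))
  rep1 <- clusterAgreement(res, labels)
  expect_equal(agreementFraction(rep1), 1)
  expect_length(discordantIds(rep1), 0L)

  # 43 subjects, 2 mismatches -> 41/43 (the 96 % figure at its rounding)
  ids43 <- sprintf("p%02d", 1:43)
  assign43 <- setNames(rep(c("severe", "mild"), c(16L, 27L)), ids43)
  res43 <- new("ClusterResult", assignments = assign43,
               centroids = rbind(mild = c(h_mid = 28, h_orb = 10.6),
                                 severe = c(h_mid = 38.6, h_orb = -6.7)),
               inertia = 1, featureSet = "pooled")
  lab43 <- data.frame(
    subject_id = ids43,
    clinician_label = rep(c("operative", "conservative"), c(16L, 27L)))
  lab43$clinician_label[1L] <- "conservative"
  lab43$clinician_label[20L] <- "operative"
  rep43 <- clusterAgreement(res43, lab43)
  expect_equal(agreementFraction(rep43), 41 / 43)
  expect_setequal(discordantIds(rep43), c("p01", "p20"))
  expect_equal(sum(contingency(rep43)), 43)

  # wholesale label inversion complements the agreement
  inv <- lab43
  inv$clinician_label <- ifelse(lab43$clinician_label == "operative",
                                "conservative", "operative")
  expect_equal(agreementFraction(clusterAgreement(res43, inv)),
               1 - agreementFraction(rep43))

  expect_error(clusterAgreement(res43, lab43[-1L, ]), "unlabeled")
})
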