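#' Two-cluster k-means severity partition
#'
#' Partitions subjects into "mild" and "severe" phenotype clusters by
#' k-means with k = 2: Lloyd's algorithm with k-means++ initialisation,
#' `nRestarts` independent seeded starts, keeping the lowest within-cluster
#' sum of squares.  Iterations stop when assignments stabilise or after 300
#' rounds; an emptied cluster is re-seeded at the point farthest from its
#' centroid.  The severe cluster is, by definition, the one with the larger
#' mid-forehead centroid (ties broken towards the smaller supraorbital
#' centroid).  Deterministic given `(features, seed, nRestarts)`; the
#' global RNG state is left untouched.
#'
#' Features are clustered raw (the two default features live on comparable
#' 1/m scales); set `standardize = TRUE` to z-score columns first.  The
#' default 2-D feature space is `(h_mid, h_orb)`; `featureSet =
#' "three_region"` clusters on `(h_mid, h_orb_left, h_orb_right)` instead.
#'
#' @param features feature table with `subject_id` and the feature columns;
#'   rows with `ok = FALSE` are dropped.
#' @param featureSet "pooled" (default) or "three_region".
#' @param seed integer RNG seed for the restarts.
#' @param nRestarts number of independent k-means++ starts.
#' @param standardize z-score the feature columns before clustering.
#' @return a [ClusterResult-class].  Centroids are reported on the raw
#'   feature scale regardless of `standardize`.
#' @examples
#' coh <- simulateCohort(seed = 7)
#' res <- kmeans2(coh)
#' res
#' @export
kmeans2 <- function(features, featureSet = c("pooled", "three_region"),
                    seed = 0L, nRestarts = 50L, standardize = FALSE) {
  featureSet <- match.arg(featureSet)
  if (!is.null(features$ok)) features <- features[features$ok, , drop = FALSE]
  cols <- if (featureSet == "pooled") c("h_mid", "h_orb")
          else c("h_mid", "h_orb_left", "h_orb_right")
  if (!all(cols %in% names(features)))
    stop("feature table lacks columns: ",
         paste(setdiff(cols, names(features)), collapse = ", "))
  # order-invariance: cluster in a canonical row order
  ord <- order(features$subject_id)
  features <- features[ord, , drop = FALSE]
  X <- as.matrix(features[, cols])
  if (nrow(X) < 2L) stop("k-means needs at least 2 subjects")
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (all(apply(X, 2L, function(c) max(c) - min(c)) == 0))
    stop("degenerate clustering: all subjects have identical features")
  Xs <- if (standardize) scale(X) else X

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))

  best <- NULL
  for (r in seq_len(nRestarts)) {
    fit <- lloyd2(Xs)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }

  assign01 <- best$assign                     # 1/2, arbitrary order
  centScaled <- best$centroids
  cent <- rowsum(X, assign01) / as.vector(table(assign01))
  colnames(cent) <- cols
  # severe = larger h_mid centroid; ties towards smaller orbital centroid
  orbCol <- if (featureSet == "pooled") "h_orb" else "h_orb_left"
  sev <- if (cent[1L, "h_mid"] > cent[2L, "h_mid"]) 1L
         else if (cent[1L, "h_mid"] < cent[2L, "h_mid"]) 2L
         else if (cent[1L, orbCol] <= cent[2L, orbCol]) 1L else 2L
  lab <- ifelse(assign01 == sev, "severe", "mild")
  names(lab) <- features$subject_id
  centroids <- rbind(mild = cent[3L - sev, ], severe = cent[sev, ])
  new("ClusterResult", assignments = lab, centroids = centroids,
      inertia = best$inertia, featureSet = featureSet)
}

# One Lloyd run with k-means++ seeding on the current RNG stream.
lloyd2 <- function(X) {
  n <- nrow(X)
  # k-means++: first centre uniform, second with probability ~ D^2
  i1 <- sample.int(n, 1L)
  d2 <- rowSums((X - matrix(X[i1, ], n, ncol(X), byrow = TRUE))^2)
  i2 <- if (all(d2 == 0)) sample.int(n, 1L)
        else sample.int(n, 1L, prob = d2)
  C <- X[c(i1, i2), , drop = FALSE]
  assign <- integer(n)
  for (it in seq_len(300L)) {
    D <- cbind(rowSums((X - matrix(C[1L, ], n, ncol(X), byrow = TRUE))^2),
               rowSums((X - matrix(C[2L, ], n, ncol(X), byrow = TRUE))^2))
    newAssign <- max.col(-D, ties.method = "first")
    for (k in 1:2) {
      if (!any(newAssign == k)) {
        # empty cluster: re-seed at the point farthest from the other centre
        far <- which.max(D[, 3L - k])
        newAssign[far] <- k
      }
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
    C <- rowsum(X, assign) / as.vector(table(assign))
  }
  D <- cbind(rowSums((X - matrix(C[1L, ], n, ncol(X), byrow = TRUE))^2),
             rowSums((X - matrix(C[2L, ], n, ncol(X), byrow = TRUE))^2))
  inertia <- sum(D[cbind(seq_len(n), assign)])
  list(assign = assign, centroids = C, inertia = inertia)
}

#' @rdname ClusterResult-class
#' @param result a [ClusterResult-class].
#' @export
assignments <- function(result) result@assignments

#' @rdname ClusterResult-class
#' @export
centroids <- function(result) result@centroids

#' @rdname ClusterResult-class
#' @export
inertia <- function(result) result@inertia

setMethod("show", "ClusterResult", function(object) {
  tab <- table(object@assignments)
  cat(sprintf("ClusterResult (k = 2, %s features): %d mild, %d severe\n",
              object@featureSet,
              if ("mild" %in% names(tab)) tab[["mild"]] else 0L,
              if ("severe" %in% names(tab)) tab[["severe"]] else 0L))
  cat("  centroids [1/m]:\n")
  print(round(object@centroids, 2))
  cat(sprintf("  within-cluster SS: %.2f\n", object@inertia))
})

#' Agreement between cluster assignment and clinician decision
#'
#' Maps severe <-> operative and mild <-> conservative and scores the
#' proportion of subjects on which the unsupervised clustering and the
#' clinicians agree, with the 2 x 2 contingency table and the list of
#' discordant subjects.
#'
#' @param result a [ClusterResult-class].
#' @param labels clinician label table (`subject_id`, `clinician_label`).
#' @return an [AgreementReport-class].
#' @export
clusterAgreement <- function(result, labels) {
  ids <- names(result@assignments)
  miss <- setdiff(ids, labels$subject_id)
  if (length(miss))
    stop("unlabeled subject(s): ", paste(miss, collapse = ", "))
  lab <- labels$clinician_label[match(ids, labels$subject_id)]
  clust <- result@assignments
  expected <- ifelse(clust == "severe", "operative", "conservative")
  disc <- ids[expected != lab]
  tab <- table(cluster = factor(clust, c("mild", "severe")),
               clinician = factor(lab, c("conservative", "operative")))
  new("AgreementReport",
      agreementFraction = 1 - length(disc) / length(ids),
      nDiscordant = length(disc),
      discordantIds = disc,
      contingency = tab)
}

#' @rdname AgreementReport-class
#' @param report an [AgreementReport-class].
#' @export
agreementFraction <- function(report) report@agreementFraction

#' @rdname AgreementReport-class
#' @export
discordantIds <- function(report) report@discordantIds

#' @rdname AgreementReport-class
#' @export
contingency <- function(report) report@contingency

setMethod("show", "AgreementReport", function(object) {
  cat(sprintf("AgreementReport: %.1f%% agreement, %d discordant subject(s)\n",
              100 * object@agreementFraction, object@nDiscordant))
  if (object@nDiscordant > 0)
    cat("  discordant:", paste(object@discordantIds, collapse = ", "), "\n")
  print(object@contingency)
})

#' Severity scatter plot of a clustered cohort
#'
#' Supraorbital versus mid-forehead mean curvature, one point per subject,
#' coloured by cluster; when a label table is supplied, subjects discordant
#' with the clinician decision are highlighted.
#'
#' @param features feature table used for clustering.
#' @param result the [ClusterResult-class] for those features.
#' @param labels optional clinician label table.
#' @return a ggplot object.
#' @export
plotClusters <- function(features, result, labels = NULL) {
  if (!is.null(features$ok)) features <- features[features$ok, , drop = FALSE]
  d <- features
  d$cluster <- result@assignments[d$subject_id]
  d$discordant <- FALSE
  if (!is.null(labels)) {
    rep <- clusterAgreement(result, labels)
    d$discordant <- d$subject_id %in% rep@discordantIds
  }
  cent <- as.data.frame(result@centroids)
  cent$cluster <- rownames(cent)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$h_mid, y = .data$h_orb,
                                       colour = .data$cluster)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$discordant), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                guide = "none") +
    ggplot2::geom_point(data = cent, shape = 3, size = 4, stroke = 1.5,
                        ggplot2::aes(shape = NULL)) +
    ggplot2::labs(x = "mid-forehead mean curvature [1/m]",
                  y = "supraorbital mean curvature [1/m]",
                  colour = "phenotype") +
    ggplot2::theme_minimal()
  if (any(d$discordant))
    p <- p + ggplot2::geom_point(data = d[d$discordant, ], shape = 1,
                                 size = 4, colour = "black")
  p
}

#' Export cluster assignments as CSV
#'
#' Columns `subject_id,cluster,clinician_label,discordant` (label columns
#' empty when no label table is given).
#'
#' @param result a [ClusterResult-class].
#' @param path output CSV path.
#' @param labels optional clinician label table.
#' @return `path`, invisibly.
#' @export
writeClusterCSV <- function(result, path, labels = NULL) {
  ids <- names(result@assignments)
  d <- data.frame(subject_id = ids, cluster = unname(result@assignments),
                  clinician_label = NA_character_, discordant = NA)
  if (!is.null(labels)) {
    rep <- clusterAgreement(result, labels)
    d$clinician_label <- labels$clinician_label[match(ids, labels$subject_id)]
    d$discordant <- ids %in% rep@discordantIds
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
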