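#' Pipeline configuration
#'
#' Assembles (and validates) the configuration consumed by
#' [runPipeline()]: input locations, curvature options, region widths and
#' clustering options.  Every analysis-relevant value actually used is
#' echoed into the run manifest, so a run is auditable.
#'
#' @param meshDir directory of per-subject `<id>.stl` meshes.
#' @param landmarkDir directory of per-subject `<id>.json` or `<id>.csv`
#'   landmark files.
#' @param labelsFile optional clinician label CSV.
#' @param outputDir where artifacts are written.
#' @param estimator "cotangent" (default) or "quadric".
#' @param smoothingIterations curvature smoothing rounds (default 0; raise
#'   for noisy scan meshes).
#' @param midWidth mid-forehead full strip width, mm.
#' @param orbWidth supraorbital band depth, mm.
#' @param upHint direction towards the vertex of the head.
#' @param featureSet,seed,nRestarts,standardize [kmeans2()] options.
#' @param simulate named list of [simulateCohort()] arguments for the
#'   `simulate` step.
#' @param exportPLY also write colour-mapped curvature PLYs.
#' @return a validated config list of class `craniocurv_config`.
#' @export
pipelineConfig <- function(meshDir = NULL, landmarkDir = NULL,
                           labelsFile = NULL, outputDir = "craniocurv_out",
                           estimator = c("cotangent", "quadric"),
                           smoothingIterations = 0L,
                           midWidth = 10, orbWidth = 10,
                           upHint = c(0, 0, 1),
                           featureSet = c("pooled", "three_region"),
                           seed = 0L, nRestarts = 50L, standardize = FALSE,
                           simulate = list(), exportPLY = FALSE) {
  estimator <- match.arg(estimator)
  featureSet <- match.arg(featureSet)
  if (midWidth <= 0 || orbWidth <= 0) stop("region widths must be > 0")
  structure(list(
    meshDir = meshDir, landmarkDir = landmarkDir, labelsFile = labelsFile,
    outputDir = outputDir, estimator = estimator,
    smoothingIterations = as.integer(smoothingIterations),
    midWidth = midWidth, orbWidth = orbWidth, upHint = upHint,
    featureSet = featureSet, seed = as.integer(seed),
    nRestarts = as.integer(nRestarts), standardize = standardize,
    simulate = simulate, exportPLY = exportPLY
  ), class = "craniocurv_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` config file whose keys mirror the
#'   [pipelineConfig()] arguments.
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  do.call(pipelineConfig, raw)
}

#' Run the curvature-to-clustering pipeline
#'
#' Executes the requested steps in order.  Available steps:
#' \describe{
#'   \item{simulate}{draw a feature-level cohort ([simulateCohort()] with
#'     `config$simulate` arguments) and write `features.csv` and
#'     `labels.csv`.}
#'   \item{curvature}{per subject in `meshDir`: read the STL, estimate the
#'     curvature field, write `curvature/<id>.csv` (and a QC PLY if
#'     configured).}
#'   \item{segment}{per subject: read landmarks, segment the three regions,
#'     write `regions/<id>.csv`.}
#'   \item{features}{combine fields and masks into `features.csv`.}
#'   \item{cluster}{k-means on `features.csv`, write `clusters.csv`, a
#'     severity scatter `clusters.png`, and — when labels are available —
#'     an agreement report `agreement.json`.}
#'   \item{report}{group summary (per clinician label) and Welch tests,
#'     written to `group_summary.csv` and `welch_tests.csv`.}
#' }
#' The mesh-based steps (`curvature`, `segment`, `features`) cache fields
#' and masks in memory within one call.  Per-subject failures are isolated:
#' the subject is recorded as failed in the manifest and excluded from
#' downstream statistics, and only a batch-level failure (no usable
#' subjects, missing configuration) raises an error.  A `manifest.json`
#' with the config echo, package version, seeds and per-subject status is
#' written on every run.
#'
#' @param config a [pipelineConfig()] list.
#' @param steps character vector of steps, in execution order.
#' @return invisibly, a list with the computed `features`, `cluster` result,
#'   `agreement`, `summary` and the per-subject `status` data.frame.
#' @export
runPipeline <- function(config,
                        steps = c("curvature", "segment", "features",
                                  "cluster", "report")) {
  stopifnot(inherits(config, "craniocurv_config"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  state <- list(features = NULL, cluster = NULL, agreement = NULL,
                summary = NULL,
                status = data.frame(subject_id = character(),
                                    step = character(), ok = logical(),
                                    note = character()))
  labels <- NULL
  if (!is.null(config$labelsFile)) labels <- readLabels(config$labelsFile)

  fields <- list(); masks <- list()

  for (step in steps) {
    state <- switch(step,
      simulate = stepSimulate(config, state),
      curvature = ,
      segment = ,
      features = {
        res <- stepMeshFeatures(config, state, step, fields, masks)
        fields <- res$fields; masks <- res$masks
        res$state
      },
      cluster = stepCluster(config, state, labels),
      report = stepReport(config, state, labels),
      stop("unknown pipeline step: ", step))
  }

  manifest <- list(
    package = as.character(utils::packageVersion("craniocurv")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    steps = steps,
    status = state$status
  )
  jsonlite::write_json(manifest, file.path(config$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(state)
}

recordStatus <- function(state, id, step, ok, note = "") {
  state$status <- rbind(state$status,
                        data.frame(subject_id = id, step = step, ok = ok,
                                   note = note))
  state
}

stepSimulate <- function(config, state) {
  coh <- do.call(simulateCohort, config$simulate)
  writeFeatureCSV(coh, file.path(config$outputDir, "features.csv"))
  utils::write.csv(coh[, c("subject_id", "clinician_label")],
                   file.path(config$outputDir, "labels.csv"),
                   row.names = FALSE)
  state$features <- coh
  recordStatus(state, "(cohort)", "simulate", TRUE,
               sprintf("%d subjects simulated", nrow(coh)))
}

subjectIds <- function(config) {
  if (is.null(config$meshDir) || !dir.exists(config$meshDir))
    stop("configuration error: meshDir is not set or does not exist")
  files <- list.files(config$meshDir, pattern = "\\.stl$", ignore.case = TRUE)
  if (length(files) == 0L)
    stop("configuration error: no STL meshes in ", config$meshDir)
  sub("\\.stl$", "", files, ignore.case = TRUE)
}

landmarkPath <- function(config, id) {
  if (is.null(config$landmarkDir))
    stop("configuration error: landmarkDir is not set")
  for (ext in c(".json", ".csv")) {
    p <- file.path(config$landmarkDir, paste0(id, ext))
    if (file.exists(p)) return(p)
  }
  stop("no landmark file for subject ", id)
}

stepMeshFeatures <- function(config, state, step, fields, masks) {
  ids <- subjectIds(config)
  for (id in ids) {
    res <- tryCatch({
      if (is.null(fields[[id]])) {
        mesh <- readSTL(file.path(config$meshDir, paste0(id, ".stl")))
        fld <- if (config$estimator == "quadric") quadricCurvature(mesh)
               else meanCurvature(mesh)
        fld <- smoothField(fld, mesh, config$smoothingIterations)
        fields[[id]] <- list(mesh = mesh, field = fld)
      }
      if (step %in% c("segment", "features") && is.null(masks[[id]])) {
        mesh <- fields[[id]]$mesh
        lm <- readLandmarks(landmarkPath(config, id), mesh)
        masks[[id]] <- list(
          midforehead = segmentMidforehead(mesh, lm, config$midWidth),
          supraorbital_left = segmentSupraorbital(
            mesh, lm@rimLeft, config$orbWidth, config$upHint,
            "supraorbital_left"),
          supraorbital_right = segmentSupraorbital(
            mesh, lm@rimRight, config$orbWidth, config$upHint,
            "supraorbital_right"))
      }
      TRUE
    }, error = function(e) conditionMessage(e))
    ok <- isTRUE(res)
    state <- recordStatus(state, id, step, ok, if (ok) "" else res)
    if (!ok) next
    if (step == "curvature") {
      dir.create(file.path(config$outputDir, "curvature"),
                 showWarnings = FALSE)
      writeCurvatureCSV(fields[[id]]$field,
                        file.path(config$outputDir, "curvature",
                                  paste0(id, ".csv")))
      if (isTRUE(config$exportPLY))
        writePLY(fields[[id]]$mesh, curvatures(fields[[id]]$field),
                 file.path(config$outputDir, "curvature",
                           paste0(id, ".ply")))
    }
    if (step == "segment") {
      dir.create(file.path(config$outputDir, "regions"),
                 showWarnings = FALSE)
      writeRegionCSV(masks[[id]], id,
                     file.path(config$outputDir, "regions",
                               paste0(id, ".csv")))
    }
  }
  if (step == "features") {
    okIds <- names(masks)
    if (length(okIds) == 0L)
      stop("batch failure: no subject produced usable regions")
    subjects <- lapply(okIds, function(id)
      list(field = fields[[id]]$field, masks = masks[[id]], source = "ct"))
    names(subjects) <- okIds
    state$features <- buildFeatures(subjects)
    writeFeatureCSV(state$features,
                    file.path(config$outputDir, "features.csv"))
  }
  list(state = state, fields = fields, masks = masks)
}

featuresOrDie <- function(config, state) {
  if (!is.null(state$features)) return(state$features)
  p <- file.path(config$outputDir, "features.csv")
  if (!file.exists(p))
    stop("configuration error: no features available; run the 'features' ",
         "or 'simulate' step first (missing ", p, ")")
  utils::read.csv(p, stringsAsFactors = FALSE)
}

pipelineLabels <- function(config, state, labels) {
  if (!is.null(labels)) return(labels)
  if (!is.null(state$features$clinician_label))
    return(state$features[, c("subject_id", "clinician_label")])
  p <- file.path(config$outputDir, "labels.csv")
  if (file.exists(p)) return(readLabels(p))
  NULL
}

stepCluster <- function(config, state, labels) {
  feat <- featuresOrDie(config, state)
  res <- kmeans2(feat, featureSet = config$featureSet, seed = config$seed,
                 nRestarts = config$nRestarts,
                 standardize = config$standardize)
  state$cluster <- res
  lab <- pipelineLabels(config, state, labels)
  writeClusterCSV(res, file.path(config$outputDir, "clusters.csv"), lab)
  if (!is.null(lab)) {
    rep <- clusterAgreement(res, lab)
    state$agreement <- rep
    jsonlite::write_json(list(
      agreement_fraction = rep@agreementFraction,
      n_discordant = rep@nDiscordant,
      discordant_ids = rep@discordantIds
    ), file.path(config$outputDir, "agreement.json"),
    auto_unbox = TRUE, digits = NA)
  }
  p <- plotClusters(feat, res, lab)
  ggplot2::ggsave(file.path(config$outputDir, "clusters.png"), p,
                  width = 6, height = 5, dpi = 150)
  recordStatus(state, "(cohort)", "cluster", TRUE,
               sprintf("inertia %.2f", res@inertia))
}

stepReport <- function(config, state, labels) {
  feat <- featuresOrDie(config, state)
  lab <- pipelineLabels(config, state, labels)
  if (is.null(lab))
    stop("configuration error: the report step needs a clinician label ",
         "table (labelsFile) or simulated labels")
  s <- groupSummary(feat, lab)
  out <- s$groups
  out <- rbind(out, data.frame(group = "difference (operative-conservative)",
                               n = NA, h_mid_mean = s$differences[["h_mid"]],
                               h_mid_sd = NA,
                               h_orb_mean = s$differences[["h_orb"]],
                               h_orb_sd = NA))
  utils::write.csv(out, file.path(config$outputDir, "group_summary.csv"),
                   row.names = FALSE)
  tests <- do.call(rbind, lapply(c("h_mid", "h_orb"), function(fn) {
    w <- welchTest(feat, lab, fn)
    data.frame(feature = fn, t = w$statistic, df = w$df, p = w$p.value)
  }))
  utils::write.csv(tests, file.path(config$outputDir, "welch_tests.csv"),
                   row.names = FALSE)
  state$summary <- s
  recordStatus(state, "(cohort)", "report", TRUE,
               sprintf("h_mid diff %.2f, h_orb diff %.2f",
                       s$differences[["h_mid"]], s$differences[["h_orb"]]))
}
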