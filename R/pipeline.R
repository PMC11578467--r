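## Pipeline orchestration: a plain-list config with full defaulting
## (every study constant — alpha, classifier settings, smoothing window,
## section policy — is config, so sensitivity analyses need no code
## change), plus the three stages: simulate a cohort to disk, extract
## measures, and build the statistics + importance report. Outputs carry
## a run manifest (config snapshot, input digests, drop counts, package
## version); nothing time-stamped, so identical config + seeds give
## byte-identical outputs.

#' Pipeline configuration with defaults
#'
#' @param ... overrides for: \code{section} ("SI+SII", "SI", "SII"),
#'   \code{mode} ("2d"/"3d"), \code{smoothingWindow} (display smoothing,
#'   default 5), \code{alpha} (significance level, default 0.05),
#'   \code{numTrees} (200), \code{minSplit} (5), \code{minLeaf} (2),
#'   \code{nSeeds} (importance refit seeds, 20), \code{seed} (1),
#'   \code{noiseSd}, \code{invalidFraction} (0.026), \code{nFrames}
#'   (150), \code{landmarkMap} (path to a JSON map, or NULL for the
#'   default).
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(section = "SI+SII", mode = "2d", smoothingWindow = 5L,
              alpha = 0.05, numTrees = 200L, minSplit = 5L, minLeaf = 2L,
              nSeeds = 20L, seed = 1L, noiseSd = 0.0025,
              invalidFraction = 0.026, nFrames = 150L,
              landmarkMap = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$section %in% c("SI", "SII", "SI+SII"),
            cfg$mode %in% c("2d", "3d"),
            cfg$alpha > 0, cfg$alpha < 1)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file whose keys override
#'   \code{\link{pipelineConfig}} defaults.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.configMap <- function(config) {
  if (is.null(config$landmarkMap)) defaultLandmarkMap()
  else readLandmarkMap(config$landmarkMap)
}

.writeJSONReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

.manifest <- function(config, inputs = character(0), counts = list()) {
  digests <- if (length(inputs))
    vapply(inputs, function(p) as.character(tools::md5sum(p)),
           character(1))
  else NULL
  list(package = "TasteFace",
       version = as.character(utils::packageVersion("TasteFace")),
       config = unclass(config),
       input_digests = as.list(digests),
       counts = counts)
}

#' Simulate a cohort dataset to disk
#'
#' Writes one landmark-stream CSV per video, the session-metadata table,
#' the generator ground truth (JSON) and a run manifest.
#'
#' @param outDir output directory (must be empty unless
#'   \code{force = TRUE}).
#' @param nSubjects number of subjects (>= 1).
#' @param seed master seed.
#' @param config a \code{PipelineConfig}.
#' @param effects,hedonic generator settings (defaults as in
#'   \code{\link{generateCohort}}).
#' @param force overwrite a non-empty directory.
#' @return invisibly, the output directory.
#' @export
runSimulate <- function(outDir, nSubjects = 64L, seed = 1L,
                        config = pipelineConfig(),
                        effects = defaultTasteEffects(),
                        hedonic = hedonicModel(), force = FALSE) {
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  if (dir.exists(outDir) && length(dir(outDir)) && !force)
    stop("output directory ", outDir,
         " is not empty (use force = TRUE to overwrite)")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  map <- .configMap(config)
  cohort <- generateCohort(
    nSubjects = nSubjects, hedonic = hedonic, effects = effects,
    seed = seed, nFrames = config$nFrames, map = map,
    noiseSd = config$noiseSd, invalidFraction = config$invalidFraction)
  streamDir <- file.path(outDir, "streams")
  dir.create(streamDir, showWarnings = FALSE)
  for (vid in names(cohort$streams))
    writeLandmarkStream(cohort$streams[[vid]],
                        file.path(streamDir, paste0(vid, ".csv")))
  writeSessionTable(cohort$records, file.path(outDir, "sessions.csv"))
  .writeJSONReport(cohort$truth, file.path(outDir, "truth.json"))
  nDrop <- sum(vapply(cohort$truth$videos,
                      function(v) length(v$droppedFrames), integer(1)))
  .writeJSONReport(
    .manifest(config,
              counts = list(subjects = nSubjects,
                            videos = length(cohort$streams),
                            frames = length(cohort$streams) *
                              config$nFrames,
                            invalid_frames = nDrop)),
    file.path(outDir, "manifest.json"))
  invisible(outDir)
}

#' Extract measure series from a simulated or ingested dataset
#'
#' Reads every video listed in the dataset's session table, computes the
#' twelve-measure series for the configured section, and writes one tidy
#' measures CSV plus a drop report in the manifest.
#'
#' @param datasetDir directory produced by \code{\link{runSimulate}} (or
#'   matching its layout: \code{sessions.csv} + \code{streams/<video_id>.csv}).
#' @param outFile output CSV (default \code{measures.csv} inside
#'   \code{datasetDir}).
#' @param config a \code{PipelineConfig}.
#' @return invisibly, the tidy measures data.frame (attribute
#'   \code{"dropped_videos"} lists videos with no retained frames).
#' @export
runExtract <- function(datasetDir,
                       outFile = file.path(datasetDir, "measures.csv"),
                       config = pipelineConfig()) {
  records <- readSessionTable(file.path(datasetDir, "sessions.csv"))
  map <- .configMap(config)
  vids <- records$video_id[!is.na(records$video_id)]
  seriesList <- list()
  droppedVideos <- character(0)
  nDegenerate <- 0L
  for (vid in vids) {
    path <- file.path(datasetDir, "streams", paste0(vid, ".csv"))
    if (!file.exists(path))
      .streamError(paste0("stream file missing for video ", vid),
                   "ioError")
    stream <- readLandmarkStream(path)
    series <- suppressWarnings(
      computeMeasureSeries(stream, map, config$section, config$mode))
    nDegenerate <- nDegenerate + series@nDropped
    if (length(series) == 0L) droppedVideos <- c(droppedVideos, vid)
    else seriesList[[vid]] <- series
  }
  if (!length(seriesList))
    stop("no video yielded any retained frames")
  writeMeasuresCSV(seriesList, outFile)
  .writeJSONReport(
    .manifest(config, inputs = file.path(datasetDir, "sessions.csv"),
              counts = list(videos_in = length(vids),
                            videos_out = length(seriesList),
                            dropped_videos = as.list(droppedVideos),
                            degenerate_frames = nDegenerate)),
    file.path(dirname(outFile), "extract_manifest.json"))
  out <- do.call(rbind, lapply(seriesList, as.data.frame))
  rownames(out) <- NULL
  attr(out, "dropped_videos") <- droppedVideos
  invisible(out)
}

.pivotMeasures <- function(measuresTab) {
  ## long -> per-video SD summary rows
  sp <- split(measuresTab, measuresTab$video_id)
  rows <- lapply(sp, function(d) {
    out <- data.frame(video_id = d$video_id[1],
                      section = d$section[1],
                      n_frames = length(unique(d$frame_index)),
                      stringsAsFactors = FALSE)
    for (mn in measureNames()) {
      v <- d$value[d$measure == mn]
      out[[mn]] <- if (length(v) > 1L) stats::sd(v) else 0
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the statistics and importance report
#'
#' Joins the tidy measures CSV with the session table and writes the
#' full analysis battery: cohort demographics and completeness tables,
#' Kruskal-Wallis tests of the hedonic ratings (by taste, and by
#' sex/age/order within each taste), per-measure one-way ANOVAs of the
#' video-level SDs by taste and by hedonic score, box-plot-ready grouped
#' distributions, trees + PCA importance rankings with their agreement,
#' and a run manifest. Identical inputs, config and seed give
#' byte-identical outputs.
#'
#' @param measuresFile tidy measures CSV from \code{\link{runExtract}}.
#' @param sessionFile session-metadata CSV.
#' @param outDir report output directory (created if needed).
#' @param config a \code{PipelineConfig}.
#' @return invisibly, a list with the in-memory report components.
#' @export
runReport <- function(measuresFile, sessionFile, outDir,
                      config = pipelineConfig()) {
  measuresTab <- readMeasuresCSV(measuresFile)
  records <- readSessionTable(sessionFile)
  known <- records$video_id[!is.na(records$video_id)]
  orphans <- setdiff(unique(measuresTab$video_id), known)
  if (length(orphans))
    .streamError(paste0("measure rows with video ids absent from the ",
                        "session table: ",
                        paste(orphans, collapse = ", ")),
                 "validationError")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  summaries <- .pivotMeasures(measuresTab)
  meta <- records[match(summaries$video_id, records$video_id),
                  c("subject_id", "taste", "hedonic_score")]
  summaries <- cbind(summaries, meta)
  summaries$taste <- as.character(summaries$taste)

  tables <- cohortTables(records)
  kwRows <- list()
  addKW <- function(test, taste) {
    data.frame(factor = test$factor,
               taste = if (is.null(taste)) "all" else taste,
               statistic = test$statistic, df = test$df,
               p_value = test$p_value,
               significant = test$p_value < config$alpha,
               stringsAsFactors = FALSE)
  }
  kwRows[[1]] <- addKW(kruskalWallis(records, "taste"), NULL)
  for (t in tasteLevels())
    for (f in c("sex", "age", "order_sequence")) {
      test <- tryCatch(kruskalWallis(records, f, taste = t),
                       error = function(e) NULL)
      if (!is.null(test))
        kwRows[[length(kwRows) + 1L]] <- addKW(test, t)
    }
  kwTab <- do.call(rbind, kwRows)

  anovaTaste <- anovaMeasures(summaries, "taste")
  anovaScore <- tryCatch(anovaMeasures(summaries, "hedonic_score"),
                         error = function(e) NULL)
  groupedTaste <- groupedDistributions(summaries, "taste")
  groupedScore <- groupedDistributions(summaries, "hedonic_score")

  fm <- buildFeatures(summaries)
  hyper <- list(numTrees = config$numTrees, minSplit = config$minSplit,
                minLeaf = config$minLeaf)
  trees <- rankImportanceTrees(fm, "taste", nSeeds = config$nSeeds,
                               seed = config$seed, hyper = hyper)
  pca <- rankImportancePCA(fm)
  agree <- compareRankings(trees, pca, k = 3L)
  impTab <- rbind(
    data.frame(method = "trees", rank = seq_along(trees@measure),
               measure = trees@measure, weight = trees@weight),
    data.frame(method = "pca", rank = seq_along(pca@measure),
               measure = pca@measure, weight = pca@weight))

  w <- function(x, f) utils::write.csv(x, file.path(outDir, f),
                                       row.names = FALSE)
  w(tables$age_table, "demographics_age.csv")
  w(tables$completeness, "completeness.csv")
  w(kwTab, "hedonic_kruskal_wallis.csv")
  w(anovaTaste, "anova_by_taste.csv")
  if (!is.null(anovaScore)) w(anovaScore, "anova_by_score.csv")
  w(groupedTaste, "grouped_sd_by_taste.csv")
  w(groupedScore, "grouped_sd_by_score.csv")
  w(impTab, "importance.csv")
  w(summaries, "video_summaries.csv")

  report <- list(
    demographics = list(age_median = tables$age_median,
                        age_sd = tables$age_sd,
                        n_subjects = sum(tables$age_table$n),
                        sex = as.list(tables$sex_table)),
    completeness = tables$completeness,
    n_tests_run = nrow(kwTab) + nrow(anovaTaste) +
      if (is.null(anovaScore)) 0L else nrow(anovaScore),
    alpha = config$alpha,
    taste_test = kwRows[[1]],
    importance_agreement = agree,
    top_measure_trees = trees@measure[1],
    top_measure_pca = pca@measure[1])
  .writeJSONReport(report, file.path(outDir, "report.json"))
  .writeJSONReport(
    .manifest(config, inputs = c(measuresFile, sessionFile),
              counts = list(videos = nrow(summaries),
                            feature_rows = nrow(features(fm)),
                            dropped_feature_rows = fm@nDropped)),
    file.path(outDir, "manifest.json"))
  invisible(list(summaries = summaries, kruskal_wallis = kwTab,
                 anova_taste = anovaTaste, anova_score = anovaScore,
                 grouped_taste = groupedTaste,
                 grouped_score = groupedScore, trees = trees, pca = pca,
                 agreement = agree, tables = tables))
}

#' Run simulate, extract and report end to end
#'
#' @param outDir working directory for the dataset and report.
#' @param nSubjects,seed,config as in the stage functions.
#' @param ... passed to \code{\link{runSimulate}}.
#' @return invisibly, the report list from \code{\link{runReport}}.
#' @export
runPipeline <- function(outDir, nSubjects = 64L, seed = 1L,
                        config = pipelineConfig(), ...) {
  dataDir <- file.path(outDir, "dataset")
  runSimulate(dataDir, nSubjects, seed, config, ...)
  runExtract(dataDir, config = config)
  runReport(file.path(dataDir, "measures.csv"),
            file.path(dataDir, "sessions.csv"),
            file.path(outDir, "report"), config)
}
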