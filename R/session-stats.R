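## Per-video variability summaries and the cohort-level group statistics:
## Kruskal-Wallis on hedonic ratings, per-measure one-way ANOVA of the
## video-level SDs, box-plot-ready grouped quantiles, and the cohort
## bookkeeping tables.

#' Summarise a video's measure variability
#'
#' Computes the sample standard deviation (n - 1 denominator) of each of
#' the twelve measures over the retained frames, the per-video feature
#' used by all group statistics and by the classifier.
#'
#' @param series a non-empty \linkS4class{MeasureSeries}.
#' @param record optional one-row session record (data.frame or list)
#'   supplying subject_id, taste and hedonic_score.
#' @return one-row data.frame: video_id, subject_id, taste,
#'   hedonic_score, section, n_frames, n_dropped, then one SD column per
#'   measure name.
#' @export
summariseVideo <- function(series, record = NULL) {
  n <- length(series@frameIndex)
  if (n == 0L)
    stop("cannot summarise an empty measure series (video ",
         series@videoId, ")")
  if (n == 1L) {
    warning("video ", series@videoId,
            " has a single retained frame; SDs reported as 0")
    sds <- stats::setNames(rep(0, 12), measureNames())
  } else {
    sds <- apply(series@measures, 2, stats::sd)
  }
  out <- data.frame(
    video_id = series@videoId,
    subject_id = if (!is.null(record)) as.character(record$subject_id)
                 else NA_character_,
    taste = if (!is.null(record)) as.character(record$taste)
            else NA_character_,
    hedonic_score = if (!is.null(record)) as.integer(record$hedonic_score)
                    else NA_integer_,
    section = series@section,
    n_frames = n,
    n_dropped = series@nDropped,
    stringsAsFactors = FALSE)
  out[measureNames()] <- as.list(sds)
  out
}

#' Summarise every video of a cohort
#'
#' Maps \code{\link{computeMeasureSeries}} + \code{\link{summariseVideo}}
#' over a list of streams, joining each to its session record by video
#' id. Videos with no retained frames are dropped and counted.
#'
#' @param streams list of \linkS4class{LandmarkStream}.
#' @param records validated session data.frame.
#' @param map a \linkS4class{LandmarkMap}.
#' @param section,mode passed to \code{\link{computeMeasureSeries}}.
#' @return data.frame of video summaries with attribute
#'   \code{"n_dropped_videos"}.
#' @export
summariseCohort <- function(streams, records, map = defaultLandmarkMap(),
                            section = "SI+SII", mode = "2d") {
  rows <- list()
  dropped <- 0L
  for (st in streams) {
    series <- suppressWarnings(
      computeMeasureSeries(st, map, section, mode))
    if (length(series) == 0L) {
      dropped <- dropped + 1L
      next
    }
    rec <- records[!is.na(records$video_id) &
                     records$video_id == videoId(st), , drop = FALSE]
    rows[[length(rows) + 1L]] <-
      summariseVideo(series, if (nrow(rec)) rec[1, ] else NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "n_dropped_videos") <- dropped
  out
}

.groupTest <- function(factorName, statistic, df, p, sizes, method) {
  structure(list(factor = factorName, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p),
                 group_sizes = sizes, method = method),
            class = "groupTest")
}

#' @export
print.groupTest <- function(x, ...) {
  cat(x$method, "on", x$factor, "|",
      sprintf("statistic = %.4g, df = %s, p = %.4g",
              x$statistic, paste(x$df, collapse = "/"), x$p_value), "\n")
  cat("  group sizes:", paste(sprintf("%s=%d", names(x$group_sizes),
                                      x$group_sizes), collapse = " "), "\n")
  invisible(x)
}

#' Kruskal-Wallis test of hedonic ratings across groups
#'
#' Rank-based H test (with tie correction, chi-square reference on k - 1
#' degrees of freedom) of the hedonic scores across the levels of a
#' design factor: sex, age, strip-order sequence or taste.
#'
#' @param records validated session data.frame (one hedonic score per
#'   row; rows with missing scores are ignored).
#' @param factor one of "sex", "age", "order_sequence", "taste".
#' @param taste optional taste level to restrict the records to (the
#'   per-strip analyses by sex/age/order are run within each taste).
#' @return A \code{groupTest} with H statistic, df = k - 1, p-value and
#'   group sizes. Empty groups are excluded with a warning; fewer than 2
#'   remaining groups is an error.
#' @export
kruskalWallis <- function(records,
                          factor = c("taste", "sex", "age",
                                     "order_sequence"),
                          taste = NULL) {
  factor <- match.arg(factor)
  if (!is.null(taste))
    records <- records[records$taste == taste, , drop = FALSE]
  records <- records[!is.na(records$hedonic_score), , drop = FALSE]
  g <- droplevels(base::factor(records[[factor]]))
  sizes <- table(g)
  if (any(sizes == 0L)) {
    warning("excluding empty group(s): ",
            paste(names(sizes)[sizes == 0L], collapse = ", "))
    g <- droplevels(g)
    sizes <- table(g)
  }
  if (nlevels(g) < 2L)
    stop("Kruskal-Wallis needs at least 2 non-empty groups for factor ",
         factor)
  kt <- stats::kruskal.test(records$hedonic_score, g)
  .groupTest(factor, kt$statistic, kt$parameter, kt$p.value,
             as.integer(sizes) |> stats::setNames(names(sizes)),
             "Kruskal-Wallis")
}

#' One-way ANOVA of per-video measure SDs across groups
#'
#' For each of the twelve measures, a one-way ANOVA of the per-video
#' standard deviations across the levels of taste or hedonic score.
#'
#' @param summaries video-summary data.frame from
#'   \code{\link{summariseCohort}}.
#' @param factor "taste" or "hedonic_score".
#' @return data.frame, one row per measure: measure, statistic (F), df1,
#'   df2, p_value. A measure with zero within-group variance everywhere
#'   but group differences is reported with statistic = Inf, p_value = 0.
#' @export
anovaMeasures <- function(summaries, factor = c("taste", "hedonic_score")) {
  factor <- match.arg(factor)
  g <- droplevels(base::factor(summaries[[factor]]))
  sizes <- table(g)
  if (nlevels(g) < 2L || any(sizes < 2L))
    stop("ANOVA needs >= 2 groups with >= 2 video summaries each")
  rows <- lapply(measureNames(), function(mn) {
    y <- summaries[[mn]]
    ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    if (ssw < .Machine$double.eps) {
      ssb <- sum(tapply(y, g, length) *
                   (tapply(y, g, mean) - mean(y))^2)
      if (ssb < .Machine$double.eps)  # all values identical
        return(data.frame(measure = mn, statistic = NA_real_,
                          df1 = nlevels(g) - 1L,
                          df2 = length(y) - nlevels(g),
                          p_value = NA_real_))
      return(data.frame(measure = mn, statistic = Inf,
                        df1 = nlevels(g) - 1L,
                        df2 = length(y) - nlevels(g), p_value = 0))
    }
    fit <- stats::aov(y ~ g)
    s <- summary(fit)[[1]]
    data.frame(measure = mn, statistic = s[["F value"]][1],
               df1 = s[["Df"]][1], df2 = s[["Df"]][2],
               p_value = s[["Pr(>F)"]][1])
  })
  out <- do.call(rbind, rows)
  attr(out, "group_sizes") <- sizes
  out
}

#' Box-plot-ready grouped distributions of measure SDs
#'
#' Per group and measure: n, median, quartiles (type-7 linear
#' interpolation) and whisker bounds under the 1.5 IQR rule (most extreme
#' data points inside the fences).
#'
#' @param summaries video-summary data.frame.
#' @param by "taste" or "hedonic_score".
#' @return tidy data.frame: group, measure, n, median, q1, q3,
#'   whisker_low, whisker_high.
#' @export
groupedDistributions <- function(summaries,
                                 by = c("taste", "hedonic_score")) {
  by <- match.arg(by)
  g <- droplevels(base::factor(summaries[[by]]))
  rows <- list()
  for (lev in levels(g)) {
    for (mn in measureNames()) {
      v <- summaries[[mn]][g == lev]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3] - q[1]
      lowFence <- q[1] - 1.5 * iqr
      highFence <- q[3] + 1.5 * iqr
      rows[[length(rows) + 1L]] <- data.frame(
        group = lev, measure = mn, n = length(v),
        median = q[2], q1 = q[1], q3 = q[3],
        whisker_low = min(v[v >= lowFence]),
        whisker_high = max(v[v <= highFence]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Cohort demographics and completeness tables
#'
#' Reproduces the cohort bookkeeping: an age-frequency table with
#' percentages plus the cohort's median and sample SD of age, a sex
#' count, and a per-taste completeness table counting hedonic ratings and
#' analysable videos, with totals.
#'
#' @param records validated session data.frame (one row per subject and
#'   taste; demographics are taken once per subject).
#' @return list with elements \code{age_table} (age, n, percent),
#'   \code{age_median}, \code{age_sd}, \code{sex_table}, and
#'   \code{completeness} (taste, n_scores, n_videos, with a Total row).
#' @export
cohortTables <- function(records) {
  subj <- records[!duplicated(records$subject_id),
                  c("subject_id", "age", "sex")]
  ages <- subj$age
  ageTab <- table(ages)
  ageTable <- data.frame(
    age = as.integer(names(ageTab)),
    n = as.integer(ageTab),
    percent = round(100 * as.integer(ageTab) / length(ages)))
  completeness <- data.frame(
    taste = tasteLevels(),
    n_scores = vapply(tasteLevels(), function(t)
      sum(records$taste == t & !is.na(records$hedonic_score)), integer(1)),
    n_videos = vapply(tasteLevels(), function(t)
      sum(records$taste == t & !is.na(records$video_id)), integer(1)),
    stringsAsFactors = FALSE)
  completeness <- rbind(completeness, data.frame(
    taste = "Total", n_scores = sum(completeness$n_scores),
    n_videos = sum(completeness$n_videos)))
  list(age_table = ageTable,
       age_median = stats::median(ages),
       age_sd = if (length(ages) > 1) stats::sd(ages) else 0,
       sex_table = table(subj$sex),
       completeness = completeness)
}
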