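test_that("per-video SDs use the n-1 denominator and known closed
          forms", {
  map <- defaultLandmarkMap()
  tpl <- neutralFaceTemplate(map)
  s <- computeMeasureSeries(constantStream(tpl, 10L), map)
  sm <- summariseVideo(s, sessionRows(1L)[1, ])
  expect_true(all(as.numeric(sm[measureNames()]) == 0))
  expect_identical(sm$taste, "control")

  ## alternating a, b, ... has SD sqrt(n/(n-1)) * |a-b| / 2 for even n
  a <- 1.3; b <- 2.9; n <- 10
  fake <- new("MeasureSeries", videoId = "alt", section = "SI+SII",
              frameIndex = 0:(n - 1),
              measures = matrix(rep(c(a, b), length.out = n * 12),
                                nrow = n, ncol = 12,
                                dimnames = list(NULL, measureNames())),
              referenceDistance = rep(1, n), nDropped = 0L)
  smAlt <- summariseVideo(fake)
  expect_equal(smAlt$eyebrow_elevation_L,
               sqrt(n / (n - 1)) * abs(a - b) / 2, tolerance = 1e-9)

  ## random series vs the two-pass oracle
  set.seed(21)
  g <- generateStream(nFrames = 60L, seed = 9)
  sr <- computeMeasureSeries(g$stream, map)
  smr <- summariseVideo(sr)
  for (mn in measureNames())
    expect_equal(smr[[mn]], oSD(measures(sr)[, mn]), tolerance = 1e-9)

  single <- new("MeasureSeries", videoId = "one", section = "SI",
                frameIndex = 0L,
                measures = matrix(1, 1, 12,
                                  dimnames = list(NULL, measureNames())),
                referenceDistance = 1, nDropped = 0L)
  expect_warning(s1 <- summariseVideo(single), "single")
  expect_true(all(as.numeric(s1[measureNames()]) == 0))
})

test_that("Kruskal-Wallis matches the direct tie-corrected formula", {
  ## identical groups: H = 0, p = 1
  rec <- rbind(sessionRows(4L, "S001", scores = c(1L, 2L, 3L, 4L)),
               sessionRows(4L, "S002", scores = c(1L, 2L, 3L, 4L)))
  rec$sex <- rep(c("female", "male"), each = 4L)
  t0 <- kruskalWallis(rec, "sex")
  expect_equal(t0$statistic, 0, tolerance = 1e-12)
  expect_equal(t0$p_value, 1, tolerance = 1e-12)

  ## three small hand-made groups with ties, against the oracle
  scores <- c(1L, 2L, 2L, 3L, 5L, 4L, 4L, 2L, 1L, 3L, 5L, 5L)
  rows <- lapply(seq_along(scores), function(i) {
    r <- sessionRows(1L, sprintf("S%03d", i))
    r$hedonic_score <- scores[i]
    r$age <- c(5L, 8L, 11L)[(i - 1L) %% 3L + 1L]
    r
  })
  rec3 <- do.call(rbind, rows)
  t3 <- kruskalWallis(rec3, "age")
  o <- oKruskalWallis(scores, rec3$age)
  expect_equal(t3$statistic, o$H, tolerance = 1e-9)
  expect_equal(t3$df, o$df)
  expect_equal(t3$p_value, o$p, tolerance = 1e-9)

  expect_error(kruskalWallis(rec3[rec3$age == 5L, ], "age"),
               "at least 2")
})

test_that("taste-dependent hedonic cohorts come out significant", {
  ## sweet >> bitter scores: the taste factor should be detected in
  ## nearly every replicate
  hits <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    rows <- lapply(1:16, function(i) {
      r <- sessionRows(4L, sprintf("S%03d", i))
      r$hedonic_score <- c(sample(2:4, 1), sample(4:5, 1),
                           sample(1:5, 1), sample(1:2, 1))
      r
    })
    rec <- do.call(rbind, rows)
    if (kruskalWallis(rec, "taste")$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("one-way ANOVA agrees with t^2 and the sum-of-squares
          oracle", {
  mkSummaries <- function(values, groups) {
    out <- data.frame(video_id = sprintf("v%02d", seq_along(values)),
                      subject_id = sprintf("s%02d", seq_along(values)),
                      taste = groups, hedonic_score = 3L,
                      section = "SI+SII", n_frames = 50L, n_dropped = 0L,
                      stringsAsFactors = FALSE)
    for (mn in measureNames()) out[[mn]] <- values
    out
  }
  ## two groups: F = t^2
  set.seed(41)
  v <- c(rnorm(8, 1), rnorm(8, 1.7))
  g <- rep(c("control", "bitter"), each = 8)
  res <- anovaMeasures(mkSummaries(v, g), "taste")
  tt <- stats::t.test(v[g == "control"], v[g == "bitter"],
                      var.equal = TRUE)
  expect_equal(res$statistic[1], unname(tt$statistic)^2,
               tolerance = 1e-9)

  ## 2x3 layout vs explicit sums of squares
  v2 <- c(2.1, 2.4, 2.2, 3.0, 3.3, 2.9, 1.4, 1.9, 1.6)
  g2 <- rep(c("control", "sweet", "bitter"), each = 3)
  res2 <- anovaMeasures(mkSummaries(v2, g2), "taste")
  o <- oAnovaF(v2, g2)
  expect_equal(res2$statistic[1], o$F, tolerance = 1e-9)
  expect_equal(res2$df1[1], o$df1)
  expect_equal(res2$df2[1], o$df2)
  expect_equal(res2$p_value[1], o$p, tolerance = 1e-9)

  ## zero within-group variance with group differences -> infinite F
  v3 <- rep(c(1, 2), each = 3)
  res3 <- anovaMeasures(mkSummaries(v3, rep(c("control", "sweet"),
                                            each = 3)), "taste")
  expect_identical(res3$statistic[1], Inf)
  expect_identical(res3$p_value[1], 0)

  ## affine invariance of F
  res4 <- anovaMeasures(mkSummaries(3 * v2 + 11, g2), "taste")
  expect_equal(res4$statistic[1], res2$statistic[1], tolerance = 1e-9)
})

test_that("grouped distributions reproduce quantiles and whiskers", {
  mk <- function(values, groups) {
    out <- data.frame(video_id = sprintf("v%02d", seq_along(values)),
                      taste = groups, hedonic_score = 3L,
                      stringsAsFactors = FALSE)
    for (mn in measureNames()) out[[mn]] <- values
    out
  }
  one <- groupedDistributions(mk(2.5, "sweet"), "taste")
  expect_true(all(one$median == 2.5 & one$q1 == 2.5 & one$q3 == 2.5 &
                    one$whisker_low == 2.5 & one$whisker_high == 2.5))

  ## known five-number fixture: 1..5 plus an outlier at 100
  v <- c(1, 2, 3, 4, 5, 100)
  gd <- groupedDistributions(mk(v, "bitter"), "taste")
  r <- gd[gd$measure == "eyebrow_elevation_L", ]
  expect_equal(r$q1, stats::quantile(v, 0.25, names = FALSE))
  expect_equal(r$median, stats::quantile(v, 0.5, names = FALSE))
  expect_equal(r$q3, stats::quantile(v, 0.75, names = FALSE))
  iqr <- r$q3 - r$q1
  expect_equal(r$whisker_low, min(v[v >= r$q1 - 1.5 * iqr]))
  expect_equal(r$whisker_high, max(v[v <= r$q3 + 1.5 * iqr]))
  expect_lt(r$whisker_high, 100)  # the outlier is outside the whisker
  expect_identical(r$n, 6L)
})

test_that("cohort tables reproduce the published demographic
          arithmetic", {
  ## expand the published age-frequency table into 64 subjects
  counts <- studyAgeCounts()
  ages <- rep(as.integer(names(counts)), counts)
  rows <- lapply(seq_along(ages), function(i) {
    r <- sessionRows(4L, sprintf("S%03d", i))
    r$age <- ages[i]
    r
  })
  rec <- do.call(rbind, rows)
  tab <- cohortTables(rec)
  expect_equal(tab$age_median, 8.5)
  expect_equal(round(tab$age_sd, 2), 1.46)
  expect_identical(tab$age_table$n, unname(counts))
  expect_identical(tab$completeness$n_scores,
                   c(64L, 64L, 64L, 64L, 256L))

  ## single-subject cohort
  tab1 <- cohortTables(sessionRows(4L))
  expect_identical(tab1$age_median, 8L)
  expect_identical(tab1$age_sd, 0)
})

test_that("SD summaries are frame-order invariant and the H statistic is
          monotone invariant", {
  set.seed(61)
  map <- defaultLandmarkMap()
  g <- generateStream(nFrames = 40L, seed = 3)
  s <- computeMeasureSeries(g$stream, map)
  perm <- sample(length(s))
  shuffled <- new("MeasureSeries", videoId = s@videoId,
                  section = s@section,
                  frameIndex = s@frameIndex[perm],
                  measures = measures(s)[perm, ],
                  referenceDistance = s@referenceDistance[perm],
                  nDropped = 0L)
  expect_equal(as.numeric(summariseVideo(s)[measureNames()]),
               as.numeric(summariseVideo(shuffled)[measureNames()]),
               tolerance = 1e-12)

  scores <- c(1L, 3L, 2L, 5L, 4L, 2L, 1L, 5L)
  rows <- lapply(seq_along(scores), function(i) {
    r <- sessionRows(1L, sprintf("S%03d", i))
    r$hedonic_score <- scores[i]
    r$sex <- c("female", "male")[(i %% 2) + 1]
    r
  })
  rec <- do.call(rbind, rows)
  h1 <- kruskalWallis(rec, "sex")$statistic
  rec2 <- rec
  rec2$hedonic_score <- as.integer(rec$hedonic_score^2 - 3)
  ## strictly monotone transform of the outcome leaves H unchanged,
  ## though the transformed scores are no longer on the 1..5 scale
  g2 <- factor(rec2$sex)
  expect_equal(unname(stats::kruskal.test(rec2$hedonic_score,
                                          g2)$statistic),
               unname(h1), tolerance = 1e-12)
})
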