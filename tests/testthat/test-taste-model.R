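## deterministic labelled feature fixture: 12 noise features, with an
## optional class shift added to chosen columns
featureFixture <- function(n = 48L, shiftCols = character(0),
                           shift = 1, seed = 1L) {
  set.seed(seed)
  taste <- rep(tasteLevels(), length.out = n)
  m <- matrix(rnorm(n * 12, 1, 0.3), n, 12,
              dimnames = list(NULL, measureNames()))
  for (col in shiftCols)
    m[, col] <- m[, col] + shift * as.integer(factor(taste))
  out <- data.frame(video_id = sprintf("v%03d", seq_len(n)),
                    subject_id = sprintf("s%03d",
                                         rep(seq_len(ceiling(n / 4)),
                                             each = 4L,
                                             length.out = n)),
                    taste = taste,
                    hedonic_score = sample(1:5, n, replace = TRUE),
                    section = "SI+SII", n_frames = 50L, n_dropped = 0L,
                    stringsAsFactors = FALSE)
  out[measureNames()] <- as.data.frame(m)
  out
}

test_that("buildFeatures keeps the canonical column order and drops
          incomplete rows", {
  sm <- featureFixture(4L)
  fm <- buildFeatures(sm)
  expect_identical(dim(features(fm)), c(4L, 12L))
  expect_identical(colnames(features(fm)), measureNames())

  smNA <- featureFixture(6L)
  smNA$eyebrow_tilt_R[3] <- NA
  fm2 <- buildFeatures(smNA)
  expect_identical(nrow(features(fm2)), 5L)
  expect_identical(fm2@nDropped, 1L)

  smAll <- featureFixture(3L)
  smAll$mouth_corner_L <- NA
  expect_error(buildFeatures(smAll), "all rows dropped")
})

test_that("trees importance finds a planted signal and sums to one", {
  fm <- buildFeatures(featureFixture(64L, "eyebrow_elevation_R",
                                     shift = 1.5, seed = 2L))
  r <- rankImportanceTrees(fm, "taste", nSeeds = 5L, seed = 1L)
  expect_identical(r@measure[1], "eyebrow_elevation_R")
  expect_equal(sum(r@weight), 1, tolerance = 1e-9)
  expect_true(all(r@weight >= 0))
  expect_true(all(abs(rowSums(r@perSeed) - 1) < 1e-9))

  ## bit-for-bit reproducible given the seed list
  r2 <- rankImportanceTrees(fm, "taste", nSeeds = 5L, seed = 1L)
  expect_identical(r@weight, r2@weight)
  expect_identical(r@measure, r2@measure)

  expect_error(rankImportanceTrees(
    buildFeatures(featureFixture(12L)[1:3, ]), "taste"), ">= 10")
})

test_that("label permutation spreads trees importance thin", {
  sm <- featureFixture(64L, "eyebrow_elevation_R", shift = 1.5,
                       seed = 3L)
  set.seed(33)
  sm$taste <- sample(sm$taste)
  fm <- buildFeatures(sm)
  r <- rankImportanceTrees(fm, "taste", nSeeds = 10L, seed = 1L)
  ## with no real signal the mean top importance stays near uniform
  expect_lte(max(r@weight), 2 / 12)
})

test_that("duplicating a signal column splits its importance", {
  sm <- featureFixture(64L, "eyebrow_elevation_R", shift = 1.5,
                       seed = 4L)
  ## all features as split candidates: with feature subsampling the two
  ## copies would be drawn more often in total than the single column,
  ## inflating their combined share
  hyperAll <- list(numTrees = 200L, minSplit = 5L, minLeaf = 2L,
                   mtry = 12L)
  single <- rankImportanceTrees(buildFeatures(sm), "taste",
                                nSeeds = 10L, seed = 1L,
                                hyper = hyperAll)
  wSingle <- importanceWeights(single)["eyebrow_elevation_R"]
  smDup <- sm
  smDup$eyebrow_elevation_L <- smDup$eyebrow_elevation_R
  dup <- rankImportanceTrees(buildFeatures(smDup), "taste",
                             nSeeds = 10L, seed = 1L, hyper = hyperAll)
  wDup <- importanceWeights(dup)
  expect_equal(unname(wDup["eyebrow_elevation_L"] +
                        wDup["eyebrow_elevation_R"]),
               unname(wSingle), tolerance = 0.05)
})

test_that("PCA ranking is deterministic, order invariant and finds a
          dominant column", {
  sm <- featureFixture(60L, seed = 5L)
  sm$mouth_corner_L <- sm$mouth_corner_L +
    3 * rep(c(0, 1), length.out = 60L)  # dominant shared variance axis
  sm$mouth_corner_R <- sm$mouth_corner_R +
    3 * rep(c(0, 1), length.out = 60L)
  fm <- buildFeatures(sm)
  r <- rankImportancePCA(fm)
  expect_true(all(c("mouth_corner_L", "mouth_corner_R") %in%
                    r@measure[1:2]))
  expect_identical(r@weight, rankImportancePCA(fm)@weight)

  ## affine rescaling of the inputs, which standardisation must cancel
  smAff <- sm
  for (i in seq_along(measureNames()))
    smAff[[measureNames()[i]]] <- 2^i * sm[[measureNames()[i]]] + i
  rAff <- rankImportancePCA(buildFeatures(smAff))
  expect_identical(rAff@measure, r@measure)
  expect_equal(rAff@weight, r@weight, tolerance = 1e-9)
})

test_that("PCA loadings match the eigen-decomposition oracle", {
  fm <- buildFeatures(featureFixture(40L, seed = 6L))
  x <- scale(features(fm))
  ev <- eigen(stats::cov(x))
  keep <- ev$values > mean(ev$values)
  evr <- ev$values / sum(ev$values)
  w <- as.numeric(ev$vectors[, keep, drop = FALSE]^2 %*% evr[keep])
  names(w) <- colnames(x)
  r <- rankImportancePCA(fm)
  expect_equal(importanceWeights(r)[names(sort(-w))],
               w[names(sort(-w))], tolerance = 1e-9)
})

test_that("PCA weights stay near-uniform on isotropic features", {
  ratios <- vapply(1:20, function(seed) {
    fm <- buildFeatures(featureFixture(200L, seed = 100L + seed))
    w <- importanceWeights(rankImportancePCA(fm))
    max(w) / min(w)
  }, numeric(1))
  expect_lte(stats::median(ratios), 2)
})

test_that("ranking agreement metrics behave at the extremes and match
          the rank-correlation oracle", {
  fm <- buildFeatures(featureFixture(40L, seed = 7L))
  r <- rankImportancePCA(fm)
  same <- compareRankings(r, r, 3L)
  expect_equal(same$top_overlap, 1)
  expect_equal(same$rank_correlation, 1)

  rev <- new("ImportanceRanking", measure = rev(r@measure),
             weight = sort(r@weight, decreasing = TRUE),
             method = "pca")
  opp <- compareRankings(r, rev, 3L)
  expect_equal(opp$top_overlap, 0)
  expect_equal(opp$rank_correlation, -1)

  set.seed(71)
  for (i in 1:5) {
    shuffled <- sample(r@measure)
    b <- new("ImportanceRanking", measure = shuffled,
             weight = sort(runif(12), decreasing = TRUE),
             method = "pca")
    got <- compareRankings(r, b, 4L)
    expect_equal(got$rank_correlation,
                 stats::cor(seq_len(12), match(r@measure, shuffled),
                            method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("subject-grouped cross-validation separates classes and
          respects grouping", {
  ## a single perfectly separating feature
  sm <- featureFixture(48L, "lip_elevation_lower", shift = 50,
                       seed = 8L)
  fm <- buildFeatures(sm)
  cv <- classifyCV(fm, "taste", folds = 4L, seed = 1L,
                   hyper = list(numTrees = 200L, minSplit = 5L,
                                minLeaf = 2L, mtry = 12L))
  expect_equal(cv$accuracy, 1)
  expect_identical(sum(cv$confusion), 48L)

  ## permuted labels: accuracy near chance
  smNull <- featureFixture(48L, seed = 9L)
  set.seed(91)
  smNull$taste <- sample(smNull$taste)
  cvNull <- classifyCV(buildFeatures(smNull), "taste", folds = 4L,
                       seed = 1L)
  expect_lt(abs(cvNull$accuracy - 0.25), 0.15)

  expect_error(classifyCV(buildFeatures(featureFixture(12L)), "taste",
                          folds = 10L), "fewer subjects")
})
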