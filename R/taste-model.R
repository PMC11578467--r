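## Measure-importance ranking and taste/score classification from the
## per-video measure-SD features. The ensemble is an extremely-randomised
## trees classifier (one random cut-point per candidate feature, no
## bootstrap) with 200 trees, sqrt(p) candidate features per split, a
## minimum of 5 samples to split an internal node and 2 per leaf;
## importances are normalised impurity decreases averaged over several
## refit seeds because single-seed tree importances are unstable at a few
## hundred rows.

#' Assemble the video-level feature matrix
#'
#' @param summaries video-summary data.frame from
#'   \code{\link{summariseCohort}} (or row-bound
#'   \code{\link{summariseVideo}} outputs).
#' @return A \linkS4class{FeatureMatrix}; rows with any undefined SD are
#'   dropped and counted in \code{nDropped}. All rows dropped is an
#'   error.
#' @export
buildFeatures <- function(summaries) {
  if (is.null(summaries) || nrow(summaries) == 0L)
    stop("no video summaries to build features from")
  m <- as.matrix(summaries[, measureNames(), drop = FALSE])
  colnames(m) <- measureNames()
  keep <- apply(is.finite(m), 1, all)
  if (!any(keep))
    stop("all rows dropped: no video has a complete set of measure SDs")
  new("FeatureMatrix",
      features = m[keep, , drop = FALSE],
      videoId = as.character(summaries$video_id[keep]),
      subjectId = as.character(summaries$subject_id[keep]),
      taste = factor(as.character(summaries$taste[keep]),
                     levels = tasteLevels()),
      score = as.integer(summaries$hedonic_score[keep]),
      nDropped = as.integer(sum(!keep)))
}

.labelVector <- function(fm, label = c("taste", "score")) {
  label <- match.arg(label)
  y <- if (label == "taste") droplevels(fm@taste)
       else factor(fm@score)
  keep <- !is.na(y)
  list(y = droplevels(y[keep]), x = fm@features[keep, , drop = FALSE],
       subject = fm@subjectId[keep])
}

.extraTrees <- function(x, y, hyper, seed) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = hyper$numTrees,
    mtry = if (is.null(hyper$mtry)) max(1L, floor(sqrt(ncol(x))))
           else hyper$mtry,
    min.node.size = hyper$minSplit,
    min.bucket = hyper$minLeaf,
    splitrule = "extratrees", num.random.splits = 1L,
    replace = FALSE, sample.fraction = 1,
    importance = "impurity",
    num.threads = 1L, seed = seed)
}

.defaultHyper <- function() list(numTrees = 200L, minSplit = 5L,
                                 minLeaf = 2L)

#' Rank measure importance with an extremely-randomised trees ensemble
#'
#' Fits the ensemble once per seed, normalises each fit's impurity-based
#' importances to sum to one, and averages across seeds. The ranking is
#' deterministic given the seed list; ties break by canonical measure
#' order.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param label "taste" or "score".
#' @param nSeeds number of refit seeds (default 20).
#' @param seed first seed; seeds used are \code{seed + 0:(nSeeds-1)}.
#' @param hyper list with numTrees, minSplit, minLeaf (defaults 200, 5,
#'   2) and optionally mtry (candidate features per split; default
#'   sqrt(p)).
#' @return An \linkS4class{ImportanceRanking} (method "trees") whose
#'   \code{perSeed} slot holds the per-seed normalised importances.
#' @export
rankImportanceTrees <- function(fm, label = c("taste", "score"),
                                nSeeds = 20L, seed = 1L,
                                hyper = .defaultHyper()) {
  lv <- .labelVector(fm, label)
  if (nlevels(lv$y) < 2L)
    stop("importance ranking needs >= 2 classes in label '",
         match.arg(label), "'")
  if (nrow(lv$x) < 10L)
    stop("importance ranking needs >= 10 videos")
  seeds <- as.integer(seed + seq_len(nSeeds) - 1L)
  perSeed <- matrix(NA_real_, nSeeds, ncol(lv$x),
                    dimnames = list(NULL, colnames(lv$x)))
  for (i in seq_len(nSeeds)) {
    fit <- .extraTrees(lv$x, lv$y, hyper, seeds[i])
    imp <- fit$variable.importance[colnames(lv$x)]
    perSeed[i, ] <- imp / sum(imp)
  }
  w <- colMeans(perSeed)
  ord <- order(-w, seq_along(w))  # ties break by canonical column order
  new("ImportanceRanking", measure = colnames(lv$x)[ord],
      weight = unname(w[ord]), method = "trees", seeds = seeds,
      perSeed = perSeed)
}

#' Rank measure importance by principal-component loadings
#'
#' Standardises the features, runs PCA, and scores each measure by the
#' sum of its squared loadings on the leading components (those with
#' above-average eigenvalue, the Kaiser rule), each weighted by the
#' component's explained-variance share. On standardised data every
#' column carries unit variance, so what distinguishes an important
#' measure is participation in the dominant correlated variance axes;
#' restricting to the leading components is what gives the score its
#' discrimination (over all components the evr-weighted squared-loading
#' sum is identically 1/p for every column). Deterministic (squared
#' loadings make component signs irrelevant); zero-variance columns are
#' excluded with a warning and ranked last with weight 0.
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @return An \linkS4class{ImportanceRanking} (method "pca").
#' @export
rankImportancePCA <- function(fm) {
  x <- fm@features
  v <- apply(x, 2, stats::var)
  drop <- v < .Machine$double.eps
  if (any(drop))
    warning("excluding zero-variance column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  xs <- x[, !drop, drop = FALSE]
  pc <- stats::prcomp(xs, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  keep <- ev > mean(ev)
  evr <- ev / sum(ev)
  w <- as.numeric(pc$rotation[, keep, drop = FALSE]^2 %*% evr[keep])
  names(w) <- colnames(xs)
  full <- stats::setNames(rep(0, ncol(x)), colnames(x))
  full[names(w)] <- w
  ord <- order(-full, seq_along(full))
  new("ImportanceRanking", measure = names(full)[ord],
      weight = unname(full[ord]), method = "pca")
}

#' Agreement between two importance rankings
#'
#' @param a,b \linkS4class{ImportanceRanking}s over the same measure set.
#' @param k top-k depth for the overlap fraction (default 3).
#' @return list: \code{k}, \code{top_overlap} (fraction of a's top k also
#'   in b's top k), \code{overlap_count}, and \code{rank_correlation}
#'   (Spearman over the full rankings).
#' @export
compareRankings <- function(a, b, k = 3L) {
  if (!setequal(a@measure, b@measure))
    stop("rankings cover different measure sets")
  topA <- a@measure[seq_len(k)]
  topB <- b@measure[seq_len(k)]
  nOver <- length(intersect(topA, topB))
  rA <- match(a@measure, a@measure)          # 1..p in a's order
  rB <- match(a@measure, b@measure)          # b's rank of the same items
  list(k = as.integer(k),
       top_overlap = nOver / k,
       overlap_count = as.integer(nOver),
       rank_correlation = stats::cor(rA, rB, method = "spearman"))
}

#' Subject-grouped cross-validated classification
#'
#' Classifies taste or hedonic score from the measure-SD features with
#' the extremely-randomised trees ensemble, using subject-grouped folds
#' so that no child contributes videos to both the training and the test
#' side of any split (identity leakage would inflate accuracy).
#'
#' @param fm a \linkS4class{FeatureMatrix}.
#' @param label "taste" or "score".
#' @param folds number of folds (default 5); must not exceed the number
#'   of distinct subjects.
#' @param seed RNG seed for fold assignment and the ensemble.
#' @param hyper ensemble hyperparameters as in
#'   \code{\link{rankImportanceTrees}}.
#' @return list: overall \code{accuracy}, \code{chance} (uniform 1/k
#'   level for k classes), \code{per_class} accuracies, \code{confusion}
#'   table (true x predicted), \code{folds}.
#' @export
classifyCV <- function(fm, label = c("taste", "score"), folds = 5L,
                       seed = 1L, hyper = .defaultHyper()) {
  lv <- .labelVector(fm, label)
  if (nlevels(lv$y) < 2L)
    stop("classification needs >= 2 classes")
  subjects <- unique(lv$subject)
  if (length(subjects) < folds)
    stop("fewer subjects (", length(subjects), ") than folds (", folds, ")")
  set.seed(seed)
  foldOf <- stats::setNames(
    sample(rep_len(seq_len(folds), length(subjects))), subjects)
  pred <- factor(rep(NA_character_, length(lv$y)), levels = levels(lv$y))
  for (f in seq_len(folds)) {
    test <- foldOf[lv$subject] == f
    if (!any(test)) next
    trainY <- droplevels(lv$y[!test])
    fit <- .extraTrees(lv$x[!test, , drop = FALSE], trainY, hyper,
                       seed + f)
    p <- stats::predict(fit, data.frame(lv$x[test, , drop = FALSE],
                                        check.names = FALSE))
    pred[test] <- as.character(p$predictions)
  }
  conf <- table(true = lv$y, predicted = pred, useNA = "no")
  acc <- mean(as.character(pred) == as.character(lv$y), na.rm = TRUE)
  perClass <- diag(conf) / pmax(1, rowSums(conf))
  list(accuracy = acc,
       chance = 1 / nlevels(lv$y),
       per_class = perClass,
       confusion = conf,
       folds = as.integer(folds))
}
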