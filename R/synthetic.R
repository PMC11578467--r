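## Synthetic landmark-stream generator with known ground truth. Videos
## are built as: neutral template + expression-event displacements +
## rigid head motion (translation/rotation walks, smooth scale drift) +
## isotropic landmark noise, with a configurable fraction of
## estimator-failure frames. The hedonic cohort model and the per-taste
## expression-effect profiles emulate the study's structure (sweet liked,
## bitter disliked, sour divisive; four strips per child, control first,
## three randomised orders).

#' Symmetric neutral-face landmark template
#'
#' Lays the map's landmarks out as a symmetric neutral face in normalised
#' coordinates (y up): eyebrows arched above elliptical eye contours,
#' nose tip on the midline, mouth below. The layout is exactly
#' mirror-symmetric across the facial midline x = 0.5.
#'
#' @param map a \linkS4class{LandmarkMap}.
#' @return A valid \linkS4class{LandmarkFrame} (frame 0) covering all map
#'   ids.
#' @export
neutralFaceTemplate <- function(map = defaultLandmarkMap()) {
  r <- map@regions
  pos <- list()   # id -> c(x, y, z)
  put <- function(ids, xyz) {
    for (i in seq_along(ids))
      pos[[as.character(ids[i])]] <<- xyz[i, ]
  }
  ## eyebrows: inner -> outer, arched
  t5 <- seq(0, 1, length.out = 5)
  browL <- cbind(x = 0.44 - 0.14 * t5, y = 0.62 + 0.015 * sin(pi * t5),
                 z = 0)
  put(r$left_eyebrow, browL)
  put(r$right_eyebrow, cbind(x = 1 - browL[, 1], y = browL[, 2], z = 0))
  ## eye contours: ellipses, first vertex at the inner corner
  nC <- length(r$left_eye_contour)
  ang <- 2 * pi * (seq_len(nC) - 1) / nC
  a <- 0.052; b <- 0.026
  cxL <- 0.435 - a; cy <- 0.565
  eyeL <- cbind(x = cxL + a * cos(ang), y = cy + b * sin(ang), z = 0)
  put(r$left_eye_contour, eyeL)
  nC2 <- length(r$right_eye_contour)
  ang2 <- 2 * pi * (seq_len(nC2) - 1) / nC2
  eyeR <- cbind(x = 1 - (cxL + a * cos(ang2)), y = cy + b * sin(ang2),
                z = 0)
  put(r$right_eye_contour, eyeR)
  ## midline and mouth landmarks
  put(r$nose_tip, cbind(x = 0.5, y = 0.46, z = -0.04))
  put(r$left_inner_eye_corner, cbind(x = 0.435, y = cy, z = 0))
  put(r$right_inner_eye_corner, cbind(x = 0.565, y = cy, z = 0))
  put(r$left_mouth_corner, cbind(x = 0.41, y = 0.33, z = 0))
  put(r$right_mouth_corner, cbind(x = 0.59, y = 0.33, z = 0))
  put(r$upper_mid_lip, cbind(x = 0.5, y = 0.355, z = 0))
  put(r$lower_mid_lip, cbind(x = 0.5, y = 0.305, z = 0))
  ids <- landmarkIds(map)
  m <- t(vapply(as.character(ids), function(k) pos[[k]], numeric(3)))
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  LandmarkFrame(0L, ids, m, valid = TRUE)
}

.eventRegions <- c("eyebrow_L", "eyebrow_R", "mouth_corner_L",
                   "mouth_corner_R", "upper_lip", "lower_lip",
                   "eye_L", "eye_R")

#' Build an expression-event table
#'
#' @param region one of eyebrow_L/R, mouth_corner_L/R, upper_lip,
#'   lower_lip, eye_L/R.
#' @param onset 0-based onset frame.
#' @param duration event length in frames (>= 1).
#' @param amplitude displacement as a fraction of the template
#'   inter-ocular distance (for eye events: relative contour
#'   contraction).
#' @param profile temporal profile: "pulse" (raised half-sine), "ramp"
#'   (linear rise) or "sustained" (quick rise then hold).
#' @return one-row data.frame; rbind rows to stack events (overlaps
#'   allowed).
#' @export
expressionEvent <- function(region, onset, duration, amplitude,
                            profile = c("pulse", "ramp", "sustained")) {
  profile <- match.arg(profile)
  stopifnot(region %in% .eventRegions, duration >= 1,
            is.finite(amplitude))
  data.frame(region = region, onset = as.integer(onset),
             duration = as.integer(duration), amplitude = amplitude,
             profile = profile, stringsAsFactors = FALSE)
}

.eventProfile <- function(profile, duration) {
  if (duration == 1L) return(1)
  s <- (seq_len(duration) - 1) / (duration - 1)
  switch(profile,
         pulse = sin(pi * s),
         ramp = s,
         sustained = pmin(1, s / max(s[2], 0.25)))
}

## per-region landmark ids and unit displacement directions (x, y)
.regionTargets <- function(map) {
  r <- map@regions
  list(
    eyebrow_L = list(ids = r$left_eyebrow, dir = c(0, 1)),
    eyebrow_R = list(ids = r$right_eyebrow, dir = c(0, 1)),
    mouth_corner_L = list(ids = r$left_mouth_corner,
                          dir = c(-1, 1) / sqrt(2)),
    mouth_corner_R = list(ids = r$right_mouth_corner,
                          dir = c(1, 1) / sqrt(2)),
    upper_lip = list(ids = r$upper_mid_lip, dir = c(0, 1)),
    lower_lip = list(ids = r$lower_mid_lip, dir = c(0, -1)),
    eye_L = list(ids = r$left_eye_contour, dir = NULL),   # contraction
    eye_R = list(ids = r$right_eye_contour, dir = NULL))
}

#' Generate one synthetic tasting video
#'
#' Deterministic given \code{seed}: neutral template plus expression
#' events, rigid head motion (translation and in-plane rotation walks,
#' smooth multiplicative scale drift about the face centroid), isotropic
#' Gaussian landmark noise, and Bernoulli estimator drop-out. The first
#' \code{siFraction} of frames are annotated as the tasting section (SI),
#' the rest as post-tasting (SII).
#'
#' @param nFrames number of frames (>= 2 so both sections exist).
#' @param events data.frame of \code{\link{expressionEvent}} rows, or
#'   NULL for a still face.
#' @param map a \linkS4class{LandmarkMap}.
#' @param template neutral-face frame (defaults to
#'   \code{\link{neutralFaceTemplate}}).
#' @param noiseSd isotropic landmark noise SD in normalised units
#'   (default 0.0025, about 2\% of the template inter-ocular distance —
#'   the error scale typical of face-mesh estimators).
#' @param motion logical; enable rigid motion + scale drift.
#' @param motionParams list(translationSd, rotationSdDeg, scaleSd):
#'   per-frame random-walk step SDs.
#' @param invalidFraction expected fraction of estimator-failure frames
#'   (default 0.026, i.e. 97.4\% of frames processed).
#' @param siFraction fraction of frames in the tasting section.
#' @param videoId,subjectId identifiers.
#' @param fps nominal frame rate.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return list: \code{stream} (a \linkS4class{LandmarkStream}),
#'   \code{events} (the realised event table), \code{droppedFrames}
#'   (0-based indices of invalid frames).
#' @export
generateStream <- function(nFrames = 150L, events = NULL,
                           map = defaultLandmarkMap(),
                           template = neutralFaceTemplate(map),
                           noiseSd = 0.0025, motion = TRUE,
                           motionParams = list(translationSd = 5e-4,
                                               rotationSdDeg = 0.05,
                                               scaleSd = 2e-4),
                           invalidFraction = 0.026, siFraction = 0.55,
                           videoId = "synthetic", subjectId = "synthetic",
                           fps = 30, seed = NULL) {
  nFrames <- as.integer(nFrames)
  stopifnot(nFrames >= 2L)
  if (!is.null(seed)) set.seed(seed)
  ids <- landmarkIds(map)
  tpl <- subsetLandmarks(template, map)
  base <- tpl@coords[match(ids, tpl@landmarkId), , drop = FALSE]
  nL <- length(ids)
  iod <- sqrt(sum((base[match(mapRegion(map, "left_inner_eye_corner"),
                              ids), 1:2] -
                   base[match(mapRegion(map, "right_inner_eye_corner"),
                              ids), 1:2])^2))
  targets <- .regionTargets(map)
  ## per-frame coordinates, frames x landmarks
  X <- matrix(rep(base[, 1], each = nFrames), nFrames, nL)
  Y <- matrix(rep(base[, 2], each = nFrames), nFrames, nL)
  Z <- matrix(rep(base[, 3], each = nFrames), nFrames, nL)
  if (!is.null(events) && nrow(events)) {
    for (e in seq_len(nrow(events))) {
      ev <- events[e, ]
      tgt <- targets[[ev$region]]
      colsIdx <- match(tgt$ids, ids)
      tt <- ev$onset + seq_len(ev$duration) - 1L
      inRange <- tt >= 0L & tt < nFrames
      prof <- .eventProfile(ev$profile, ev$duration)[inRange]
      rows <- tt[inRange] + 1L
      if (!length(rows)) next
      if (is.null(tgt$dir)) {
        ## eye squint: contract contour toward its centroid
        cx <- rowMeans(X[rows, colsIdx, drop = FALSE])
        cyv <- rowMeans(Y[rows, colsIdx, drop = FALSE])
        shrink <- 1 - ev$amplitude * prof
        X[rows, colsIdx] <- cx + shrink * (X[rows, colsIdx, drop = FALSE] - cx)
        Y[rows, colsIdx] <- cyv + shrink * (Y[rows, colsIdx, drop = FALSE] - cyv)
      } else {
        d <- ev$amplitude * iod * prof
        X[rows, colsIdx] <- X[rows, colsIdx, drop = FALSE] + d * tgt$dir[1]
        Y[rows, colsIdx] <- Y[rows, colsIdx, drop = FALSE] + d * tgt$dir[2]
      }
    }
  }
  if (isTRUE(motion)) {
    ctr <- colMeans(base)
    tx <- cumsum(stats::rnorm(nFrames, 0, motionParams$translationSd))
    ty <- cumsum(stats::rnorm(nFrames, 0, motionParams$translationSd))
    th <- cumsum(stats::rnorm(nFrames, 0,
                              motionParams$rotationSdDeg * pi / 180))
    sc <- exp(cumsum(stats::rnorm(nFrames, 0, motionParams$scaleSd)))
    dx <- X - ctr[1]; dy <- Y - ctr[2]
    X <- ctr[1] + sc * (cos(th) * dx - sin(th) * dy) + tx
    Y <- ctr[2] + sc * (sin(th) * dx + cos(th) * dy) + ty
    Z <- ctr[3] + sc * (Z - ctr[3])
  }
  if (noiseSd > 0) {
    X <- X + stats::rnorm(nFrames * nL, 0, noiseSd)
    Y <- Y + stats::rnorm(nFrames * nL, 0, noiseSd)
    Z <- Z + stats::rnorm(nFrames * nL, 0, noiseSd)
  }
  invalid <- stats::runif(nFrames) < invalidFraction
  frameList <- vector("list", nFrames)
  for (t in seq_len(nFrames)) {
    frameList[[t]] <- if (invalid[t])
      LandmarkFrame(t - 1L, valid = FALSE)
    else
      LandmarkFrame(t - 1L, ids,
                    cbind(x = X[t, ], y = Y[t, ], z = Z[t, ]))
  }
  siEnd <- max(0L, as.integer(floor(siFraction * nFrames)) - 1L)
  sec <- SectionAnnotation(0L, siEnd,
                           if (siEnd < nFrames - 1L) siEnd + 1L
                           else NA_integer_,
                           if (siEnd < nFrames - 1L) nFrames - 1L
                           else NA_integer_)
  stream <- LandmarkStream(videoId, subjectId, frameList, sec, fps)
  list(stream = stream,
       events = if (is.null(events))
         expressionEvent("eyebrow_L", 0, 1, 0)[0, ] else events,
       droppedFrames = which(invalid) - 1L)
}

#' Per-taste hedonic score model
#'
#' @param probs 4 x 5 matrix of score probabilities (rows in
#'   \code{\link{tasteLevels}} order). The default encodes the expected
#'   pattern: control peaked at 3, sweet at 5, bitter at 1, sour
#'   dispersed.
#' @return A \linkS4class{HedonicModel}.
#' @export
hedonicModel <- function(probs = NULL) {
  if (is.null(probs))
    probs <- rbind(control = c(0.05, 0.15, 0.55, 0.15, 0.10),
                   sweet   = c(0.02, 0.03, 0.10, 0.25, 0.60),
                   sour    = c(0.20, 0.20, 0.20, 0.20, 0.20),
                   bitter  = c(0.60, 0.25, 0.10, 0.03, 0.02))
  probs <- probs[tasteLevels(), , drop = FALSE]
  colnames(probs) <- as.character(1:5)
  new("HedonicModel", probs = probs)
}

#' Draw hedonic scores from a HedonicModel
#'
#' @param model a \linkS4class{HedonicModel}.
#' @param taste character vector of taste levels.
#' @return integer scores in 1..5, one per element of \code{taste}.
#' @export
drawHedonicScores <- function(model, taste) {
  vapply(as.character(taste), function(t)
    sample(1:5, 1L, prob = model@probs[t, ]), integer(1),
    USE.NAMES = FALSE)
}

#' Default per-taste expression-effect profiles
#'
#' Event amplitudes (fractions of inter-ocular distance; eye events:
#' relative contraction) per facial region and taste. The defaults
#' loosely encode the observed response pattern — bitter driving
#' lower-lip activity, sweet driving brow raises — but they are
#' configuration, not hard-coded truth: pass any named list of the same
#' shape to \code{\link{generateCohort}}.
#'
#' @return named list (one element per taste) of named amplitude lists.
#' @export
defaultTasteEffects <- function() {
  list(
    control = list(eyebrow_L = 0.02, eyebrow_R = 0.02, lower_lip = 0.02),
    sweet = list(eyebrow_L = 0.10, eyebrow_R = 0.12,
                 mouth_corner_L = 0.05, mouth_corner_R = 0.05),
    sour = list(eye_L = 0.08, eye_R = 0.08, upper_lip = 0.06,
                eyebrow_L = 0.04, eyebrow_R = 0.04),
    bitter = list(lower_lip = 0.12, mouth_corner_L = 0.06,
                  mouth_corner_R = 0.06, eyebrow_L = 0.03,
                  eyebrow_R = 0.03))
}

#' Eyebrow-only effect profiles for recovery experiments
#'
#' Effect profiles in which only the eyebrow-raise event amplitude
#' differs across tastes, so eyebrow elevation is the sole measure with a
#' class signal; used to verify that the importance ranking recovers a
#' planted ground truth.
#'
#' @param amplitudes named numeric vector of per-taste eyebrow
#'   amplitudes (fractions of inter-ocular distance).
#' @param ratioR right/left amplitude ratio (mild observer-right
#'   dominance by default).
#' @return named list of per-taste effect lists.
#' @export
eyebrowOnlyEffects <- function(amplitudes = c(control = 0.01,
                                              sweet = 0.14, sour = 0.05,
                                              bitter = 0.09),
                               ratioR = 1.25) {
  lapply(stats::setNames(tasteLevels(), tasteLevels()), function(t)
    list(eyebrow_L = unname(amplitudes[t]),
         eyebrow_R = unname(amplitudes[t]) * ratioR))
}

#' Generate a synthetic tasting cohort with ground truth
#'
#' Each subject contributes one control video plus the three taste
#' videos in one of the three randomised strip orders; ages are drawn
#' from the published age-frequency distribution, hedonic scores from the
#' per-taste \linkS4class{HedonicModel}, and each video's expression
#' events from the taste's effect profile with a subject-level random
#' gain. Fully reproducible from \code{seed}.
#'
#' @param nSubjects number of children (>= 1).
#' @param hedonic a \linkS4class{HedonicModel}.
#' @param effects per-taste effect profiles (see
#'   \code{\link{defaultTasteEffects}}).
#' @param seed master integer seed.
#' @param nFrames frames per video.
#' @param eventsPerRegion expression events per active region and video.
#' @param ageWeights named integer vector of age frequencies used as
#'   sampling weights (default: the published distribution).
#' @param subjectGainSd SD of the log-normal subject-level amplitude
#'   gain.
#' @param map,noiseSd,motion,motionParams,invalidFraction,siFraction,fps
#'   passed to \code{\link{generateStream}}.
#' @return list: \code{streams} (named by video id), \code{records}
#'   (validated session data.frame), \code{truth} (per-subject gains and
#'   per-video realised events, dropped frames and seeds).
#' @export
generateCohort <- function(nSubjects = 64L, hedonic = hedonicModel(),
                           effects = defaultTasteEffects(), seed = 1L,
                           nFrames = 150L, eventsPerRegion = 2L,
                           ageWeights = studyAgeCounts(),
                           subjectGainSd = 0.2,
                           map = defaultLandmarkMap(), noiseSd = 0.0025,
                           motion = TRUE,
                           motionParams = list(translationSd = 5e-4,
                                               rotationSdDeg = 0.05,
                                               scaleSd = 2e-4),
                           invalidFraction = 0.026, siFraction = 0.55,
                           fps = 30) {
  nSubjects <- as.integer(nSubjects)
  if (nSubjects < 1L) stop("nSubjects must be >= 1")
  set.seed(seed)
  template <- neutralFaceTemplate(map)
  streams <- list()
  recRows <- list()
  truth <- list(seed = as.integer(seed), subjects = list(),
                videos = list())
  ages <- as.integer(names(ageWeights))
  for (i in seq_len(nSubjects)) {
    sid <- sprintf("S%03d", i)
    age <- sample(ages, 1L, prob = ageWeights)
    sex <- sample(c("female", "male"), 1L, prob = c(36, 28))
    ord <- sample(orderSequences(), 1L)
    gain <- exp(stats::rnorm(1, 0, subjectGainSd))
    truth$subjects[[sid]] <- list(age = age, sex = sex, order = ord,
                                  gain = gain)
    tastes <- c("control", strsplit(ord, "-", fixed = TRUE)[[1]])
    for (taste in tastes) {
      vid <- sprintf("V%03d_%s", i, taste)
      score <- drawHedonicScores(hedonic, taste)
      prof <- effects[[taste]]
      evRows <- list()
      for (region in names(prof)) {
        for (k in seq_len(eventsPerRegion)) {
          onset <- sample.int(max(1L, nFrames - 30L), 1L) - 1L
          duration <- sample(15:30, 1L)
          amp <- prof[[region]] * gain * stats::runif(1, 0.8, 1.2)
          evRows[[length(evRows) + 1L]] <-
            expressionEvent(region, onset, duration, amp, "pulse")
        }
      }
      ev <- if (length(evRows)) do.call(rbind, evRows) else NULL
      vseed <- sample.int(2147483646L, 1L)
      g <- generateStream(nFrames = nFrames, events = ev, map = map,
                          template = template, noiseSd = noiseSd,
                          motion = motion, motionParams = motionParams,
                          invalidFraction = invalidFraction,
                          siFraction = siFraction, videoId = vid,
                          subjectId = sid, fps = fps, seed = vseed)
      streams[[vid]] <- g$stream
      s <- sections(g$stream)
      recRows[[length(recRows) + 1L]] <- data.frame(
        subject_id = sid, age = age, sex = sex, taste = taste,
        order_sequence = ord, hedonic_score = score, video_id = vid,
        si_start = s@siStart, si_end = s@siEnd,
        sii_start = s@siiStart, sii_end = s@siiEnd,
        stringsAsFactors = FALSE)
      truth$videos[[vid]] <- list(subject = sid, taste = taste,
                                  seed = vseed, events = g$events,
                                  droppedFrames = g$droppedFrames)
    }
  }
  records <- validateSessionRecords(do.call(rbind, recRows))
  list(streams = streams, records = records, truth = truth)
}
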