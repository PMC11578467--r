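#' @import methods
NULL

#' LandmarkFrame: one video frame of estimated facial landmarks
#'
#' Holds the indexed 3D landmark coordinates of a single video frame as
#' produced by a face-mesh estimator, together with a validity flag.
#' Frames on which the estimator failed (child turned away, face covered)
#' are kept in the stream with \code{valid = FALSE} and empty coordinates,
#' so per-video drop-out can be reported exactly.
#'
#' @slot frameIndex integer(1), 0-based frame number within the video.
#' @slot landmarkId integer vector of landmark indices (unique).
#' @slot coords numeric matrix with one row per landmark and columns
#'   \code{x}, \code{y}, \code{z}, in estimator-normalised units.
#' @slot valid logical(1); \code{FALSE} when the estimator failed.
#'
#' @exportClass LandmarkFrame
setClass("LandmarkFrame",
  representation(
    frameIndex = "integer",
    landmarkId = "integer",
    coords     = "matrix",
    valid      = "logical"
  ),
  prototype(
    frameIndex = 0L,
    landmarkId = integer(0),
    coords     = matrix(numeric(0), ncol = 3,
                        dimnames = list(NULL, c("x", "y", "z"))),
    valid      = TRUE
  )
)

setValidity("LandmarkFrame", function(object) {
  msg <- character(0)
  if (length(object@frameIndex) != 1L || is.na(object@frameIndex) ||
      object@frameIndex < 0L)
    msg <- c(msg, "frameIndex must be a single non-negative integer")
  if (length(object@valid) != 1L || is.na(object@valid))
    msg <- c(msg, "valid must be TRUE or FALSE")
  if (anyDuplicated(object@landmarkId))
    msg <- c(msg, "landmark ids must be unique within a frame")
  if (nrow(object@coords) != length(object@landmarkId))
    msg <- c(msg, "coords must have one row per landmark id")
  if (ncol(object@coords) != 3L)
    msg <- c(msg, "coords must have columns x, y, z")
  if (isTRUE(object@valid) && nrow(object@coords) > 0L &&
      !all(is.finite(object@coords)))
    msg <- c(msg, "a valid frame must have finite coordinates")
  if (length(msg)) msg else TRUE
})

#' Construct a LandmarkFrame
#'
#' @param frameIndex 0-based frame number.
#' @param landmarkId integer vector of landmark indices.
#' @param coords numeric matrix (n x 3) or data.frame with columns x, y, z.
#' @param valid logical; `FALSE` marks an estimator-failure frame.
#' @return A \linkS4class{LandmarkFrame}.
#' @examples
#' LandmarkFrame(0L, c(1L, 2L), cbind(x = c(0, 1), y = c(0, 1), z = 0))
#' @export
LandmarkFrame <- function(frameIndex, landmarkId = integer(0),
                          coords = NULL, valid = TRUE) {
  if (is.null(coords))
    coords <- matrix(numeric(0), ncol = 3)
  if (is.data.frame(coords))
    coords <- as.matrix(coords[, c("x", "y", "z")])
  coords <- matrix(as.numeric(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  new("LandmarkFrame", frameIndex = as.integer(frameIndex),
      landmarkId = as.integer(landmarkId), coords = coords,
      valid = as.logical(valid))
}

#' SectionAnnotation: tasting (SI) and post-tasting (SII) frame spans
#'
#' SI runs from strip insertion until just before removal; SII, when
#' present, from just after removal until the end of usable footage.
#' Bounds are 0-based frame indices, inclusive on both ends.
#'
#' @slot siStart,siEnd integer(1), SI bounds.
#' @slot siiStart,siiEnd integer(1) or NA when the post-tasting section
#'   was not annotated.
#' @exportClass SectionAnnotation
setClass("SectionAnnotation",
  representation(siStart = "integer", siEnd = "integer",
                 siiStart = "integer", siiEnd = "integer"),
  prototype(siStart = 0L, siEnd = 0L,
            siiStart = NA_integer_, siiEnd = NA_integer_)
)

setValidity("SectionAnnotation", function(object) {
  msg <- character(0)
  if (is.na(object@siStart) || is.na(object@siEnd))
    msg <- c(msg, "SI bounds are required")
  else if (object@siStart > object@siEnd)
    msg <- c(msg, "si_start must be <= si_end")
  hasS2 <- !is.na(object@siiStart) || !is.na(object@siiEnd)
  if (hasS2) {
    if (is.na(object@siiStart) || is.na(object@siiEnd))
      msg <- c(msg, "both SII bounds must be given, or neither")
    else {
      if (!is.na(object@siEnd) && object@siiStart <= object@siEnd)
        msg <- c(msg, "sii_start must be > si_end")
      if (object@siiStart > object@siiEnd)
        msg <- c(msg, "sii_start must be <= sii_end")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SectionAnnotation
#'
#' @param siStart,siEnd inclusive 0-based SI bounds.
#' @param siiStart,siiEnd inclusive SII bounds, or NA when absent.
#' @return A \linkS4class{SectionAnnotation}.
#' @export
SectionAnnotation <- function(siStart, siEnd,
                              siiStart = NA_integer_, siiEnd = NA_integer_) {
  new("SectionAnnotation",
      siStart = as.integer(siStart), siEnd = as.integer(siEnd),
      siiStart = as.integer(siiStart), siiEnd = as.integer(siiEnd))
}

#' LandmarkStream: one tasting video as an ordered landmark-frame sequence
#'
#' @slot videoId character(1) opaque video identifier.
#' @slot subjectId character(1) opaque subject identifier.
#' @slot frames list of \linkS4class{LandmarkFrame}, strictly increasing
#'   \code{frameIndex}.
#' @slot sections \linkS4class{SectionAnnotation}.
#' @slot fps numeric(1) frames per second, or NA when unknown.
#' @exportClass LandmarkStream
setClass("LandmarkStream",
  representation(videoId = "character", subjectId = "character",
                 frames = "list", sections = "SectionAnnotation",
                 fps = "numeric"),
  prototype(videoId = "", subjectId = "", frames = list(),
            fps = NA_real_)
)

setValidity("LandmarkStream", function(object) {
  msg <- character(0)
  if (length(object@frames)) {
    ok <- vapply(object@frames, is, logical(1), class2 = "LandmarkFrame")
    if (!all(ok))
      return("frames must all be LandmarkFrame objects")
    idx <- vapply(object@frames, slot, integer(1), name = "frameIndex")
    if (any(diff(idx) <= 0L))
      msg <- c(msg, "frame indices must be strictly increasing")
    rng <- range(idx)
    s <- object@sections
    bounds <- c(s@siStart, s@siEnd, s@siiStart, s@siiEnd)
    bounds <- bounds[!is.na(bounds)]
    if (length(bounds) && (min(bounds) < rng[1] || max(bounds) > rng[2]))
      msg <- c(msg, "section bounds fall outside the frame index range")
  }
  if (length(object@fps) == 1L && !is.na(object@fps) && object@fps <= 0)
    msg <- c(msg, "fps must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a LandmarkStream
#'
#' @param videoId,subjectId identifiers.
#' @param frames list of \linkS4class{LandmarkFrame} (sorted by index on
#'   construction).
#' @param sections a \linkS4class{SectionAnnotation}.
#' @param fps frames per second (optional).
#' @return A \linkS4class{LandmarkStream}.
#' @export
LandmarkStream <- function(videoId, subjectId, frames, sections,
                           fps = NA_real_) {
  idx <- vapply(frames, slot, integer(1), name = "frameIndex")
  frames <- frames[order(idx)]
  new("LandmarkStream", videoId = as.character(videoId),
      subjectId = as.character(subjectId), frames = frames,
      sections = sections, fps = as.numeric(fps))
}

#' LandmarkMap: named sets of key facial landmark indices
#'
#' Identifies which estimator mesh indices outline each facial region used
#' by the geometric measures: the five-point eyebrows, the closed
#' eye-contour polygons, the nose tip, the inner eye corners, the mouth
#' corners and the mid-lip points. The default map covers exactly 53
#' distinct mesh indices. Left/right is from the observer's point of view.
#'
#' @slot regions named list of integer vectors.
#' @exportClass LandmarkMap
setClass("LandmarkMap", representation(regions = "list"))

.mapRegionNames <- c(
  "left_eyebrow", "right_eyebrow",
  "left_eye_contour", "right_eye_contour",
  "nose_tip", "left_inner_eye_corner", "right_inner_eye_corner",
  "left_mouth_corner", "right_mouth_corner",
  "upper_mid_lip", "lower_mid_lip")

setValidity("LandmarkMap", function(object) {
  msg <- character(0)
  r <- object@regions
  miss <- setdiff(.mapRegionNames, names(r))
  if (length(miss))
    return(paste("missing regions:", paste(miss, collapse = ", ")))
  for (nm in c("left_eyebrow", "right_eyebrow"))
    if (length(r[[nm]]) != 5L)
      msg <- c(msg, paste(nm, "must have exactly 5 ids (inner to outer)"))
  for (nm in c("left_eye_contour", "right_eye_contour"))
    if (length(r[[nm]]) < 4L)
      msg <- c(msg, paste(nm, "must have at least 4 ids"))
  for (nm in c("nose_tip", "left_inner_eye_corner", "right_inner_eye_corner",
               "left_mouth_corner", "right_mouth_corner",
               "upper_mid_lip", "lower_mid_lip"))
    if (length(r[[nm]]) != 1L)
      msg <- c(msg, paste(nm, "must be a single id"))
  for (nm in .mapRegionNames)
    if (anyDuplicated(r[[nm]]))
      msg <- c(msg, paste(nm, "contains duplicated ids"))
  if (length(msg)) msg else TRUE
})

#' MeasureSeries: per-frame values of the twelve facial measures
#'
#' One row per retained (valid, non-degenerate) frame of the requested
#' task section; columns in the fixed order of \code{\link{measureNames}}.
#' Distances are dimensionless (scaled by the per-frame reference
#' distance), apertures are scaled by the squared reference, angles are in
#' degrees.
#'
#' @slot videoId character(1).
#' @slot section character(1): "SI", "SII" or "SI+SII".
#' @slot frameIndex integer vector of retained frame indices.
#' @slot measures numeric matrix, one row per retained frame, columns
#'   \code{\link{measureNames}}.
#' @slot referenceDistance numeric vector of per-frame pre-scaling
#'   reference distances (all > 0).
#' @slot nDropped integer(1): valid frames dropped as degenerate.
#' @exportClass MeasureSeries
setClass("MeasureSeries",
  representation(videoId = "character", section = "character",
                 frameIndex = "integer", measures = "matrix",
                 referenceDistance = "numeric", nDropped = "integer"),
  prototype(nDropped = 0L)
)

setValidity("MeasureSeries", function(object) {
  msg <- character(0)
  n <- length(object@frameIndex)
  if (nrow(object@measures) != n ||
      length(object@referenceDistance) != n)
    msg <- c(msg, "frameIndex, measures and referenceDistance lengths differ")
  if (!identical(colnames(object@measures), measureNames()))
    msg <- c(msg, "measure columns must follow measureNames() order")
  if (n > 0 && any(object@referenceDistance <= 0))
    msg <- c(msg, "referenceDistance must be > 0 for retained frames")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: per-video measure-variability features with labels
#'
#' Rows are videos, columns the twelve per-video measure standard
#' deviations in \code{\link{measureNames}} order; taste and hedonic
#' labels plus the subject grouping ride along for classification and
#' subject-grouped cross-validation.
#'
#' @slot features numeric matrix (videos x 12), no missing values.
#' @slot videoId,subjectId character vectors, one per row.
#' @slot taste factor with levels control/sweet/sour/bitter.
#' @slot score integer hedonic scores (1..5, NA allowed).
#' @slot nDropped integer(1): summaries dropped for undefined features.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(features = "matrix", videoId = "character",
                 subjectId = "character", taste = "factor",
                 score = "integer", nDropped = "integer"),
  prototype(nDropped = 0L)
)

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  n <- nrow(object@features)
  if (!identical(colnames(object@features), measureNames()))
    msg <- c(msg, "feature columns must follow measureNames() order")
  if (anyNA(object@features))
    msg <- c(msg, "feature matrix must not contain missing values")
  if (length(object@videoId) != n || length(object@subjectId) != n ||
      length(object@taste) != n || length(object@score) != n)
    msg <- c(msg, "label lengths must equal the number of rows")
  if (length(msg)) msg else TRUE
})

#' ImportanceRanking: ordered measure-importance weights
#'
#' @slot measure character vector of measure names, most important first.
#' @slot weight numeric weights aligned with \code{measure}; the trees
#'   method normalises them to sum to one.
#' @slot method character(1): "trees" or "pca".
#' @slot seeds integer vector of refit seeds ("trees" only).
#' @slot perSeed numeric matrix of per-seed importances (seeds x measures,
#'   canonical column order), empty for deterministic methods.
#' @exportClass ImportanceRanking
setClass("ImportanceRanking",
  representation(measure = "character", weight = "numeric",
                 method = "character", seeds = "integer",
                 perSeed = "matrix"),
  prototype(seeds = integer(0),
            perSeed = matrix(numeric(0), nrow = 0, ncol = 0))
)

setValidity("ImportanceRanking", function(object) {
  msg <- character(0)
  if (length(object@measure) != length(object@weight))
    msg <- c(msg, "measure and weight lengths differ")
  if (any(object@weight < -1e-12))
    msg <- c(msg, "weights must be non-negative")
  if (is.unsorted(rev(object@weight)))
    msg <- c(msg, "weights must be ordered non-increasing")
  if (!object@method %in% c("trees", "pca"))
    msg <- c(msg, "method must be 'trees' or 'pca'")
  if (object@method == "trees" && length(object@weight) &&
      abs(sum(object@weight) - 1) > 1e-9)
    msg <- c(msg, "trees weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' HedonicModel: per-taste distributions of the 5-point hedonic score
#'
#' Encodes how children in each taste condition distribute their ratings
#' on the 5-point smiley-face scale (1 = dislike, 5 = like). The default
#' reproduces the expected pattern: sweet peaked high, bitter peaked low,
#' control peaked at the midpoint, sour dispersed.
#'
#' @slot probs numeric matrix (4 tastes x 5 scores); rows sum to 1,
#'   rownames control/sweet/sour/bitter.
#' @exportClass HedonicModel
setClass("HedonicModel", representation(probs = "matrix"))

setValidity("HedonicModel", function(object) {
  p <- object@probs
  msg <- character(0)
  if (!identical(rownames(p), tasteLevels()))
    msg <- c(msg, "rows must be named control, sweet, sour, bitter")
  if (ncol(p) != 5L)
    msg <- c(msg, "must have 5 score columns")
  if (any(p < 0))
    msg <- c(msg, "probabilities must be non-negative")
  if (nrow(p) == 4L && any(abs(rowSums(p) - 1) > 1e-9))
    msg <- c(msg, "each taste's score distribution must sum to 1")
  if (length(msg)) msg else TRUE
})

#' The four taste-strip conditions
#'
#' @return Character vector \code{c("control","sweet","sour","bitter")}.
#' @export
tasteLevels <- function() c("control", "sweet", "sour", "bitter")

#' The three randomised strip-testing sequences
#'
#' The control strip is always tasted first (as practice); the remaining
#' three strips follow one of three randomised orders.
#'
#' @return Character vector of the three order labels.
#' @export
orderSequences <- function()
  c("sweet-sour-bitter", "sour-bitter-sweet", "bitter-sweet-sour")
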