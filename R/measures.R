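## Per-frame measure operations and whole-stream series extraction.
## The per-frame functions validate degenerate configurations explicitly;
## computeMeasureSeries uses the vectorised kernels and drops degenerate
## frames with a count instead.

.frameArrays <- function(frame, map) {
  if (!isTRUE(frame@valid))
    .streamError(sprintf("frame %d is marked invalid", frame@frameIndex),
                 "invalidFrameError")
  .framesToArrays(list(frame), map)
}

#' Per-frame reference distance
#'
#' Euclidean distance between the right inner eye corner and the nose
#' tip, used to rescale every distance measure so that camera distance
#' and zoom cancel. Computed in the x-y image plane by default.
#'
#' @param frame a valid \linkS4class{LandmarkFrame} containing the map's
#'   ids.
#' @param map a \linkS4class{LandmarkMap}.
#' @param mode "2d" (image plane, default) or "3d".
#' @return positive numeric scalar; coincident landmarks raise a
#'   degenerate-frame error.
#' @export
referenceDistance <- function(frame, map, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  a <- .frameArrays(frame, map)
  cols <- .mapCols(map, a$ids)
  ref <- .kReference(a$X, a$Y, a$Z, cols, mode)
  if (ref < .Machine$double.eps)
    .streamError(sprintf(
      "frame %d: reference landmarks coincide (zero reference distance)",
      frame@frameIndex), "degenerateFrameError")
  ref
}

.measureOne <- function(frame, map, mode, name) {
  a <- .frameArrays(frame, map)
  cols <- .mapCols(map, a$ids)
  ref <- .kReference(a$X, a$Y, a$Z, cols, mode)
  if (ref < .Machine$double.eps)
    .streamError(sprintf(
      "frame %d: zero reference distance", frame@frameIndex),
      "degenerateFrameError")
  all <- .kAllMeasures(a$X, a$Y, a$Z, cols, mode)
  unname(all$measures[1, name])
}

#' Eyebrow elevation
#'
#' Reference-scaled Euclidean distance between the median of the five
#' eyebrow landmarks and the nose tip. The median of the point set is
#' taken coordinate-wise in the face-intrinsic frame whose x-axis is the
#' inner-eye-corner line: an image-axis median would not be
#' rotation-equivariant, and the measure must be invariant under in-plane
#' head rotation.
#'
#' @inheritParams referenceDistance
#' @param side "L" or "R" (observer's point of view).
#' @return dimensionless non-negative numeric scalar.
#' @export
eyebrowElevation <- function(frame, map, side = c("L", "R"),
                             mode = c("2d", "3d")) {
  side <- match.arg(side); mode <- match.arg(mode)
  .measureOne(frame, map, mode, paste0("eyebrow_elevation_", side))
}

#' Eyebrow tilt
#'
#' Unsigned angle, folded into [0, 90] degrees, between the
#' total-least-squares (principal-axis) line through the five eyebrow
#' landmarks and the line connecting the two inner eye corners, both in
#' the image plane.
#'
#' @inheritParams eyebrowElevation
#' @return angle in degrees in [0, 90]; coincident eyebrow points raise
#'   an undefined-fit error.
#' @export
eyebrowTilt <- function(frame, map, side = c("L", "R")) {
  side <- match.arg(side)
  v <- .measureOne(frame, map, "2d", paste0("eyebrow_tilt_", side))
  if (is.nan(v))
    .streamError(sprintf(
      "frame %d: eyebrow points coincide, tilt line undefined",
      frame@frameIndex), "undefinedFitError")
  v
}

#' Eyebrow shape
#'
#' Interior angle at the middle (third) eyebrow landmark between the
#' segments to the inner and outer endpoints, in [0, 180] degrees
#' (collinear points give 180).
#'
#' @inheritParams eyebrowElevation
#' @return angle in degrees; a middle point coincident with an endpoint
#'   raises an undefined-angle error.
#' @export
eyebrowShape <- function(frame, map, side = c("L", "R")) {
  side <- match.arg(side)
  v <- .measureOne(frame, map, "2d", paste0("eyebrow_shape_", side))
  if (is.nan(v))
    .streamError(sprintf(
      "frame %d: middle eyebrow landmark coincides with an endpoint",
      frame@frameIndex), "undefinedAngleError")
  v
}

#' Palpebral aperture
#'
#' Absolute shoelace area of the ordered eye-contour polygon in the image
#' plane, scaled by the squared reference distance so the measure is
#' dimensionless like the distance measures.
#'
#' @inheritParams eyebrowElevation
#' @return non-negative numeric scalar.
#' @export
palpebralAperture <- function(frame, map, side = c("L", "R")) {
  side <- match.arg(side)
  contour <- mapRegion(map, paste0(
    if (side == "L") "left" else "right", "_eye_contour"))
  if (length(contour) < 3L)
    .streamError("eye contour needs at least 3 points", "validationError")
  .measureOne(frame, map, "2d", paste0("palpebral_aperture_", side))
}

#' Lip elevation
#'
#' Reference-scaled Euclidean distance between the mid-lip landmark
#' (upper or lower) and the nose tip.
#'
#' @inheritParams referenceDistance
#' @param which "upper" or "lower".
#' @export
lipElevation <- function(frame, map, which = c("upper", "lower"),
                         mode = c("2d", "3d")) {
  which <- match.arg(which); mode <- match.arg(mode)
  .measureOne(frame, map, mode, paste0("lip_elevation_", which))
}

#' Mouth corner distance
#'
#' Reference-scaled Euclidean distance between the mouth-corner landmark
#' and the nose tip.
#'
#' @inheritParams eyebrowElevation
#' @export
mouthCorner <- function(frame, map, side = c("L", "R"),
                        mode = c("2d", "3d")) {
  side <- match.arg(side); mode <- match.arg(mode)
  .measureOne(frame, map, mode, paste0("mouth_corner_", side))
}

#' All twelve measures of one frame
#'
#' @inheritParams referenceDistance
#' @return named numeric vector in \code{\link{measureNames}} order.
#' @export
measureVector <- function(frame, map, mode = c("2d", "3d")) {
  mode <- match.arg(mode)
  a <- .frameArrays(frame, map)
  cols <- .mapCols(map, a$ids)
  out <- .kAllMeasures(a$X, a$Y, a$Z, cols, mode)
  if (out$reference[1] < .Machine$double.eps)
    .streamError(sprintf("frame %d: zero reference distance",
                         frame@frameIndex), "degenerateFrameError")
  out$measures[1, ]
}

#' Compute the per-frame measure series of a video
#'
#' Applies all twelve measures to every retained frame of the requested
#' task section — every frame, whether it shows a neutral, transitioning
#' or peak expression, so the dynamics are captured in full. Frames with
#' \code{valid = FALSE} are excluded; valid frames with a degenerate
#' (zero) reference distance are dropped with a warning and counted in
#' the result's \code{nDropped} slot.
#'
#' @param stream a \linkS4class{LandmarkStream}.
#' @param map a \linkS4class{LandmarkMap}; all map ids must be present in
#'   every retained frame.
#' @param section "SI", "SII" or "SI+SII" (default).
#' @param mode "2d" (default) or "3d" for distance measures.
#' @return A \linkS4class{MeasureSeries}; zero retained frames give an
#'   empty series (with a warning).
#' @export
computeMeasureSeries <- function(stream, map = defaultLandmarkMap(),
                                 section = c("SI+SII", "SI", "SII"),
                                 mode = c("2d", "3d")) {
  section <- match.arg(section)
  mode <- match.arg(mode)
  frameList <- selectFrames(stream, section)
  empty <- function(nDropped) {
    warning("no retained frames for video ", stream@videoId,
            " in section ", section)
    new("MeasureSeries", videoId = stream@videoId, section = section,
        frameIndex = integer(0),
        measures = matrix(numeric(0), 0, 12,
                          dimnames = list(NULL, measureNames())),
        referenceDistance = numeric(0), nDropped = nDropped)
  }
  if (!length(frameList)) return(empty(0L))
  a <- .framesToArrays(frameList, map)
  cols <- .mapCols(map, a$ids)
  out <- .kAllMeasures(a$X, a$Y, a$Z, cols, mode)
  keep <- out$reference > .Machine$double.eps &
    apply(is.finite(out$measures), 1, all)
  nDropped <- sum(!keep)
  if (nDropped > 0)
    warning(sprintf("video %s: dropped %d degenerate frame(s)",
                    stream@videoId, nDropped))
  if (!any(keep)) return(empty(as.integer(nDropped)))
  new("MeasureSeries", videoId = stream@videoId, section = section,
      frameIndex = a$frameIndex[keep],
      measures = out$measures[keep, , drop = FALSE],
      referenceDistance = out$reference[keep],
      nDropped = as.integer(nDropped))
}

#' Centred moving average of a measure series
#'
#' Smooths each measure with a centred window, shortening the series by
#' window - 1 frames. Intended for display only: all variability
#' statistics and classifier features use unsmoothed series.
#'
#' @param series a \linkS4class{MeasureSeries}.
#' @param window odd integer >= 1 (1 = identity); the display convention
#'   is a 5-frame window.
#' @return A shortened \linkS4class{MeasureSeries}.
#' @export
movingAverage <- function(series, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1 (centred convention)")
  n <- length(series@frameIndex)
  if (window > n)
    stop("window exceeds series length")
  if (window == 1L) return(series)
  half <- (window - 1L) %/% 2L
  keep <- (half + 1L):(n - half)
  sm <- apply(series@measures, 2, function(v)
    stats::filter(v, rep(1 / window, window), sides = 2))
  sm <- matrix(sm, nrow = n,
               dimnames = list(NULL, colnames(series@measures)))
  refSm <- as.numeric(stats::filter(series@referenceDistance,
                                    rep(1 / window, window), sides = 2))
  new("MeasureSeries", videoId = series@videoId, section = series@section,
      frameIndex = series@frameIndex[keep],
      measures = sm[keep, , drop = FALSE],
      referenceDistance = refSm[keep],
      nDropped = series@nDropped)
}

#' Write measure series to a tidy CSV
#'
#' @param seriesList a MeasureSeries or list of them.
#' @param path output CSV (columns video_id, section, frame_index,
#'   measure, value).
#' @export
writeMeasuresCSV <- function(seriesList, path) {
  if (is(seriesList, "MeasureSeries")) seriesList <- list(seriesList)
  tab <- do.call(rbind, lapply(seriesList, as.data.frame))
  tab$value <- .fmtNum(tab$value)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tidy measures CSV
#'
#' @param path CSV written by \code{\link{writeMeasuresCSV}}.
#' @return data.frame in long format.
#' @export
readMeasuresCSV <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(video_id = "character",
                                 section = "character",
                                 frame_index = "integer",
                                 measure = "character",
                                 value = "numeric"))
}
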