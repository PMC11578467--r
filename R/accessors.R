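#' Accessors for TasteFace objects
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @param region for \code{mapRegion}: one of the named landmark regions
#'   (e.g. \code{"left_eyebrow"}, \code{"nose_tip"}).
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("landmarkIds", "LandmarkFrame", function(x, ...) x@landmarkId)

#' @rdname accessors
#' @export
setMethod("landmarkIds", "LandmarkMap", function(x, ...)
  sort(unique(unlist(x@regions, use.names = FALSE))))

#' @rdname accessors
#' @export
setMethod("coords", "LandmarkFrame", function(x, ...) {
  m <- x@coords
  rownames(m) <- x@landmarkId
  m
})

#' @rdname accessors
#' @export
setMethod("frames", "LandmarkStream", function(x, ...) x@frames)

#' @rdname accessors
#' @export
setMethod("sections", "LandmarkStream", function(x, ...) x@sections)

#' @rdname accessors
#' @export
setMethod("videoId", "LandmarkStream", function(x, ...) x@videoId)

#' @rdname accessors
#' @export
setMethod("videoId", "MeasureSeries", function(x, ...) x@videoId)

#' @rdname accessors
#' @export
setMethod("subjectId", "LandmarkStream", function(x, ...) x@subjectId)

#' @rdname accessors
#' @export
setMethod("validFraction", "LandmarkStream", function(x, ...) {
  if (!length(x@frames)) return(NA_real_)
  mean(vapply(x@frames, slot, logical(1), name = "valid"))
})

#' @rdname accessors
#' @export
setMethod("mapRegion", "LandmarkMap", function(x, region, ...) {
  if (!region %in% names(x@regions))
    stop("unknown landmark region: ", region)
  x@regions[[region]]
})

#' @rdname accessors
#' @export
setMethod("measures", "MeasureSeries", function(x, ...) x@measures)

#' @rdname accessors
#' @export
setMethod("features", "FeatureMatrix", function(x, ...) x@features)

#' @rdname accessors
#' @export
setMethod("importanceWeights", "ImportanceRanking", function(x, ...) {
  w <- x@weight
  names(w) <- x@measure
  w
})

#' Number of retained frames in a MeasureSeries
#' @param x a MeasureSeries.
#' @export
setMethod("length", "MeasureSeries", function(x) length(x@frameIndex))

#' Tidy long-format view of a MeasureSeries
#'
#' @param x a \linkS4class{MeasureSeries}.
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @return data.frame with columns video_id, section, frame_index,
#'   measure, value.
#' @export
as.data.frame.MeasureSeries <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  n <- length(x@frameIndex)
  p <- ncol(x@measures)
  data.frame(
    video_id = rep(x@videoId, n * p),
    section = rep(x@section, n * p),
    frame_index = rep(x@frameIndex, times = p),
    measure = rep(colnames(x@measures), each = n),
    value = as.vector(x@measures),
    stringsAsFactors = FALSE)
}

setMethod("show", "LandmarkFrame", function(object) {
  cat("LandmarkFrame | frame", object@frameIndex,
      if (object@valid) "(valid)" else "(invalid)",
      "|", length(object@landmarkId), "landmarks\n")
})

setMethod("show", "LandmarkStream", function(object) {
  s <- object@sections
  cat("LandmarkStream", object@videoId,
      "| subject", object@subjectId,
      "|", length(object@frames), "frames,",
      sprintf("%.1f%% valid", 100 * validFraction(object)), "\n")
  cat("  SI [", s@siStart, ",", s@siEnd, "]",
      if (!is.na(s@siiStart))
        paste0(" SII [", s@siiStart, ",", s@siiEnd, "]")
      else " (no SII)", "\n", sep = "")
})

setMethod("show", "LandmarkMap", function(object) {
  cat("LandmarkMap |", length(landmarkIds(object)), "distinct landmarks in",
      length(object@regions), "regions\n")
  for (nm in names(object@regions))
    cat("  ", nm, ": ", paste(object@regions[[nm]], collapse = " "),
        "\n", sep = "")
})

setMethod("show", "MeasureSeries", function(object) {
  cat("MeasureSeries", object@videoId, "| section", object@section,
      "|", length(object@frameIndex), "frames retained,",
      object@nDropped, "degenerate dropped\n")
  if (length(object@frameIndex))
    print(round(rbind(mean = colMeans(object@measures),
                      sd = apply(object@measures, 2, stats::sd)), 4))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix |", nrow(object@features), "videos x",
      ncol(object@features), "measure-SD features |",
      object@nDropped, "dropped\n")
  cat("  tastes:", paste(sprintf("%s=%d", levels(object@taste),
                                 tabulate(object@taste)), collapse = " "),
      "\n")
})

setMethod("show", "ImportanceRanking", function(object) {
  cat("ImportanceRanking (", object@method, ")",
      if (length(object@seeds)) paste0(" over ", length(object@seeds),
                                       " seeds"), "\n", sep = "")
  print(data.frame(rank = seq_along(object@measure),
                   measure = object@measure,
                   weight = round(object@weight, 4)), row.names = FALSE)
})

setMethod("show", "HedonicModel", function(object) {
  cat("HedonicModel: per-taste score distributions (1..5)\n")
  print(round(object@probs, 3))
})
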