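#' @rdname accessors
#' @export
setGeneric("landmarkIds", function(x, ...) standardGeneric("landmarkIds"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x, ...) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("sections", function(x, ...) standardGeneric("sections"))

#' @rdname accessors
#' @export
setGeneric("videoId", function(x, ...) standardGeneric("videoId"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x, ...) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("validFraction", function(x, ...) standardGeneric("validFraction"))

#' @rdname accessors
#' @export
setGeneric("mapRegion", function(x, region, ...) standardGeneric("mapRegion"))

#' @rdname accessors
#' @export
setGeneric("measures", function(x, ...) standardGeneric("measures"))

#' @rdname accessors
#' @export
setGeneric("features", function(x, ...) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("importanceWeights", function(x, ...)
  standardGeneric("importanceWeights"))
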