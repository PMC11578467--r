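#' Construct a LandmarkMap from named index sets
#'
#' @param regions named list of integer vectors; required names are
#'   left/right_eyebrow (5 ids each, inner to outer), left/right_eye_contour
#'   (ordered closed polygons, >= 4 ids), nose_tip,
#'   left/right_inner_eye_corner, left/right_mouth_corner, upper_mid_lip,
#'   lower_mid_lip (single ids).
#' @return A \linkS4class{LandmarkMap}.
#' @export
LandmarkMap <- function(regions) {
  regions <- lapply(regions, function(v) as.integer(v))
  new("LandmarkMap", regions = regions[.mapRegionNames])
}

#' The default 53-landmark map
#'
#' Reads the map shipped with the package: 53 distinct mesh indices
#' outlining the eyebrows, eye contours, nose tip, inner eye corners,
#' mouth corners and mid-lip points. The index values are
#' estimator-flavoured but approximate — no authoritative list of the
#' region indices exists — so the map is data, not code: copy and edit the
#' JSON file to match your estimator, then load it with
#' \code{\link{readLandmarkMap}}.
#'
#' @return A \linkS4class{LandmarkMap} with 53 distinct ids.
#' @examples
#' map <- defaultLandmarkMap()
#' length(landmarkIds(map))  # 53
#' @export
defaultLandmarkMap <- function() {
  path <- system.file("extdata", "landmark_map_default.json",
                      package = "TasteFace", mustWork = TRUE)
  readLandmarkMap(path)
}

#' Read a LandmarkMap from a JSON config file
#'
#' @param path JSON file with one array of integer indices per region
#'   (keys as in \code{\link{LandmarkMap}}); keys starting with "_" are
#'   ignored as comments.
#' @return A \linkS4class{LandmarkMap}.
#' @export
readLandmarkMap <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw), "_")]
  LandmarkMap(raw)
}

#' Write a LandmarkMap to a JSON config file
#'
#' @param map a \linkS4class{LandmarkMap}.
#' @param path output file path.
#' @export
writeLandmarkMap <- function(map, path) {
  jsonlite::write_json(map@regions, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
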