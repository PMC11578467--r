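#' Published cohort bookkeeping constants
#'
#' The study cohort's printed age-frequency distribution and per-taste
#' completeness counts, used as generator defaults and for demographic
#' arithmetic checks.
#'
#' \code{studyAgeCounts()} returns the number of children at each age in
#' years (64 children aged 5 to 11). \code{studyVideoCounts()} returns the
#' number of analysable videos received per taste strip (197 in total from
#' 64 participants, each of whom contributed one hedonic rating per strip,
#' 256 ratings in all).
#'
#' @return A named integer vector (names = ages, or taste levels).
#' @examples
#' sum(studyAgeCounts())    # 64 children
#' sum(studyVideoCounts())  # 197 videos
#' @export
studyAgeCounts <- function() {
  c(`5` = 1L, `6` = 3L, `7` = 10L, `8` = 18L, `9` = 13L,
    `10` = 11L, `11` = 8L)
}

#' @rdname studyAgeCounts
#' @export
studyVideoCounts <- function() {
  c(control = 51L, sour = 46L, sweet = 54L, bitter = 46L)
}

#' The twelve facial measures, in canonical column order
#'
#' Six measure families, each with its left/right (or upper/lower)
#' variants, from the observer's point of view:
#' eyebrow elevation (distance from the coordinate-wise median of the five
#' eyebrow landmarks to the nose tip), eyebrow tilt (angle between the
#' fitted eyebrow line and the inner-eye-corner line), eyebrow shape
#' (interior angle at the middle eyebrow landmark), palpebral aperture
#' (area of the eye-contour polygon), lip elevation (mid-lip to nose tip
#' distance) and mouth corner (mouth-corner to nose tip distance).
#' Distances are scaled by the per-frame reference distance (right inner
#' eye corner to nose tip), apertures by its square; angles are in degrees.
#'
#' @return Character vector of the 12 measure names in fixed order.
#' @export
measureNames <- function() {
  c("eyebrow_elevation_L", "eyebrow_elevation_R",
    "eyebrow_tilt_L", "eyebrow_tilt_R",
    "eyebrow_shape_L", "eyebrow_shape_R",
    "palpebral_aperture_L", "palpebral_aperture_R",
    "lip_elevation_upper", "lip_elevation_lower",
    "mouth_corner_L", "mouth_corner_R")
}
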