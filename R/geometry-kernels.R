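## Vectorised geometry kernels. Every kernel operates on coordinate
## matrices X, Y (and Z in 3D mode) of dimension nFrames x nLandmarks so
## whole streams are processed without per-frame R loops. Column indices
## come from matching the map's region ids against the canonical id order.
## All angle/area constructs are taken in the x-y image plane; the 3D
## switch affects distance measures only.

.rad2deg <- 180 / pi

.rowMedian <- function(m) {
  ## coordinate-wise median over a small fixed number of columns
  apply(m, 1L, stats::median)
}

.kDistance <- function(X, Y, Z, i, j, mode) {
  d2 <- (X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2
  if (mode == "3d") d2 <- d2 + (Z[, i] - Z[, j])^2
  sqrt(d2)
}

.kReference <- function(X, Y, Z, cols, mode) {
  .kDistance(X, Y, Z, cols$right_inner_eye_corner, cols$nose_tip, mode)
}

## The coordinate-wise median is taken in the face-intrinsic frame whose
## x-axis is the inner-eye-corner line: a plain image-plane median would
## not be rotation-equivariant, and the measure must be similarity
## invariant.
.kEyebrowElevation <- function(X, Y, Z, cols, side, mode) {
  b <- cols[[paste0(side, "_eyebrow")]]
  th <- atan2(Y[, cols$right_inner_eye_corner] -
                Y[, cols$left_inner_eye_corner],
              X[, cols$right_inner_eye_corner] -
                X[, cols$left_inner_eye_corner])
  ct <- cos(th); st <- sin(th)
  bx <- X[, b, drop = FALSE]; by <- Y[, b, drop = FALSE]
  mx <- .rowMedian(ct * bx + st * by)
  my <- .rowMedian(-st * bx + ct * by)
  nx <- ct * X[, cols$nose_tip] + st * Y[, cols$nose_tip]
  ny <- -st * X[, cols$nose_tip] + ct * Y[, cols$nose_tip]
  d2 <- (mx - nx)^2 + (my - ny)^2
  if (mode == "3d") {
    mz <- .rowMedian(Z[, b, drop = FALSE])
    d2 <- d2 + (mz - Z[, cols$nose_tip])^2
  }
  sqrt(d2)
}

## Total-least-squares (principal-axis) line through the five brow points,
## against the inner-eye-corner line; unsigned angle folded into [0, 90].
.kEyebrowTilt <- function(X, Y, cols, side) {
  b <- cols[[paste0(side, "_eyebrow")]]
  bx <- X[, b, drop = FALSE]; by <- Y[, b, drop = FALSE]
  mx <- rowMeans(bx); my <- rowMeans(by)
  sxx <- rowMeans(bx * bx) - mx * mx
  syy <- rowMeans(by * by) - my * my
  sxy <- rowMeans(bx * by) - mx * my
  thetaB <- 0.5 * atan2(2 * sxy, sxx - syy)
  thetaE <- atan2(Y[, cols$right_inner_eye_corner] -
                    Y[, cols$left_inner_eye_corner],
                  X[, cols$right_inner_eye_corner] -
                    X[, cols$left_inner_eye_corner])
  d <- abs(thetaB - thetaE) * .rad2deg
  d <- d %% 180
  ang <- pmin(d, 180 - d)
  ang[sxx + syy < .Machine$double.eps] <- NaN  # coincident brow points
  ang
}

## Interior angle at the middle (3rd) brow landmark between the segments
## to the two endpoints (1st and 5th), in [0, 180].
.kEyebrowShape <- function(X, Y, cols, side) {
  b <- cols[[paste0(side, "_eyebrow")]]
  ux <- X[, b[1]] - X[, b[3]]; uy <- Y[, b[1]] - Y[, b[3]]
  vx <- X[, b[5]] - X[, b[3]]; vy <- Y[, b[5]] - Y[, b[3]]
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  cosA <- (ux * vx + uy * vy) / (nu * nv)
  ang <- acos(pmin(1, pmax(-1, cosA))) * .rad2deg
  ang[nu < .Machine$double.eps | nv < .Machine$double.eps] <- NaN
  ang
}

## Absolute shoelace area of the ordered closed eye contour polygon.
.kAperture <- function(X, Y, cols, side) {
  p <- cols[[paste0(side, "_eye_contour")]]
  nxt <- c(p[-1], p[1])
  0.5 * abs(rowSums(X[, p, drop = FALSE] * Y[, nxt, drop = FALSE] -
                      X[, nxt, drop = FALSE] * Y[, p, drop = FALSE]))
}

.kLip <- function(X, Y, Z, cols, which, mode) {
  id <- cols[[paste0(which, "_mid_lip")]]
  .kDistance(X, Y, Z, id, cols$nose_tip, mode)
}

.kMouthCorner <- function(X, Y, Z, cols, side, mode) {
  id <- cols[[paste0(side, "_mouth_corner")]]
  .kDistance(X, Y, Z, id, cols$nose_tip, mode)
}

## Resolve map region ids to column positions of the canonical id order.
.mapCols <- function(map, ids) {
  lapply(map@regions, function(v) {
    pos <- match(v, ids)
    if (anyNA(pos))
      stop("map ids absent from frame data: ",
           paste(v[is.na(pos)], collapse = ", "))
    pos
  })
}

## Full 12-measure kernel: returns list(measures = n x 12 matrix,
## reference = numeric n). Reference scaling applied here; callers decide
## what to do with non-positive references.
.kAllMeasures <- function(X, Y, Z, cols, mode = "2d") {
  ref <- .kReference(X, Y, Z, cols, mode)
  m <- cbind(
    eyebrow_elevation_L = .kEyebrowElevation(X, Y, Z, cols, "left", mode) / ref,
    eyebrow_elevation_R = .kEyebrowElevation(X, Y, Z, cols, "right", mode) / ref,
    eyebrow_tilt_L = .kEyebrowTilt(X, Y, cols, "left"),
    eyebrow_tilt_R = .kEyebrowTilt(X, Y, cols, "right"),
    eyebrow_shape_L = .kEyebrowShape(X, Y, cols, "left"),
    eyebrow_shape_R = .kEyebrowShape(X, Y, cols, "right"),
    palpebral_aperture_L = .kAperture(X, Y, cols, "left") / ref^2,
    palpebral_aperture_R = .kAperture(X, Y, cols, "right") / ref^2,
    lip_elevation_upper = .kLip(X, Y, Z, cols, "upper", mode),
    lip_elevation_lower = .kLip(X, Y, Z, cols, "lower", mode),
    mouth_corner_L = .kMouthCorner(X, Y, Z, cols, "left", mode),
    mouth_corner_R = .kMouthCorner(X, Y, Z, cols, "right", mode))
  m[, "lip_elevation_upper"] <- m[, "lip_elevation_upper"] / ref
  m[, "lip_elevation_lower"] <- m[, "lip_elevation_lower"] / ref
  m[, "mouth_corner_L"] <- m[, "mouth_corner_L"] / ref
  m[, "mouth_corner_R"] <- m[, "mouth_corner_R"] / ref
  list(measures = m, reference = ref)
}

## Stack a list of frames (all containing the map ids) into coordinate
## matrices ordered by the canonical sorted id vector.
.framesToArrays <- function(frameList, map) {
  ids <- landmarkIds(map)
  n <- length(frameList)
  X <- matrix(NA_real_, n, length(ids))
  Y <- matrix(NA_real_, n, length(ids))
  Z <- matrix(NA_real_, n, length(ids))
  for (i in seq_len(n)) {
    f <- frameList[[i]]
    pos <- match(ids, f@landmarkId)
    if (anyNA(pos))
      .streamError(sprintf(
        "frame %d lacks landmark id %d required by the map",
        f@frameIndex, ids[which(is.na(pos))[1]]), "missingLandmarkError")
    X[i, ] <- f@coords[pos, 1]
    Y[i, ] <- f@coords[pos, 2]
    Z[i, ] <- f@coords[pos, 3]
  }
  list(X = X, Y = Y, Z = Z, ids = ids,
       frameIndex = vapply(frameList, slot, integer(1),
                           name = "frameIndex"))
}
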