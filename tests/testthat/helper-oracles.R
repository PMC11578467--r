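## Independent oracles: deliberately naive re-derivations (loops, eigen
## decompositions, fan triangulation, direct rank formulas) used only to
## check the package's vectorised implementations.

oDist <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - q[i])^2
  unname(sqrt(s))
}

## coordinate-wise median of an n x 2 point set via sorting
oMedianPoint <- function(pts) {
  c(sort(pts[, 1])[[ceiling(nrow(pts) / 2)]],
    sort(pts[, 2])[[ceiling(nrow(pts) / 2)]])
}

## coordinate-wise median taken in the frame aligned with the
## inner-eye-corner axis, then distance to the nose tip
oEyebrowElevation <- function(brow, nose, cornerL, cornerR, ref) {
  th <- atan2(cornerR[2] - cornerL[2], cornerR[1] - cornerL[1])
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2,
              byrow = TRUE)  # rotation by -th
  browC <- t(R %*% t(brow))
  noseC <- drop(R %*% nose)
  oDist(oMedianPoint(browC), noseC) / ref
}

## principal axis of the 2x2 covariance via eigen(), folded angle vs the
## inner-eye-corner line
oTilt <- function(brow, cornerL, cornerR) {
  S <- stats::cov(brow) * (nrow(brow) - 1) / nrow(brow)
  v <- eigen(S)$vectors[, 1]
  thB <- atan2(v[2], v[1])
  thE <- atan2(cornerR[2] - cornerL[2], cornerR[1] - cornerL[1])
  d <- abs(thB - thE) * 180 / pi
  d <- d %% 180
  unname(min(d, 180 - d))
}

## interior angle via atan2(|cross|, dot) rather than acos
oShape <- function(p1, mid, p5) {
  u <- p1 - mid
  v <- p5 - mid
  cross <- u[1] * v[2] - u[2] * v[1]
  dot <- sum(u * v)
  unname(atan2(abs(cross), dot) * 180 / pi)
}

## polygon area by fan triangulation from the first vertex
oFanArea <- function(poly) {
  a <- 0
  for (i in 2:(nrow(poly) - 1)) {
    u <- poly[i, ] - poly[1, ]
    v <- poly[i + 1, ] - poly[1, ]
    a <- a + (u[1] * v[2] - u[2] * v[1]) / 2
  }
  unname(abs(a))
}

oMovingAverage <- function(v, window) {
  half <- (window - 1) / 2
  out <- numeric(0)
  for (i in seq_along(v))
    if (i - half >= 1 && i + half <= length(v))
      out <- c(out, mean(v[(i - half):(i + half)]))
  out
}

oSD <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

## Kruskal-Wallis H with tie correction, direct formula
oKruskalWallis <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) -
    3 * (N + 1)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  k <- length(unique(groups))
  list(H = H, df = k - 1, p = stats::pchisq(H, k - 1, lower.tail = FALSE))
}

## one-way ANOVA F from explicit sums of squares
oAnovaF <- function(values, groups) {
  gm <- mean(values)
  k <- length(unique(groups))
  N <- length(values)
  ssb <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  Fv <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = Fv, df1 = k - 1, df2 = N - k,
       p = stats::pf(Fv, k - 1, N - k, lower.tail = FALSE))
}

## ---- fixture builders -------------------------------------------------

## a frame with fully random coordinates on all of the map's ids
randomFrame <- function(map, frameIndex = 0L, spread = 1) {
  ids <- landmarkIds(map)
  LandmarkFrame(frameIndex, ids,
                cbind(x = runif(length(ids), -spread, spread),
                      y = runif(length(ids), -spread, spread),
                      z = runif(length(ids), -spread, spread)))
}

## random frame whose nose tip lies on the x = 0.5 midline and whose
## inner eye corners are mirror images, so the facial midline is defined
randomMidlineFrame <- function(map, frameIndex = 0L) {
  f <- randomFrame(map, frameIndex)
  ids <- f@landmarkId
  m <- f@coords
  nose <- match(mapRegion(map, "nose_tip"), ids)
  cl <- match(mapRegion(map, "left_inner_eye_corner"), ids)
  cr <- match(mapRegion(map, "right_inner_eye_corner"), ids)
  m[nose, 1] <- 0.5
  d <- runif(1, 0.05, 0.4)
  ey <- runif(1, -1, 1)
  m[cl, 1:2] <- c(0.5 - d, ey)
  m[cr, 1:2] <- c(0.5 + d, ey)
  LandmarkFrame(frameIndex, ids, m)
}

## mirror a frame across x = 0.5 AND swap the left/right region labels,
## preserving within-region point order
mirrorFrame <- function(frame, map) {
  ids <- frame@landmarkId
  m <- frame@coords
  out <- m
  out[, 1] <- 1 - m[, 1]
  swap <- list(c("left_eyebrow", "right_eyebrow"),
               c("left_eye_contour", "right_eye_contour"),
               c("left_inner_eye_corner", "right_inner_eye_corner"),
               c("left_mouth_corner", "right_mouth_corner"))
  res <- out
  for (pair in swap) {
    a <- match(mapRegion(map, pair[1]), ids)
    b <- match(mapRegion(map, pair[2]), ids)
    res[a, ] <- out[b, ]
    res[b, ] <- out[a, ]
  }
  LandmarkFrame(frame@frameIndex, ids, res)
}

## apply translation + in-plane rotation + uniform scaling to a frame
similarityTransform <- function(frame, angleDeg, scale, tx, ty) {
  th <- angleDeg * pi / 180
  m <- frame@coords
  x <- scale * (cos(th) * m[, 1] - sin(th) * m[, 2]) + tx
  y <- scale * (sin(th) * m[, 1] + cos(th) * m[, 2]) + ty
  LandmarkFrame(frame@frameIndex, frame@landmarkId,
                cbind(x = x, y = y, z = scale * m[, 3]))
}

## a tiny hand-built stream: nFrames copies of a frame, SI/SII annotated
constantStream <- function(frame, nFrames = 10L, siEnd = NULL,
                           invalidAt = integer(0),
                           videoId = "fix", subjectId = "sub") {
  if (is.null(siEnd)) siEnd <- nFrames %/% 2 - 1L
  fr <- lapply(seq_len(nFrames) - 1L, function(t) {
    if (t %in% invalidAt) LandmarkFrame(t, valid = FALSE)
    else LandmarkFrame(t, frame@landmarkId, frame@coords)
  })
  LandmarkStream(videoId, subjectId, fr,
                 SectionAnnotation(0L, siEnd, siEnd + 1L, nFrames - 1L))
}

## minimal valid session-record data.frame
sessionRows <- function(n = 4L, subject = "S001",
                        tastes = tasteLevels()[seq_len(n)],
                        scores = rep(3L, n)) {
  data.frame(subject_id = subject, age = 8L, sex = "female",
             taste = tastes, order_sequence = "sweet-sour-bitter",
             hedonic_score = scores,
             video_id = paste0(subject, "_", tastes),
             si_start = 0L, si_end = 4L, sii_start = 5L, sii_end = 9L,
             stringsAsFactors = FALSE)
}

frameCoords <- function(frame, id) {
  unname(frame@coords[match(id, frame@landmarkId), 1:2])
}
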