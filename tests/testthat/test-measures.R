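## A small map whose geometry is easy to position by hand: the single-id
## regions and 5-point brows keep their roles, eye contours are 4-point
## polygons.
handMap <- function() {
  LandmarkMap(list(
    left_eyebrow = 1:5, right_eyebrow = 6:10,
    left_eye_contour = 11:14, right_eye_contour = 15:18,
    nose_tip = 19L, left_inner_eye_corner = 20L,
    right_inner_eye_corner = 21L, left_mouth_corner = 22L,
    right_mouth_corner = 23L, upper_mid_lip = 24L, lower_mid_lip = 25L))
}

## place named coordinates on the hand map; everything defaults to a
## non-degenerate scatter so the reference is well defined
handFrame <- function(..., ref = c(3, 4)) {
  ids <- 1:25
  set.seed(99)
  m <- cbind(x = runif(25, 2, 3), y = runif(25, 2, 3), z = 0)
  m[19, 1:2] <- c(0, 0)       # nose tip at origin
  m[21, 1:2] <- ref           # right inner corner: reference = |ref|
  m[20, 1:2] <- c(-ref[1], ref[2])
  over <- list(...)
  for (k in names(over))
    m[as.integer(k), seq_along(over[[k]])] <- over[[k]]
  LandmarkFrame(0L, ids, m)
}

test_that("reference distance follows the 3-4-5 triangle and flags
          coincident landmarks", {
  map <- handMap()
  expect_equal(referenceDistance(handFrame(), map), 5)
  degen <- handFrame(`21` = c(0, 0))
  expect_error(referenceDistance(degen, map),
               class = "degenerateFrameError")
})

test_that("eyebrow elevation is the scaled median-to-nose distance", {
  map <- handMap()
  ## all five left-brow points at (0, 5): distance 5, reference 5 -> 1
  f <- handFrame(`1` = c(0, 5), `2` = c(0, 5), `3` = c(0, 5),
                 `4` = c(0, 5), `5` = c(0, 5))
  expect_equal(eyebrowElevation(f, map, "L"), 1)
  ## doubling every coordinate leaves the scaled measure unchanged
  doubled <- LandmarkFrame(0L, f@landmarkId, f@coords * 2)
  expect_equal(eyebrowElevation(doubled, map, "L"), 1)
})

test_that("eyebrow tilt matches hand-set angles", {
  map <- handMap()
  ## brow on a horizontal line, corner line horizontal -> 0 degrees
  flat <- handFrame(`1` = c(1, 7), `2` = c(2, 7), `3` = c(3, 7),
                    `4` = c(4, 7), `5` = c(5, 7), ref = c(4, 0))
  expect_equal(eyebrowTilt(flat, map, "L"), 0, tolerance = 1e-9)
  ## brow on y = x against a horizontal corner line -> 45 degrees
  diag <- handFrame(`1` = c(1, 1), `2` = c(2, 2), `3` = c(3, 3),
                    `4` = c(4, 4), `5` = c(5, 5), ref = c(4, 0))
  expect_equal(eyebrowTilt(diag, map, "L"), 45, tolerance = 1e-9)
  coincident <- handFrame(`1` = c(1, 1), `2` = c(1, 1), `3` = c(1, 1),
                          `4` = c(1, 1), `5` = c(1, 1))
  expect_error(eyebrowTilt(coincident, map, "L"),
               class = "undefinedFitError")
})

test_that("eyebrow shape is the interior angle at the middle landmark", {
  map <- handMap()
  collinear <- handFrame(`1` = c(1, 7), `2` = c(2, 7), `3` = c(3, 7),
                         `4` = c(4, 7), `5` = c(5, 7))
  expect_equal(eyebrowShape(collinear, map, "L"), 180)
  right <- handFrame(`1` = c(-1, 0), `3` = c(0, 1), `5` = c(1, 0))
  expect_equal(eyebrowShape(right, map, "L"), 90)
  degenerate <- handFrame(`1` = c(1, 1), `3` = c(1, 1))
  expect_error(eyebrowShape(degenerate, map, "L"),
               class = "undefinedAngleError")
})

test_that("palpebral aperture is the reference-squared-scaled shoelace
          area", {
  map <- handMap()
  sq <- handFrame(`11` = c(0, 0), `12` = c(1, 0), `13` = c(1, 1),
                  `14` = c(0, 1), ref = c(1, 0))
  expect_equal(palpebralAperture(sq, map, "L"), 1)
  ## doubling the reference divides the aperture by 4
  sq2 <- handFrame(`11` = c(0, 0), `12` = c(1, 0), `13` = c(1, 1),
                   `14` = c(0, 1), ref = c(2, 0))
  expect_equal(palpebralAperture(sq2, map, "L"), 0.25)
})

test_that("lip elevation and mouth corner are scaled nose distances", {
  map <- handMap()
  f <- handFrame(`25` = c(0, -2), `22` = c(1, -1), ref = c(1, 0))
  expect_equal(lipElevation(f, map, "lower"), 2)
  expect_equal(mouthCorner(f, map, "L"), sqrt(2))
  ## translation invariance
  shifted <- LandmarkFrame(0L, f@landmarkId,
                           sweep(f@coords, 2, c(10, -3, 2), "+"))
  expect_equal(lipElevation(shifted, map, "lower"), 2, tolerance = 1e-9)
  expect_equal(mouthCorner(shifted, map, "L"), sqrt(2), tolerance = 1e-9)
})

test_that("every operation matches its independent oracle on random
          frames", {
  set.seed(101)
  map <- defaultLandmarkMap()
  for (rep in 1:200) {
    f <- randomFrame(map)
    ids <- f@landmarkId
    xy <- f@coords[, 1:2]
    at <- function(region) xy[match(mapRegion(map, region), ids), ,
                              drop = FALSE]
    nose <- drop(at("nose_tip"))
    ref <- oDist(drop(at("right_inner_eye_corner")), nose)
    expect_equal(referenceDistance(f, map), ref, tolerance = 1e-9)
    expect_equal(eyebrowElevation(f, map, "L"),
                 oEyebrowElevation(at("left_eyebrow"), nose,
                                   drop(at("left_inner_eye_corner")),
                                   drop(at("right_inner_eye_corner")),
                                   ref),
                 tolerance = 1e-9)
    expect_equal(eyebrowTilt(f, map, "R"),
                 oTilt(at("right_eyebrow"),
                       drop(at("left_inner_eye_corner")),
                       drop(at("right_inner_eye_corner"))),
                 tolerance = 1e-9)
    brow <- at("left_eyebrow")
    expect_equal(eyebrowShape(f, map, "L"),
                 oShape(brow[1, ], brow[3, ], brow[5, ]),
                 tolerance = 1e-9)
    expect_equal(palpebralAperture(f, map, "R"),
                 oFanArea(at("right_eye_contour")) / ref^2,
                 tolerance = 1e-9)
    expect_equal(lipElevation(f, map, "upper"),
                 oDist(drop(at("upper_mid_lip")), nose) / ref,
                 tolerance = 1e-9)
    expect_equal(mouthCorner(f, map, "R"),
                 oDist(drop(at("right_mouth_corner")), nose) / ref,
                 tolerance = 1e-9)
  }
})

test_that("all measures are similarity invariant", {
  set.seed(102)
  map <- defaultLandmarkMap()
  for (rep in 1:20) {
    f <- randomFrame(map)
    g <- similarityTransform(f, angleDeg = runif(1, -180, 180),
                             scale = runif(1, 0.3, 3),
                             tx = runif(1, -5, 5), ty = runif(1, -5, 5))
    expect_equal(measureVector(g, map), measureVector(f, map),
                 tolerance = 1e-6)
  }
})

test_that("mirroring across the facial midline swaps the sided
          measures", {
  set.seed(103)
  map <- defaultLandmarkMap()
  swapped <- c(eyebrow_elevation_L = "eyebrow_elevation_R",
               eyebrow_elevation_R = "eyebrow_elevation_L",
               eyebrow_tilt_L = "eyebrow_tilt_R",
               eyebrow_tilt_R = "eyebrow_tilt_L",
               eyebrow_shape_L = "eyebrow_shape_R",
               eyebrow_shape_R = "eyebrow_shape_L",
               palpebral_aperture_L = "palpebral_aperture_R",
               palpebral_aperture_R = "palpebral_aperture_L",
               lip_elevation_upper = "lip_elevation_upper",
               lip_elevation_lower = "lip_elevation_lower",
               mouth_corner_L = "mouth_corner_R",
               mouth_corner_R = "mouth_corner_L")
  for (rep in 1:20) {
    f <- randomMidlineFrame(map)
    m <- measureVector(f, map)
    mm <- measureVector(mirrorFrame(f, map), map)
    expect_equal(unname(mm[swapped[names(m)]]), unname(m),
                 tolerance = 1e-9)
  }
})

test_that("measure series are constant for a constant face and scale
          invariant under zoom drift", {
  map <- defaultLandmarkMap()
  tpl <- neutralFaceTemplate(map)
  st <- constantStream(tpl, nFrames = 12L)
  s <- computeMeasureSeries(st, map)
  expect_identical(length(s), 12L)
  expect_true(all(apply(measures(s), 2, function(v)
    max(abs(v - v[1]))) < 1e-12))

  ## inject a smooth 2x zoom: all coordinates scaled per frame
  n <- 20L
  zoomFrames <- lapply(seq_len(n) - 1L, function(t) {
    sc <- 1 + t / (n - 1)            # 1 -> 2
    LandmarkFrame(t, tpl@landmarkId, tpl@coords * sc)
  })
  zoom <- LandmarkStream("zoom", "s", zoomFrames,
                         SectionAnnotation(0L, n %/% 2 - 1L,
                                           n %/% 2, n - 1L))
  sz <- computeMeasureSeries(zoom, map)
  drift <- apply(measures(sz), 2, function(v) max(abs(v - v[1])))
  expect_true(all(drift < 1e-6))
})

test_that("degenerate frames are dropped and counted", {
  map <- defaultLandmarkMap()
  tpl <- neutralFaceTemplate(map)
  ids <- tpl@landmarkId
  bad <- tpl@coords
  bad[] <- rep(c(0.5, 0.5, 0), each = nrow(bad))  # all points coincide
  frames <- c(lapply(0:3, function(t)
    LandmarkFrame(t, ids, tpl@coords)),
    list(LandmarkFrame(4L, ids, bad)),
    lapply(5:9, function(t) LandmarkFrame(t, ids, tpl@coords)))
  st <- LandmarkStream("deg", "s", frames,
                       SectionAnnotation(0L, 4L, 5L, 9L))
  expect_warning(s <- computeMeasureSeries(st, map), "degenerate")
  expect_identical(length(s), 9L)
  expect_identical(s@nDropped, 1L)
  expect_false(4L %in% s@frameIndex)
})

test_that("the moving average is centred, shortening and matches the
          naive oracle", {
  map <- defaultLandmarkMap()
  tpl <- neutralFaceTemplate(map)
  st <- constantStream(tpl, nFrames = 10L)
  s <- computeMeasureSeries(st, map)
  expect_equal(measures(movingAverage(s, 5L)),
               measures(s)[3:8, ], tolerance = 1e-12)
  expect_identical(movingAverage(s, 1L), s)
  expect_error(movingAverage(s, 4L), "odd")
  expect_error(movingAverage(s, 11L), "length")

  ## [1..5] with window 5 -> single value 3; random series vs oracle
  set.seed(104)
  g <- generateStream(nFrames = 40L, seed = 5, invalidFraction = 0)
  sr <- computeMeasureSeries(g$stream, map)
  sm <- movingAverage(sr, 3L)
  for (mn in c("eyebrow_elevation_L", "palpebral_aperture_R"))
    expect_equal(unname(measures(sm)[, mn]),
                 oMovingAverage(measures(sr)[, mn], 3L),
                 tolerance = 1e-12)
  five <- measures(sr)[1:5, "mouth_corner_L"]
  expect_equal(oMovingAverage(five, 5L), mean(five))
})

test_that("empty sections yield an empty-series signal", {
  map <- defaultLandmarkMap()
  st <- constantStream(neutralFaceTemplate(map), nFrames = 10L,
                       invalidAt = 0:4)  # SI entirely invalid
  expect_warning(s <- computeMeasureSeries(st, map, section = "SI"),
                 "no retained frames")
  expect_identical(length(s), 0L)
})
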