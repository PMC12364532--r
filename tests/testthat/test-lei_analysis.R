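test_that("calibration is physical length over pixel length", {
  expect_equal(calibrate(100, 10), 0.1)
  expect_equal(calibrate(1, 1), 1)
  expect_error(calibrate(0, 10), "positive")
  expect_error(calibrate(100, -1), "positive")
})

test_that("the radius is a quarter of the summed ellipse axes", {
  expect_equal(radiusFromAxes(20, 20), 10)
  expect_equal(radiusFromAxes(24, 16), 10)
  expect_error(radiusFromAxes(0, 0), "degenerate")
  expect_error(radiusFromAxes(10, 20), "major >= minor")
})

test_that("the elevation index is the arctangent of h over r, in degrees", {
  expect_equal(computeLEI(5, 5), 45)
  expect_equal(computeLEI(0, 7.3), 0)
  expect_equal(computeLEI(8.6602540, 5), 60, tolerance = 1e-6)
  expect_error(computeLEI(5, 0), "positive")
  expect_error(computeLEI(-1, 5), "non-negative")
})

test_that("the index rises with height and falls with radius", {
  h <- seq(0.5, 20, length.out = 25)
  expect_true(all(diff(computeLEI(h, 7)) > 0))
  r <- seq(0.5, 20, length.out = 25)
  expect_true(all(diff(computeLEI(7, r)) < 0))
})

test_that("swapping h and r complements the angle to 90 degrees", {
  set.seed(2)
  h <- runif(40, 0.01, 50); r <- runif(40, 0.01, 50)
  expect_equal(computeLEI(h, r) + computeLEI(r, h), rep(90, 40),
               tolerance = 1e-9)
})

test_that("a rendered series is measured within two degrees of truth", {
  dir <- withr::local_tempdir()
  thetas <- c(10, 30, 50)
  for (i in seq_along(thetas)) {
    sc <- renderScene(SceneParams(elevationDeg = thetas[i]))
    t <- 30 * (i - 1)
    png::writePNG(framePixels(sc$top),
                  file.path(dir, sprintf("p01_top_%04d.png", t)))
    png::writePNG(framePixels(sc$side),
                  file.path(dir, sprintf("p01_side_%04d.png", t)))
  }
  idx <- indexSeries(dir, 30)
  rec <- buildRecords(idx, SegmentationParams(), linePosition = 240,
                      cal = Calibration(0.15), logFun = NULL)
  expect_equal(nrow(rec), 3L)
  expect_true(all(abs(rec$lei_deg - thetas) <= 2))
  expect_equal(rec$mm_per_px_top, rep(0.15, 3))

  # blank one side view: two records survive, one skip is reported
  png::writePNG(array(0, dim = c(280, 280, 3)),
                file.path(dir, "p01_side_0030.png"))
  rec <- buildRecords(indexSeries(dir, 30), SegmentationParams(),
                      linePosition = 240, cal = Calibration(0.15),
                      logFun = NULL)
  expect_equal(nrow(rec), 2L)
  skips <- attr(rec, "skips")
  expect_equal(nrow(skips), 1L)
  expect_equal(skips$timestamp_min, 30)
  expect_match(skips$reason, "side")
})

test_that("a series without complete pairs yields an empty table and a warning", {
  dir <- withr::local_tempdir()
  writeTinyFrame(dir, "a", "top", 0)
  idx <- indexSeries(dir, 30)
  expect_warning(
    rec <- buildRecords(idx, SegmentationParams(), 100,
                        Calibration(0.1), logFun = NULL),
    "no complete")
  expect_equal(nrow(rec), 0L)
})

test_that("group aggregation computes the textbook SEM", {
  rec <- data.frame(plant_id = rep(c("a", "b", "c"), 2),
                    timestamp_min = rep(c(0, 30), each = 3),
                    lei_deg = c(1, 2, 3, 2, 4, 6))
  g <- aggregateGroup(rec, "grp", onsetMin = 0)
  expect_equal(g$sem_deg[1], 1 / sqrt(3), tolerance = 1e-9)
  expect_equal(g$mean_dlei_deg, c(0, 2))   # mean 4 at 30 min, 2 at onset
  expect_equal(g$n, c(3L, 3L))
})

test_that("normalization pins the onset to exactly zero and is shift invariant", {
  set.seed(5)
  rec <- expand.grid(plant_id = c("a", "b", "c", "d"),
                     timestamp_min = seq(0, 120, 30),
                     stringsAsFactors = FALSE)
  rec$lei_deg <- 20 + 5 * sin(rec$timestamp_min / 40) +
    rnorm(nrow(rec), 0, 1)
  g0 <- aggregateGroup(rec, "g", onsetMin = 0)
  expect_identical(g0$mean_dlei_deg[g0$timestamp_min == 0], 0)

  recShift <- rec; recShift$lei_deg <- rec$lei_deg + 11.3
  gS <- aggregateGroup(recShift, "g", onsetMin = 0)
  expect_equal(gS$mean_dlei_deg, g0$mean_dlei_deg, tolerance = 1e-9)
  expect_equal(gS$sem_deg, g0$sem_deg, tolerance = 1e-9)
})

test_that("constant trajectories normalize to an all-zero course", {
  rec <- expand.grid(plant_id = c("a", "b"),
                     timestamp_min = seq(0, 90, 30),
                     stringsAsFactors = FALSE)
  rec$lei_deg <- ifelse(rec$plant_id == "a", 25, 31)
  g <- aggregateGroup(rec, "g", onsetMin = 0)
  expect_equal(g$mean_dlei_deg, rep(0, 4))
})

test_that("a single-plant timepoint reports SEM zero with a flag", {
  rec <- data.frame(plant_id = c("a", "b", "a"),
                    timestamp_min = c(0, 0, 30),
                    lei_deg = c(10, 12, 15))
  g <- aggregateGroup(rec, "g", onsetMin = 0)
  expect_equal(g$sem_deg[g$timestamp_min == 30], 0)
  expect_equal(g$n[g$timestamp_min == 30], 1L)
  expect_match(attr(g, "flags"), "single plant")
})

test_that("aggregation without an onset record is an error", {
  rec <- data.frame(plant_id = "a", timestamp_min = 30, lei_deg = 10)
  expect_error(aggregateGroup(rec, "g", onsetMin = 0), "onset")
})

test_that("per-plant normalization is available as an option", {
  rec <- data.frame(plant_id = rep(c("a", "b"), each = 2),
                    timestamp_min = rep(c(0, 30), 2),
                    lei_deg = c(10, 15, 30, 33))
  g <- aggregateGroup(rec, "g", onsetMin = 0, normalize = "plant")
  expect_equal(g$mean_dlei_deg, c(0, 4))   # mean of (5, 3)
})
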