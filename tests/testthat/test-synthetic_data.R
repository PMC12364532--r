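test_that("scene truth follows the cylinder formulas exactly", {
  sc <- renderScene(SceneParams(leafLengthMm = 20, elevationDeg = 45,
                                eccentricity = 1, mmPerPxTop = 0.2,
                                mmPerPxSide = 0.2))
  expect_equal(rTrueMm(sc$truth), 20 * cos(pi / 4), tolerance = 1e-9)
  expect_equal(hTrueMm(sc$truth), 20 * sin(pi / 4), tolerance = 1e-9)
  expect_equal(leiTrueDeg(sc$truth), 45, tolerance = 1e-9)
})

test_that("a flat plant renders a degenerate side view with zero index", {
  sc <- renderScene(SceneParams(elevationDeg = 0))
  expect_equal(leiTrueDeg(sc$truth), 0)
  expect_equal(hTrueMm(sc$truth), 0)
  expect_equal(silhouettePxCount(sc$truth)[["side"]], 0L)
})

test_that("an eccentric rosette keeps its truth internally consistent", {
  sc <- renderScene(SceneParams(elevationDeg = 30, eccentricity = 0.8))
  L <- 20; th <- 30 * pi / 180
  expect_equal(rTrueMm(sc$truth), L * cos(th) * 0.9, tolerance = 1e-9)
  expect_equal(leiTrueDeg(sc$truth),
               atan(L * sin(th) / (L * cos(th) * 0.9)) * 180 / pi,
               tolerance = 1e-9)
  expect_gt(leiTrueDeg(sc$truth), 30)  # narrower rosette raises the index

  # rendered ellipse area matches pi * a * b within 1%
  a <- L * cos(th) / 0.15; b <- 0.8 * a
  expect_lte(abs(sum(sc$topMask) - pi * a * b) / (pi * a * b), 0.01)
})

test_that("silhouettes that exceed the frame are an error, never clipped", {
  expect_error(renderScene(SceneParams(leafLengthMm = 50,
                                       elevationDeg = 5)),
               "exceeds")
})

test_that("channel noise stays in range and is reproducible by seed", {
  sc1 <- renderScene(SceneParams(elevationDeg = 40, noiseSd = 0.05,
                                 seed = 9))
  sc2 <- renderScene(SceneParams(elevationDeg = 40, noiseSd = 0.05,
                                 seed = 9))
  expect_identical(framePixels(sc1$top), framePixels(sc2$top))
  expect_gte(min(framePixels(sc1$top)), 0)
  expect_lte(max(framePixels(sc1$top)), 1)
})

test_that("a null response model simulates flat trajectories", {
  m <- ResponseModel(baselineDeg = 20, amplitudeDeg = 0, oscAmpDeg = 0,
                     plantSdDeg = 0, frameSdDeg = 0)
  tr <- simulateTimecourse(m, 3, 360, 30, seed = 1)
  expect_equal(unique(tr$lei_true_deg), 20)
  expect_equal(nrow(tr), 3 * 13)
})

test_that("the same seed reproduces the same trajectories", {
  a <- simulateTimecourse("wt_low", 4, 720, 30, seed = 33)
  b <- simulateTimecourse("wt_low", 4, 720, 30, seed = 33)
  expect_identical(a, b)
  c <- simulateTimecourse("wt_low", 4, 720, 30, seed = 34)
  expect_false(identical(a, c))
})

test_that("a noiseless logistic response rises monotonically to near its amplitude", {
  m <- ResponseModel(baselineDeg = 22, amplitudeDeg = 25,
                     halftimeMin = 300, riseRatePerMin = 0.015,
                     oscAmpDeg = 0, plantSdDeg = 0, frameSdDeg = 0)
  tr <- simulateTimecourse(m, 1, 2160, 30, seed = 1)
  lei <- tr$lei_true_deg
  expect_true(all(diff(lei[seq_len(which.max(lei))]) >= 0))
  expect_gte(max(lei) - 22, 0.95 * 25)
})

test_that("a transient response decays back towards baseline", {
  m <- responsePreset("pif7_low")
  m@plantSdDeg <- 0; m@frameSdDeg <- 0; m@oscAmpDeg <- 0
  tr <- simulateTimecourse(m, 1, 2160, 30, seed = 1)
  lei <- tr$lei_true_deg
  expect_gt(max(lei) - lei[1], 10)              # clear response
  expect_lt(abs(lei[length(lei)] - lei[1]), 2)  # back near baseline
})

test_that("unknown presets fail loudly, known ones are listed", {
  expect_error(responsePreset("superplant"), "wt_low")
  for (p in listPresets()) expect_s4_class(responsePreset(p),
                                           "ResponseModel")
})

test_that("dataset generation writes the promised files deterministically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  m <- responsePreset("wt_low")
  res1 <- generateDataset(m, SceneParams(), nPlants = 2,
                          durationMin = 120, intervalMin = 30,
                          seed = 4, outDir = dir1)
  expect_equal(res1$nImages, 20L)       # 2 plants x 5 timepoints x 2 views
  expect_equal(nrow(res1$truth), 10L)
  expect_true(file.exists(res1$truthCsv))
  expect_setequal(
    list.files(dir1, pattern = "p01_top"),
    sprintf("p01_top_%04d.png", seq(0, 120, 30)))

  res2 <- generateDataset(m, SceneParams(), nPlants = 2,
                          durationMin = 120, intervalMin = 30,
                          seed = 4, outDir = dir2)
  expect_identical(unname(tools::md5sum(res1$truthCsv)),
                   unname(tools::md5sum(res2$truthCsv)))
})

test_that("with a circular rosette the scene angle equals the simulated index", {
  dir <- withr::local_tempdir()
  m <- ResponseModel(baselineDeg = 30, amplitudeDeg = 10, oscAmpDeg = 0,
                     plantSdDeg = 0, frameSdDeg = 0)
  res <- generateDataset(m, SceneParams(eccentricity = 1), nPlants = 1,
                         durationMin = 90, intervalMin = 30, seed = 2,
                         outDir = dir)
  tr <- simulateTimecourse(m, 1, 90, 30, seed = 2)
  expect_equal(res$truth$lei_true_deg, tr$lei_true_deg, tolerance = 1e-9)
})
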