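test_that("moments of tiny hand-computed masks are exact", {
  m <- matrix(FALSE, 10, 10); m[5, 7] <- TRUE
  mm <- maskMoments(m)
  expect_equal(mm@n, 1L)
  expect_equal(mm@centroid, c(5, 7))
  expect_equal(c(mm@mu20, mm@mu02, mm@mu11), c(0, 0, 0))

  # two pixels on one row, two columns apart
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[2, 4] <- TRUE
  mm <- maskMoments(m)
  expect_equal(mm@centroid, c(2, 3))
  expect_equal(mm@mu02, 1)
  expect_equal(mm@mu20, 0)
  expect_equal(mm@mu11, 0)

  expect_error(maskMoments(matrix(FALSE, 3, 3)), "empty mask")
})

test_that("a 101 x 101 filled square has mu20 = mu02 = 850, mu11 = 0", {
  m <- matrix(TRUE, 101, 101)
  mm <- maskMoments(m)
  expect_equal(mm@mu20, 850)             # (101^2 - 1) / 12
  expect_equal(mm@mu02, 850)
  expect_equal(mm@mu11, 0)
  ref <- naiveMoments(m)
  expect_equal(mm@mu20, ref$mu20, tolerance = 1e-12)
})

test_that("moments agree with the double-loop oracle on random masks", {
  set.seed(42)
  for (i in 1:10) {
    H <- sample(10:80, 1); W <- sample(10:80, 1)
    m <- matrix(runif(H * W) > 0.7, H, W)
    if (!any(m)) m[1, 1] <- TRUE
    mm <- maskMoments(m)
    ref <- naiveMoments(m)
    expect_equal(mm@n, ref$n)
    expect_equal(mm@centroid, ref$centroid, tolerance = 1e-9)
    expect_equal(mm@mu20, ref$mu20, tolerance = 1e-9)
    expect_equal(mm@mu02, ref$mu02, tolerance = 1e-9)
    expect_equal(mm@mu11, ref$mu11, tolerance = 1e-9)
  }
})

test_that("the moment ellipse of a disc recovers the diameter", {
  m <- rasterDisc(201, 201, 101, 101, 50)
  fit <- fitEllipse(m)
  expect_lt(abs(majorAxisPx(fit) - 100) / 100, 0.01)
  expect_lt(abs(minorAxisPx(fit) - 100) / 100, 0.01)
})

test_that("the moment ellipse recovers axes and orientation of ellipses", {
  m <- rasterEllipse(201, 301, 101, 151, 60, 30)
  fit <- fitEllipse(m)
  expect_lt(abs(majorAxisPx(fit) - 120) / 120, 0.01)
  expect_lt(abs(minorAxisPx(fit) - 60) / 60, 0.01)
  expect_lt(abs(orientationRad(fit)) * 180 / pi, 1)

  rot <- rasterEllipse(301, 301, 151, 151, 60, 30, phiDeg = 30)
  fitR <- fitEllipse(rot)
  expect_lt(abs(majorAxisPx(fitR) - majorAxisPx(fit)) / 120, 0.01)
  expect_lt(abs(minorAxisPx(fitR) - minorAxisPx(fit)) / 60, 0.01)
  expect_lt(axialDiffDeg(orientationRad(fitR) * 180 / pi, 30), 1)
})

test_that("collinear masks are degenerate, not an error", {
  m <- matrix(FALSE, 20, 20); m[5, 3:17] <- TRUE
  fit <- fitEllipse(m)
  expect_true(fit@degenerate)
  expect_equal(minorAxisPx(fit), 0)
  expect_gt(majorAxisPx(fit), 0)
})

test_that("ellipse axes are translation invariant and bounded by the bbox diagonal", {
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(FALSE, 60, 60)
    m[sample(15:45, 40, TRUE) + 60 * (sample(15:45, 40, TRUE) - 1)] <- TRUE
    fit <- fitEllipse(m)
    shifted <- matrix(FALSE, 60, 60)
    shifted[11:60, 11:60] <- m[1:50, 1:50]
    # shift keeps all foreground if it sat within rows/cols 15:45
    fitS <- fitEllipse(shifted)
    expect_equal(majorAxisPx(fitS), majorAxisPx(fit), tolerance = 1e-12)
    expect_equal(minorAxisPx(fitS), minorAxisPx(fit), tolerance = 1e-12)

    coords <- which(m, arr.ind = TRUE)
    diag <- sqrt(diff(range(coords[, 1]))^2 + diff(range(coords[, 2]))^2)
    expect_lte(minorAxisPx(fit), majorAxisPx(fit))
    expect_lte(majorAxisPx(fit), diag + 1e-9)
  }
})

test_that("ellipse axes are rotation invariant within 1.5%", {
  for (phi in c(15, 45, 72)) {
    base <- rasterEllipse(301, 301, 151, 151, 50, 25)
    rot <- rasterEllipse(301, 301, 151, 151, 50, 25, phiDeg = phi)
    f0 <- fitEllipse(base); f1 <- fitEllipse(rot)
    expect_lt(abs(majorAxisPx(f1) - majorAxisPx(f0)) / majorAxisPx(f0),
              0.015)
    expect_lt(abs(minorAxisPx(f1) - minorAxisPx(f0)) / minorAxisPx(f0),
              0.015)
  }
})

test_that("height is the row distance from the highest pixel to the soil line", {
  m <- matrix(FALSE, 200, 100); m[20:150, 40:60] <- TRUE
  hm <- measureHeight(m, linePosition = 100)
  expect_equal(heightPx(hm), 80)
  expect_equal(hm@topRow, 20)

  # everything at or below the line: flagged zero, not an error
  low <- matrix(FALSE, 200, 100); low[120:150, 40:60] <- TRUE
  hm <- measureHeight(low, linePosition = 100)
  expect_equal(heightPx(hm), 0)
  expect_true(hm@flagged)

  expect_error(measureHeight(matrix(FALSE, 10, 10), 5), "empty mask")
})

test_that("pixels below the line are ignored only when clipping is on", {
  m <- matrix(FALSE, 200, 100)
  m[120:130, 40:60] <- TRUE               # below the line
  hm <- measureHeight(m, 100, clipBelowLine = FALSE)
  expect_equal(heightPx(hm), 0)           # max(0, 100 - 120)
  expect_false(hm@flagged)
})

test_that("rendered side silhouettes give the apex height within one pixel", {
  # pick theta so the apex sits 120 px above the soil row at 0.15 mm/px
  th <- asin(120 * 0.15 / 20) * 180 / pi
  sc <- renderScene(SceneParams(leafLengthMm = 20, elevationDeg = th))
  hm <- measureHeight(sc$sideMask, linePosition = 240)
  expect_lte(abs(heightPx(hm) - 120), 1)
})

test_that("adding a pixel above the top never decreases height", {
  m <- matrix(FALSE, 100, 50); m[40:60, 20:30] <- TRUE
  h0 <- heightPx(measureHeight(m, 90))
  for (r in c(35, 20, 5)) {
    m[r, 25] <- TRUE
    expect_gte(heightPx(measureHeight(m, 90)), h0)
    h0 <- heightPx(measureHeight(m, 90))
  }
})
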