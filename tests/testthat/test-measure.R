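test_that("polygon areas match closed forms", {
  expect_equal(contourAreaPx(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1.0)
  expect_equal(contourAreaPx(rbind(c(0, 0), c(2, 0), c(0, 2))), 2.0)
  th <- seq(0, 2 * pi, length.out = 1025)[-1025]
  gon <- cbind(10 * cos(th), 10 * sin(th))
  expect_lt(abs(contourAreaPx(gon) - pi * 100) / (pi * 100), 0.001)
  # orientation independence
  expect_equal(contourAreaPx(gon[rev(seq_len(1024)), ]), contourAreaPx(gon))
})

test_that("self-intersecting polygons are rejected", {
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(contourAreaPx(bow), "self-intersecting")
})

test_that("pixel-to-physical conversion and error rates are exact", {
  expect_equal(toCm2(40000, 0.005), 1.0)
  expect_equal(toCm2(0, 0.01), 0)
  expect_equal(toCm2(125664, 0.01), 12.5664)
  expect_error(toCm2(100, -1), "positive")
  expect_equal(errorRate(12.57, 12.57), 0)
  expect_equal(errorRate(12.95, 12.57), 3.0231, tolerance = 1e-4)
  expect_equal(errorRate(12.23, 12.57), -2.7048, tolerance = 1e-4)
  expect_error(errorRate(1, 0), "positive")
  # linear in `measured` with slope 100/truth
  expect_equal(errorRate(15, 10) - errorRate(12, 10), (15 - 12) * 100 / 10)
})

test_that("L x W baseline reproduces the clinical overestimation factors", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- cbind(3 * cos(th), 3 * sin(th))           # diameter 6
  lw <- lwArea(circ)
  true <- contourAreaPx(circ, checkSimple = FALSE)
  expect_equal(lw / true, 4 / pi, tolerance = 1e-3) # ~1.27: +27%
  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  expect_equal(lwArea(tri) / 2.0, 2.0, tolerance = 1e-9)
  sq <- rbind(c(0, 0), c(3, 0), c(3, 3), c(0, 3))
  expect_equal(lwArea(sq), 9, tolerance = 1e-9)
  expect_error(lwArea(rbind(c(0, 0), c(1, 0), c(2, 0))), "degenerate")
})

test_that("L x W dominates the polygon area for convex wounds", {
  set.seed(8)
  for (i in 1:10) {
    pts <- cbind(runif(30, 0, 10), runif(30, 0, 10))
    hull <- pts[grDevices::chull(pts), ]
    expect_gte(lwArea(hull), contourAreaPx(hull, checkSimple = FALSE))
  }
})

test_that("the full pipeline measures the reference defect model accurately", {
  m <- measureImage(fxRender90(), seed = 1)
  expect_lt(abs(errorRate(m@areaCm2, 12.566)), 1)
  expect_gt(m@lwAreaCm2, m@areaCm2)                 # circle: L x W overshoots
  expect_true(all(c("detect", "rectify", "normalize", "segment", "measure")
                  %in% names(m@stageReport)))
  expect_equal(m@stageReport$detect$status, "ok")
})

test_that("pipeline failures surface the stage name and keep a partial report", {
  noPatch <- array(0.5, c(120, 160, 3))
  m <- measureImage(noPatch)
  expect_true(is.na(m@areaCm2))
  expect_match(m@stageReport$error$message, "patch not detected")
  expect_error(measureImage(noPatch, onError = "stop"), "patch not detected")
})

test_that("validation study is deterministic and within the error envelope", {
  t1 <- runValidationStudy(distances = 40, angles = c(60, 90), nReps = 2L,
                           seed = 3)
  t2 <- runValidationStudy(distances = 40, angles = c(60, 90), nReps = 2L,
                           seed = 3)
  expect_identical(t1, t2)
  expect_true(all(t1$n_ok == 2L))
  expect_lt(max(abs(t1$mean_error_pct)), 3.39)
  # single noise-free cell at (30, 90): error under 1%
  t0 <- runValidationStudy(distances = 30, angles = 90, nReps = 1L,
                           seed = 2, noiseSigma = 0)
  expect_lt(abs(t0$mean_error_pct), 1)
})

test_that("measured cell side recovers the physical 0.7 cm", {
  rect <- rectifyImage(fxRender60(), fxDetect60(), targetPxPerCm = 100)
  cs <- measureCellSideCm(rect)
  expect_lt(abs(cs$cellSideCm - 0.7) / 0.7, 0.02)
  expect_equal(cs$n, 24L)
})
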