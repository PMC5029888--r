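test_that("analytic truth areas are exact for the supported shapes", {
  expect_equal(truthArea(sceneSpec("circle", r = 2)), pi * 4, tolerance = 1e-12)
  expect_equal(truthArea(sceneSpec("circle", r = 2)), 12.566, tolerance = 1e-4)
  # degenerate ellipse a = b = 1 is the unit circle
  expect_equal(truthArea(sceneSpec("ellipse", a = 1, b = 1)), pi,
               tolerance = 1e-12)
})

test_that("blob polygon area matches a rejection-sampling oracle", {
  poly <- blobPolygon(rBase = 2, nVertices = 64L, seed = 7)
  sc <- sceneSpec("blob", vertices = poly)
  mc <- oracleMcArea(poly, n = 1e6)
  expect_lt(abs(truthArea(sc) - mc) / mc, 0.002)
})

test_that("unsupported shape tags are rejected", {
  expect_error(sceneSpec("star"))
  expect_error(woundpatch:::.analyticArea("star", list()), "unsupported")
})

test_that("projected patch corners equal an independent 3x4 camera-matrix projection", {
  for (cfg in list(c(30, 90), c(40, 60), c(50, 30))) {
    cam <- captureConfig(cfg[1], cfg[2])
    rs <- renderScene(sceneSpec(), cam)
    g <- 2.1; ox <- 2.5; oy <- -1.05
    plane <- rbind(c(ox, oy + g), c(ox + g, oy + g), c(ox + g, oy), c(ox, oy))
    truth <- oracleProjectPlane(plane, cfg[1], cfg[2], cam@focalPx,
                                cam@widthPx, cam@heightPx)
    expect_lt(max(abs(rs@patchCorners - truth)), 1e-9)
  }
})

test_that("fronto-parallel projection preserves the patch's square shape", {
  rs <- fxRender90()
  p <- rs@patchCorners
  side1 <- sqrt(sum((p[2, ] - p[1, ])^2))
  side2 <- sqrt(sum((p[3, ] - p[2, ])^2))
  expect_lt(abs(side1 / side2 - 1), 1e-9)
  # (side)^2 / quad area = 1: no perspective distortion at theta = 90
  quadArea <- abs(woundpatch:::.shoelace(p))
  expect_lt(abs(side1^2 / quadArea - 1), 1e-6)
})

test_that("rendering is deterministic for identical scene, camera and seed", {
  sc <- sceneSpec(noiseSigma = 0.02, seed = 5L)
  cam <- captureConfig(40, 60)
  a <- renderScene(sc, cam)
  b <- renderScene(sc, cam)
  expect_identical(a@image, b@image)
  expect_identical(a@truthMask, b@truthMask)
  c2 <- renderScene(sc, cam, seed = 6L)
  expect_false(identical(a@image, c2@image))
})

test_that("truth mask area agrees with the analytic area and is resolution-stable", {
  # at theta = 90 the plane-to-image map is a pure scaling f/d
  sc <- sceneSpec()
  cam1 <- captureConfig(30, 90, focalPx = 1600, widthPx = 640L, heightPx = 480L)
  cam2 <- captureConfig(30, 90, focalPx = 3200, widthPx = 1280L, heightPx = 960L)
  a1 <- sum(renderScene(sc, cam1)@truthMask) * (30 / 1600)^2
  a2 <- sum(renderScene(sc, cam2)@truthMask) * (30 / 3200)^2
  expect_lt(abs(a1 - truthArea(sc)) / truthArea(sc), 0.005)
  expect_lt(abs(a1 - a2) / a2, 0.005)
})

test_that("out-of-frame scene elements raise a named error", {
  sc <- sceneSpec(patchOffsetCm = c(8, -1.05))   # patch pushed out of view
  expect_error(renderScene(sc, captureConfig(30, 90)), "patch")
  # wide wound that exceeds the (short) frame while the patch stays inside
  sc2 <- sceneSpec("circle", r = 5.5, patchOffsetCm = c(6.2, -1.05))
  cam <- captureConfig(30, 90, focalPx = 1200, widthPx = 800L,
                       heightPx = 400L)
  expect_error(renderScene(sc2, cam), "wound")
})

test_that("scene validity rejects inconsistent specifications", {
  expect_error(sceneSpec("circle", r = 2, patchOffsetCm = c(0.5, -1)),
               "overlap")
  expect_error(sceneSpec(illumination = c(1, -1, 1)), "illumination")
  expect_error(sceneSpec(noiseSigma = -0.1), "noise")
})
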