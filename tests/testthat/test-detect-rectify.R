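test_that("detection recovers the projected patch corners on noise-free renders", {
  for (fx in list(list(fxRender90(), fxDetect90()),
                  list(fxRender60(), fxDetect60()))) {
    rs <- fx[[1]]; det <- fx[[2]]
    err <- sqrt(rowSums((det@corners - rs@patchCorners)^2))
    expect_lt(max(err), 1)
    expect_equal(det@confidence, 1)
  }
})

test_that("corner ordering is canonical regardless of in-plane rotation", {
  rs <- fxRender60()
  det0 <- fxDetect60()
  # rotate the photograph 90 deg clockwise: (x, y) -> (h - 1 - y, x)
  img <- rs@image
  h <- dim(img)[1]
  rot <- aperm(img[h:1, , , drop = FALSE], c(2, 1, 3))
  det1 <- detectPatch(rot)
  expected <- cbind(h - 1 - det0@corners[, 2], det0@corners[, 1])
  expect_lt(max(abs(det1@corners - expected)), 1)
  # cell colors stay in physical row-major order
  expect_lt(max(abs(det1@cellColors - det0@cellColors), na.rm = TRUE), 0.05)
})

test_that("patch-free images raise 'patch not detected'", {
  gray <- array(0.5, c(60, 80, 3))
  expect_error(detectPatch(gray), "patch not detected")
})

test_that("detection is equivariant under patch translation", {
  cam <- captureConfig(40, 60)
  det0 <- fxDetect60()
  sc1 <- sceneSpec(patchOffsetCm = c(3.0, -1.05))   # +0.5 cm in plane x
  rs1 <- renderScene(sc1, cam)
  det1 <- detectPatch(rs1)
  expect_lt(max(abs(det1@corners - rs1@patchCorners)), 1)
  expect_gt(max(abs(det1@corners - det0@corners)), 2)  # it did move
})

test_that("rectification produces the calibrated patch square and scale", {
  rect <- fxRect90()
  expect_equal(rect@scaleCmPerPx, 1 / 25)
  pr <- rect@patchRegion
  side <- c(pr[3] - pr[1], pr[4] - pr[2])
  expect_lt(max(abs(side - 2.1 * 25)), 1)
  # the patch really is there: sampled cell colors match the references
  obs <- sampleCellColors(rect)
  expect_lt(max(abs(obs - referenceColors(defaultPatchSpec()))), 0.06)
  expect_equal(rectifyImage(fxRender90(), fxDetect90(),
                            targetPxPerCm = 100)@scaleCmPerPx, 0.01)
})

test_that("rectification removes perspective: oblique circle becomes round", {
  sc <- sceneSpec()
  rs <- renderScene(sc, captureConfig(30, 30))
  det <- detectPatch(rs)
  rect <- rectifyImage(rs, det, targetPxPerCm = 25)
  lum <- 0.299 * rect@image[, , 1] + 0.587 * rect@image[, , 2] +
    0.114 * rect@image[, , 3]
  dark <- which(lum < 0.45, arr.ind = TRUE)
  # exclude the patch region (black cell is dark too)
  pr <- rect@patchRegion
  inPatch <- dark[, 2] - 1 >= pr[1] - 2 & dark[, 2] - 1 <= pr[3] + 2 &
    dark[, 1] - 1 >= pr[2] - 2 & dark[, 1] <= pr[4] + 2
  dark <- dark[!inPatch, , drop = FALSE]
  aspect <- diff(range(dark[, 2])) / diff(range(dark[, 1]))
  expect_lt(abs(aspect - 1), 0.02)
})

test_that("excessive raster sizes are rejected with advice", {
  expect_error(rectifyImage(fxRender90(), fxDetect90(),
                            targetPxPerCm = 1000, maxRasterPx = 1e6),
               "px_per_cm")
})

test_that("scale correctness: measured area within 1% of truth across the grid", {
  # noise-free end-to-end scale invariant at the grid extremes
  for (cfg in list(c(30, 90), c(50, 30))) {
    rs <- if (cfg[1] == 30) fxRender90()
          else renderScene(sceneSpec(), captureConfig(cfg[1], cfg[2]))
    m <- measureImage(rs, seed = 3)
    expect_lt(abs(errorRate(m@areaCm2, 12.566)), 1)
  }
})

test_that("patch spec validity enforces distinctness and asymmetry", {
  cols <- referenceColors(defaultPatchSpec())
  cols[2, ] <- cols[1, ]
  expect_error(patchSpec(cols), "distance")
  # rotationally symmetric arrangement is ambiguous: not constructible
  expect_true(woundpatch:::.patchRotationAmbiguous(
    matrix(0.5, 9, 3), 3L, 3L))
})
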