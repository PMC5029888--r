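test_that("identity and scaling cases recover the exact map", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  H <- estimateHomography(sq, sq)
  expect_lt(max(abs(H@H - diag(3))), 1e-9)
  H2 <- estimateHomography(sq, sq * 3 + 1)
  expect_lt(max(abs(applyHomography(H2, c(0.5, 0.5)) - c(2.5, 2.5))), 1e-9)
})

test_that("collinear correspondences are rejected as degenerate", {
  bad <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 1))
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_error(estimateHomography(bad, sq), "degenerate")
  expect_error(estimateHomography(sq, bad), "degenerate")
})

test_that("four-point DLT agrees with an SVD-nullspace oracle on projected points", {
  cam <- captureConfig(40, 60)
  g <- 2.1; ox <- 2.5; oy <- -1.05
  plane <- rbind(c(ox, oy + g), c(ox + g, oy + g), c(ox + g, oy), c(ox, oy))
  img <- oracleProjectPlane(plane, 40, 60, cam@focalPx, cam@widthPx,
                            cam@heightPx)
  canon <- rbind(c(0, 0), c(g, 0), c(g, g), c(0, g))
  H <- estimateHomography(img, canon)
  Ho <- oracleSvdDLT(img, canon)
  # 20 extra projected test points must map identically (< 0.1 px in the
  # source frame) and to their known plane positions
  set.seed(1)
  testPlane <- cbind(runif(20, -2, 5), runif(20, -2, 2))
  testImg <- oracleProjectPlane(testPlane, 40, 60, cam@focalPx,
                                cam@widthPx, cam@heightPx)
  canonTrue <- cbind(testPlane[, 1] - ox, (oy + g) - testPlane[, 2])
  p1 <- applyHomography(H, testImg)
  p2 <- applyHomography(Ho, testImg)
  pxPerCm <- cam@focalPx / 40
  expect_lt(max(abs(p1 - p2)) * pxPerCm, 0.1)
  expect_lt(max(abs(p1 - canonTrue)) * pxPerCm, 0.1)
})

test_that("homography round trip returns points to within 1e-6 px", {
  src <- rbind(c(10, 20), c(200, 15), c(220, 180), c(5, 190))
  dst <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  H <- estimateHomography(src, dst)
  Hi <- invertHomography(H)
  set.seed(2)
  pts <- cbind(runif(50, 0, 220), runif(50, 0, 190))
  back <- applyHomography(Hi, applyHomography(H, pts))
  expect_lt(max(abs(back - pts)), 1e-6)
})

test_that("homography objects are validated", {
  expect_error(new("Homography", H = matrix(0, 3, 3)), "invertible|normalized")
  H <- diag(3); H[3, 3] <- 2
  expect_error(new("Homography", H = H), "normalized")
})
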