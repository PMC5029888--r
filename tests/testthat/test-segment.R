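test_that("edge map behaves correctly on constant, step and disk images", {
  # constant image: all-zero map, not an error
  expect_true(all(computeEdgeMap(array(0.7, c(20, 20, 3)), 1)@f == 0))
  # vertical step edge: maximal response on the edge column, symmetric
  img <- array(0.2, c(32, 32, 3))
  img[, 17:32, ] <- 0.8
  f <- computeEdgeMap(img, 1)@f
  row <- f[16, ]
  peak <- which.max(row)
  expect_true(peak %in% 16:17)
  # the edge sits between columns 16 and 17, so the profile is symmetric
  # about that midpoint
  expect_lt(max(abs(row[16 - (0:5)] - row[17 + (0:5)])), 1e-6)
  # disk: the argmax ridge radius matches the true circle radius within 1 px
  d <- fxDisk()
  f2 <- computeEdgeMap(d$img, 1)@f
  th <- seq(0, 2 * pi, length.out = 100)[-100]
  rr <- seq(d$R - 4, d$R + 4, by = 0.1)
  prof <- sapply(rr, function(r) mean(woundpatch:::.bilinear(
    f2, d$cx + r * cos(th), d$cy + r * sin(th))))
  expect_lt(abs(rr[which.max(prof)] - d$R), 1)
})

test_that("GVF iteration matches a dense fixed-point solve on small grids", {
  # 7x7 single step edge, mu = 0.2 (also checked at other small sizes)
  for (dims in list(c(7, 7), c(11, 9), c(15, 15))) {
    f <- matrix(0, dims[1], dims[2])
    f[, floor(dims[2] / 2)] <- 1
    gg <- computeGVF(f, gvfParams(mu = 0.2, nIter = 20000L), stopTol = 1e-12)
    dn <- oracleDenseGVF(f, 0.2)
    expect_lt(max(abs(gg@u - dn$u)), 1e-5)
    expect_lt(max(abs(gg@v - dn$v)), 1e-5)
  }
})

test_that("GVF limit behaviors: zero map and pure diffusion far from edges", {
  z <- computeGVF(matrix(0, 10, 10), gvfParams(nIter = 50L))
  expect_true(all(z@u == 0) && all(z@v == 0))
  # far from edges the converged field satisfies the discrete Laplace
  # equation (pure diffusion)
  d <- fxDisk()
  f <- computeEdgeMap(d$img, 1)@f
  g <- computeGVF(f, gvfParams(nIter = 5000L), stopTol = 1e-8)
  gr <- woundpatch:::.gradient(f)
  far <- (gr$gx^2 + gr$gy^2) == 0
  far[c(1, nrow(far)), ] <- FALSE; far[, c(1, ncol(far))] <- FALSE
  lapU <- woundpatch:::.laplacian(g@u)
  expect_lt(max(abs(lapU[far])), 1e-3)
})

test_that("GVF stability bound on dt is enforced", {
  expect_error(gvfParams(mu = 0.5, dt = 1), "stability")
})

test_that("GVF aligns with the edge-map gradient at strong edges", {
  d <- fxDisk()
  g <- fxDiskGVF()
  f <- computeEdgeMap(d$img, 1)@f
  gr <- woundpatch:::.gradient(f)
  mag <- sqrt(gr$gx^2 + gr$gy^2)
  strong <- mag >= stats::quantile(mag, 0.99)
  dotp <- (g@u * gr$gx + g@v * gr$gy)[strong]
  norms <- (sqrt(g@u^2 + g@v^2) * mag)[strong]
  angles <- acos(pmin(1, pmax(-1, dotp / norms))) * 180 / pi
  expect_lt(max(angles), 10)
})

test_that("snake converges onto a circular boundary within 1 px RMS", {
  d <- fxDisk()
  g <- fxDiskGVF()
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  init <- cbind(d$cx + 1.3 * d$R * cos(th), d$cy + 1.3 * d$R * sin(th))
  fin <- evolveSnake(init, g, snakeParams())
  rr <- sqrt((fin[, 1] - d$cx)^2 + (fin[, 2] - d$cy)^2)
  expect_lt(sqrt(mean((rr - d$R)^2)), 1)
})

test_that("with zero external force internal tension shrinks the contour", {
  z <- new("GVFField", u = matrix(0, 120, 120), v = matrix(0, 120, 120),
           residual = 0, iterations = 0L)
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  x <- cbind(60 + 20 * cos(th), 60 + 20 * sin(th))
  p <- snakeParams()
  areas <- numeric(0); energies <- numeric(0)
  for (i in 1:50) {
    x <- evolveSnake(x, z, snakeParams(maxIter = 1L, tolPx = 1e-12))
    areas <- c(areas, abs(woundpatch:::.shoelace(x)))
    energies <- c(energies, woundpatch:::snakeEnergy(
      x, matrix(0, 120, 120), p))
  }
  expect_true(all(diff(areas) < 0))
  expect_true(all(diff(energies) < 0))
  # shrinking a small contour to nothing raises the collapse error
  xs <- cbind(60 + 4 * cos(th), 60 + 4 * sin(th))
  expect_error(evolveSnake(xs, z, snakeParams(maxIter = 5000L,
                                              tolPx = 1e-12)),
               "contour collapse")
})

test_that("snake energy decreases from initialization to convergence", {
  d <- fxDisk()
  g <- fxDiskGVF()
  em <- computeEdgeMap(d$img, 1)
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  init <- cbind(d$cx + 1.3 * d$R * cos(th), d$cy + 1.3 * d$R * sin(th))
  fin <- evolveSnake(init, g, snakeParams())
  p <- snakeParams()
  expect_lt(woundpatch:::snakeEnergy(fin, em, p),
            woundpatch:::snakeEnergy(init, em, p))
})

test_that("the snake follows GVF into a deep boundary concavity", {
  h <- 120; w <- 120
  xx <- matrix(rep(0:(w - 1), each = h), h, w)
  yy <- matrix(rep(0:(h - 1), w), h, w)
  um <- (xx >= 30 & xx <= 90 & yy >= 30 & yy <= 90) &
    !(xx >= 45 & xx <= 75 & yy >= 30 & yy <= 70)
  img <- array(0.8, c(h, w, 3))
  for (ch in 1:3) { m <- img[, , ch]; m[um] <- 0.2; img[, , ch] <- m }
  g <- computeGVF(computeEdgeMap(img, 1), gvfParams(nIter = 3000L),
                  stopTol = 1e-7)
  th <- seq(0, 2 * pi, length.out = 302)[-302]
  init <- cbind(60 + 46 * cos(th), 62 + 46 * sin(th))
  fin <- evolveSnake(init, g, snakeParams(maxIter = 3000L))
  bnd <- which(um & !(rbind(FALSE, um[-h, ]) & rbind(um[-1, ], FALSE) &
                      cbind(FALSE, um[, -w]) & cbind(um[, -1], FALSE)))
  ai <- arrayInd(bnd, c(h, w))
  bp <- cbind(ai[, 2] - 1, ai[, 1] - 1)
  dmax <- max(apply(bp, 1, function(p)
    min(sqrt((fin[, 1] - p[1])^2 + (fin[, 2] - p[2])^2))))
  expect_lt(dmax, 2)
})

test_that("k-means initialization encloses the wound and is seeded-deterministic", {
  rect <- fxRect90()
  init1 <- kmeansInitContour(rect, seed = 4)
  init2 <- kmeansInitContour(rect, seed = 4)
  expect_identical(init1, init2)
  # strictly encloses the true wound footprint
  s <- rect@scaleCmPerPx
  cx <- (-2.5 - rect@offsetCm[1]) / s
  cy <- (1.05 - rect@offsetCm[2]) / s
  th <- seq(0, 2 * pi, length.out = 72)[-72]
  edge <- cbind(cx + (2 / s) * cos(th), cy + (2 / s) * sin(th))
  expect_true(all(woundpatch:::.pointInPolygon(edge[, 1], edge[, 2], init1)))
})

test_that("degenerate images raise 'no wound candidate found'", {
  uni <- array(0.6, c(60, 80, 3))
  expect_error(kmeansInitContour(uni, seed = 1), "no wound candidate")
  # scene with the wound painted in skin color: nothing to find
  sc <- sceneSpec(woundColor = c(0.80, 0.62, 0.50), noiseSigma = 0.005)
  rs <- renderScene(sc, captureConfig(30, 90))
  det <- detectPatch(rs)
  rect <- rectifyImage(rs, det, targetPxPerCm = 25)
  expect_error(segmentWound(rect, seed = 1), "no wound candidate")
})

test_that("segmentation overlaps ground truth (Jaccard) with and without noise", {
  rs <- fxRender90()
  m <- measureImage(rs, seed = 5)
  rect <- rectifyImage(rs, fxDetect90(), targetPxPerCm = 25)
  src <- contourToSourceFrame(m@contour, rect)
  h <- dim(rs@image)[1]; w <- dim(rs@image)[2]
  cmask <- contourToMask(src, h, w)
  expect_gte(jaccard(cmask, rs@truthMask), 0.95)

  scN <- sceneSpec(noiseSigma = 0.02, seed = 9L)
  rsN <- renderScene(scN, captureConfig(30, 90))
  mN <- measureImage(rsN, seed = 5)
  rectN <- rectifyImage(rsN, detectPatch(rsN), targetPxPerCm = 25)
  srcN <- contourToSourceFrame(mN@contour, rectN)
  expect_gte(jaccard(contourToMask(srcN, h, w), rsN@truthMask), 0.90)
})

test_that("measured area is robust to in-plane wound rotation", {
  a0 <- measureImage(renderScene(sceneSpec("ellipse", a = 2, b = 1),
                                 captureConfig(40, 60)), seed = 6)@areaCm2
  a45 <- measureImage(renderScene(sceneSpec("ellipse", a = 2, b = 1,
                                            thetaRad = pi / 4),
                                  captureConfig(40, 60)), seed = 6)@areaCm2
  expect_lt(abs(a45 - a0) / a0, 0.02)
})
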