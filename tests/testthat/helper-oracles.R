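# Independent oracles used to check package computations.  Each is coded
# from first principles, separately from the implementation it checks.

# Full 3x4 pinhole camera matrix P = K [R | t] for the scene camera
# (distance d along the optical axis, elevation theta to the plane, axis
# through the plane origin), applied to 3D points on z = 0.
oracleProjectPlane <- function(pts2d, distanceCm, angleDeg, focalPx,
                               widthPx, heightPx) {
  th <- angleDeg * pi / 180
  C <- distanceCm * c(0, -cos(th), sin(th))          # camera center
  zc <- -C / sqrt(sum(C^2))                          # optical axis (to origin)
  xc <- c(1, 0, 0)
  yc <- c(zc[2] * xc[3] - zc[3] * xc[2],
          zc[3] * xc[1] - zc[1] * xc[3],
          zc[1] * xc[2] - zc[2] * xc[1])
  R <- rbind(xc, yc, zc)
  t <- -R %*% C
  K <- matrix(c(focalPx, 0, (widthPx - 1) / 2,
                0, focalPx, (heightPx - 1) / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  P <- K %*% cbind(R, t)
  X <- rbind(t(pts2d), 0, 1)
  q <- P %*% X
  t(q[1:2, , drop = FALSE] / rep(q[3, ], each = 2))
}

# SVD-nullspace direct linear transform (homogeneous formulation)
oracleSvdDLT <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nv = 9)$v[, 9]
  H <- matrix(h, 3, 3, byrow = TRUE)
  H / H[3, 3]
}

# Dense fixed-point solve of the GVF equations on a small grid:
# (mu L - diag(b)) u = -b fx, with the same Neumann (replicate) Laplacian
# convention as the diffusion scheme, assembled as an explicit matrix.
oracleDenseGVF <- function(f, mu) {
  h <- nrow(f); w <- ncol(f)
  cl <- c(1L, seq_len(w - 1L)); cr <- c(seq_len(w)[-1], w)
  rt <- c(1L, seq_len(h - 1L)); rb <- c(seq_len(h)[-1], h)
  gx <- (f[, cr, drop = FALSE] - f[, cl, drop = FALSE]) / 2
  gy <- (f[rb, , drop = FALSE] - f[rt, , drop = FALSE]) / 2
  b <- gx^2 + gy^2
  n <- h * w
  id <- function(r, c) (c - 1L) * h + r
  L <- matrix(0, n, n)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    i <- id(r, c)
    for (nb in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
      rr <- min(max(nb[1], 1), h); cc <- min(max(nb[2], 1), w)
      L[i, id(rr, cc)] <- L[i, id(rr, cc)] + 1
    }
    L[i, i] <- L[i, i] - 4
  }
  A <- mu * L - diag(as.vector(b))
  list(u = matrix(solve(A, -as.vector(b) * as.vector(gx)), h, w),
       v = matrix(solve(A, -as.vector(b) * as.vector(gy)), h, w))
}

# Monte-Carlo polygon area by rejection sampling in the bounding box
oracleMcArea <- function(poly, n = 1e6, seed = 42) {
  set.seed(seed)
  x0 <- min(poly[, 1]); x1 <- max(poly[, 1])
  y0 <- min(poly[, 2]); y1 <- max(poly[, 2])
  xs <- runif(n, x0, x1); ys <- runif(n, y0, y1)
  inside <- woundpatch:::.pointInPolygon(xs, ys, poly)
  mean(inside) * (x1 - x0) * (y1 - y0)
}

# Rasterize a closed contour to a binary mask on an h x w grid
contourToMask <- function(contour, h, w) {
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  matrix(as.numeric(woundpatch:::.pointInPolygon(xs, ys, contour)), h, w)
}

jaccard <- function(a, b) sum(a > 0 & b > 0) / sum(a > 0 | b > 0)

# Map a rectified-frame contour back to source-image pixel coordinates
contourToSourceFrame <- function(contour, rect) {
  cm <- cbind(contour[, 1] * rect@scaleCmPerPx + rect@offsetCm[1],
              contour[, 2] * rect@scaleCmPerPx + rect@offsetCm[2])
  applyHomography(invertHomography(rect@homography), cm)
}
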