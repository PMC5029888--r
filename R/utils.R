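# Internal geometry and raster helpers shared across the pipeline.
# Image convention: 0-based pixel centers, origin top-left, x rightward,
# y downward; an image is an array [row = y + 1, col = x + 1, channel].

# Evaluate a function with a locally fixed RNG seed, restoring global state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Signed shoelace sum of a closed polygon (n x 2, last vertex != first).
.shoelace <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

.isConvexQuad <- function(p) {
  if (nrow(p) != 4L) return(FALSE)
  z <- numeric(4)
  for (i in 1:4) {
    a <- p[i, ]; b <- p[i %% 4 + 1, ]; c <- p[(i + 1) %% 4 + 1, ]
    z[i] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
  }
  all(z > 1e-9) || all(z < -1e-9)
}

# TRUE where (x, y) lies inside the closed polygon `poly` (n x 2); even-odd
# crossing rule, vectorized over the query points.
.pointInPolygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Bilinear sampling of a 2D matrix at 0-based (x, y); coordinates clamped to
# the valid domain so out-of-range queries return the nearest edge value.
.bilinear <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- pmin(floor(x), w - 2); y0 <- pmin(floor(y), h - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * h + y0 + 1          # column-major linear index
  v00 <- m[i00];     v10 <- m[i00 + h]
  v01 <- m[i00 + 1]; v11 <- m[i00 + h + 1]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

# Resample a closed contour (n x 2) to m points at uniform arc-length spacing.
.resampleClosed <- function(p, m) {
  q <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(q)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) return(p[rep(1, m), , drop = FALSE])
  s <- seq(0, total, length.out = m + 1)[1:m]
  cbind(stats::approx(cum, q[, 1], xout = s)$y,
        stats::approx(cum, q[, 2], xout = s)$y)
}

# Perimeter of a closed polygon.
.perimeter <- function(p) {
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(q)^2)))
}

# Separable Gaussian blur with replicate padding; sigma in pixels.
.gaussBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  .conv1 <- function(mat, along) {
    n <- if (along == 1) nrow(mat) else ncol(mat)
    idx <- function(off) pmin(pmax(seq_len(n) + off, 1L), n)
    out <- 0
    for (j in seq_along(k)) {
      off <- j - r - 1L
      out <- out + k[j] * (if (along == 1) mat[idx(off), , drop = FALSE]
                           else mat[, idx(off), drop = FALSE])
    }
    out
  }
  .conv1(.conv1(m, 1), 2)
}

# Central-difference gradient of a matrix (replicate boundary); returns
# list(gx, gy) with x along columns, y along rows.
.gradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  cl <- c(1L, seq_len(w - 1L)); cr <- c(seq_len(w)[-1], w)
  rt <- c(1L, seq_len(h - 1L)); rb <- c(seq_len(h)[-1], h)
  list(gx = (m[, cr, drop = FALSE] - m[, cl, drop = FALSE]) / 2,
       gy = (m[rb, , drop = FALSE] - m[rt, , drop = FALSE]) / 2)
}

# 5-point Laplacian with Neumann (replicate) boundary conditions.
.laplacian <- function(m) {
  h <- nrow(m); w <- ncol(m)
  cl <- c(1L, seq_len(w - 1L)); cr <- c(seq_len(w)[-1], w)
  rt <- c(1L, seq_len(h - 1L)); rb <- c(seq_len(h)[-1], h)
  m[, cl, drop = FALSE] + m[, cr, drop = FALSE] +
    m[rt, , drop = FALSE] + m[rb, , drop = FALSE] - 4 * m
}

# Luma (Rec. 601) of an h x w x 3 array.
.gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Median color of the 1-pixel image border; robust stand-in for normal skin.
.borderMedian <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  sapply(1:3, function(ch) {
    m <- img[, , ch]
    stats::median(c(m[1, ], m[h, ], m[, 1], m[, w]))
  })
}

# Bounding box (x0, y0, x1, y1) of a scene's wound footprint in plane cm.
.woundBBox <- function(scene) {
  sp <- scene@shapeParams
  switch(scene@woundShape,
    circle = c(-sp$r, -sp$r, sp$r, sp$r),
    ellipse = {
      th <- if (is.null(sp$theta)) 0 else sp$theta
      ex <- sqrt((sp$a * cos(th))^2 + (sp$b * sin(th))^2)
      ey <- sqrt((sp$a * sin(th))^2 + (sp$b * cos(th))^2)
      c(-ex, -ey, ex, ey)
    },
    blob = c(min(sp$vertices[, 1]), min(sp$vertices[, 2]),
             max(sp$vertices[, 1]), max(sp$vertices[, 2]))
  )
}

.stopStage <- function(stage, msg) {
  cond <- structure(
    class = c("woundpatchStageError", "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = sys.call(-1),
         stage = stage)
  )
  stop(cond)
}
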