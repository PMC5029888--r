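#' Snake (active contour) parameters
#'
#' Defaults are the fixed values used by the measurement pipeline:
#' alpha = 0.2 (elasticity), beta = 0.2 (rigidity), gamma = 1.0 (step
#' size), kappa = 0.5 (external force weight).
#'
#' @param alpha,beta,gamma,kappa positive evolution weights.
#' @param maxIter iteration cap.
#' @param tolPx stop when mean vertex displacement falls below this (px).
#' @return A [SnakeParams-class].
#' @export
snakeParams <- function(alpha = 0.2, beta = 0.2, gamma = 1.0, kappa = 0.5,
                        maxIter = 500L, tolPx = 0.01) {
  new("SnakeParams", alpha = alpha, beta = beta, gamma = gamma,
      kappa = kappa, maxIter = as.integer(maxIter), tolPx = tolPx)
}

#' Gradient-vector-flow parameters
#'
#' mu = 0.2 is the canonical regularization weight of the GVF literature;
#' the iteration count defaults (nIter = NA) to 80 * max(side) / 64, scaling
#' the diffusion range with image size.  dt = 1 satisfies the explicit
#' scheme's stability bound dt <= 1/(4 mu) for the default mu.
#'
#' @param mu regularization weight (> 0).
#' @param nIter iterations, or NA for the size-scaled default.
#' @param dt diffusion time step.
#' @return A [GVFParams-class].
#' @export
gvfParams <- function(mu = 0.2, nIter = NA_integer_, dt = 1.0) {
  new("GVFParams", mu = mu, nIter = as.integer(nIter), dt = dt)
}

#' Automatic initial contour by k-means color clustering
#'
#' Clusters the pixel colors (k-means, seeded, 10 restarts), calls the
#' cluster whose mean color lies farthest from the image-border median the
#' wound (the border is presumed normal skin; ties go to the smaller
#' cluster), takes the largest connected component of that cluster, and
#' returns its convex hull dilated outward by 5\% of the component's
#' equivalent diameter, resampled to uniform vertex spacing.  The patch
#' region is excluded by painting it with the border-median color first.
#'
#' @param rect a [RectifiedImage-class] (or bare h x w x 3 array).
#' @param k number of color clusters.
#' @param seed RNG seed (k-means restarts).
#' @param minWoundPx minimum component size to accept.
#' @param minContrast minimum RGB distance between the wound cluster's
#'   center and the border-median color; below it the image is treated as
#'   wound-free (clusters that only split sensor noise).
#' @return n x 2 matrix of contour vertices (0-based px, closed implicitly).
#' @section Errors: "no wound candidate found" when the wound cluster is
#'   empty/too small, indistinct from skin, or the image is uniform.
#' @export
kmeansInitContour <- function(rect, k = 2L, seed = 1L, minWoundPx = 50L,
                              minContrast = 0.1) {
  img <- .maskedImage(rect)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  border <- .borderMedian(img)
  km <- tryCatch(
    withSeed(seed, {
      fitIdx <- if (nrow(px) > 20000L)
        sort(sample.int(nrow(px), 20000L)) else seq_len(nrow(px))
      suppressWarnings(    # near-uniform inputs trip Quick-TRANSfer limits
        stats::kmeans(px[fitIdx, , drop = FALSE], centers = k,
                      nstart = 10L, iter.max = 50L))
    }),
    error = function(e) NULL)
  if (is.null(km))
    .stopStage("kmeans_init", "no wound candidate found (degenerate clustering)")
  # assign every pixel to its nearest center
  cd <- sapply(seq_len(k), function(j)
    colSums((t(px) - km$centers[j, ])^2))
  lab <- max.col(-cd)
  dBorder <- sqrt(colSums((t(km$centers) - border)^2))
  sizes <- tabulate(lab, k)
  ord <- order(-dBorder, sizes)        # farthest first; ties -> smaller cluster
  woundK <- ord[1]
  if (dBorder[woundK] < minContrast)
    .stopStage("kmeans_init",
               "no wound candidate found (no cluster distinct from skin)")
  mask <- matrix(as.numeric(lab == woundK), h, w)
  comp <- EBImage::bwlabel(mask)
  cs <- tabulate(comp[comp > 0])
  if (!length(cs) || max(cs) < minWoundPx)
    .stopStage("kmeans_init", "no wound candidate found")
  big <- which.max(cs)
  idx <- which(comp == big)
  ai <- arrayInd(idx, c(h, w))
  pts <- cbind(ai[, 2] - 1, ai[, 1] - 1)           # (x, y)
  hullI <- grDevices::chull(pts)
  hull <- pts[hullI, , drop = FALSE]
  ctr <- colMeans(pts)
  eqD <- 2 * sqrt(length(idx) / pi)
  dir <- sweep(hull, 2, ctr)
  nrm <- sqrt(rowSums(dir^2)); nrm[nrm == 0] <- 1
  hull <- hull + dir / nrm * (0.05 * eqD)
  n <- max(60L, min(500L, round(.perimeter(hull))))   # ~1 px vertex spacing
  .resampleClosed(hull, n)
}

# paint the patch region (and a safety margin) with the border-median color
.maskedImage <- function(rect, marginPx = 3) {
  if (is(rect, "RectifiedImage")) {
    img <- rect@image
    pr <- rect@patchRegion
    h <- dim(img)[1]; w <- dim(img)[2]
    xs <- max(0, floor(pr[1] - marginPx)):min(w - 1, ceiling(pr[3] + marginPx))
    ys <- max(0, floor(pr[2] - marginPx)):min(h - 1, ceiling(pr[4] + marginPx))
    if (length(xs) && length(ys)) {
      bm <- .borderMedian(img)
      for (ch in 1:3) img[ys + 1, xs + 1, ch] <- bm[ch]
    }
    img
  } else rect
}

#' Edge map: normalized gradient magnitude
#'
#' f = |grad(G_sigma * gray(image))|, min-max normalized to [0,1].  A
#' constant image yields an all-zero map (valid, not an error).
#'
#' @param image [RectifiedImage-class], h x w x 3 array, or h x w matrix.
#' @param sigma Gaussian smoothing sigma in px.
#' @return An [EdgeMap-class].
#' @export
computeEdgeMap <- function(image, sigma = 1.0) {
  stopifnot(sigma >= 0)
  gray <- if (is(image, "RectifiedImage")) .gray(.maskedImage(image))
          else if (length(dim(image)) == 3L) .gray(image)
          else image
  gs <- .gaussBlur(gray, sigma)
  g <- .gradient(gs)
  f <- sqrt(g$gx^2 + g$gy^2)
  rng <- range(f)
  if (rng[2] > rng[1]) f <- (f - rng[1]) / (rng[2] - rng[1])
  else f <- matrix(0, nrow(f), ncol(f))
  new("EdgeMap", f = f, sigma = sigma)
}

#' Gradient vector flow of an edge map
#'
#' Diffuses the edge-map gradient into a smooth force field by the
#' fixed-point iteration
#' \deqn{u \leftarrow u + dt\,(\mu \nabla^2 u - (u - f_x)(f_x^2 + f_y^2))}
#' (likewise v with f_y), initialized at (u, v) = grad f, with Neumann
#' boundary conditions.  Stops after \code{nIter} steps or when the largest
#' component update falls below \code{stopTol}.
#'
#' @param f an [EdgeMap-class] (or bare matrix in [0,1]).
#' @param params a [GVFParams-class].
#' @param stopTol early-stop threshold on the max update.
#' @return A [GVFField-class].
#' @export
computeGVF <- function(f, params = gvfParams(), stopTol = 1e-4) {
  fm <- if (is(f, "EdgeMap")) f@f else f
  validObject(params)
  g <- .gradient(fm)
  fx <- g$gx; fy <- g$gy
  b <- fx^2 + fy^2
  u <- fx; v <- fy
  nIter <- if (is.na(params@nIter))
    max(1L, as.integer(round(80 * max(dim(fm)) / 64))) else params@nIter
  dt <- params@dt; mu <- params@mu
  res <- Inf
  it <- 0L
  while (it < nIter) {
    it <- it + 1L
    du <- dt * (mu * .laplacian(u) - (u - fx) * b)
    dv <- dt * (mu * .laplacian(v) - (v - fy) * b)
    u <- u + du
    v <- v + dv
    res <- max(max(abs(du)), max(abs(dv)))
    if (res < stopTol) break
  }
  new("GVFField", u = u, v = v, residual = res, iterations = it)
}

#' Evolve an active contour on a GVF force field
#'
#' Semi-implicit snake iteration
#' \deqn{x_{t+1} = (I + \gamma K)^{-1} (x_t + \gamma \kappa F(x_t))}
#' where K is the cyclic pentadiagonal stiffness matrix of the
#' finite-difference discretization of \eqn{\alpha |x'|^2 + \beta |x''|^2}
#' and F samples (u, v) by bilinear interpolation.  The contour is
#' resampled to uniform spacing every 10 iterations; evolution stops when
#' the mean vertex displacement drops below \code{tolPx} or at
#' \code{maxIter}.
#'
#' @param init n x 2 initial contour (closed, 0-based px).
#' @param field a [GVFField-class].
#' @param p a [SnakeParams-class].
#' @param normalizeForce use the unit-magnitude GVF field as the external
#'   force (default).  The raw field decays with distance from edges, so a
#'   contour bridging a deep concavity stalls where tension balances the
#'   weak force; the normalized field keeps the attraction strength
#'   constant and gives the characteristic convergence into boundary
#'   cavities.
#' @return The final contour (n x 2) with attributes \code{iterations} and
#'   \code{finalDisplacement}.
#' @section Errors: "contour collapse" when the contour shrinks below 8
#'   vertices or 20 px^2 of enclosed area.
#' @export
evolveSnake <- function(init, field, p = snakeParams(),
                        normalizeForce = TRUE) {
  x <- as.matrix(init)
  stopifnot(ncol(x) == 2L, nrow(x) >= 8L)
  validObject(p)
  n <- nrow(x)
  Ainv <- .snakeSystemInverse(n, p)
  fu <- field@u; fv <- field@v
  if (normalizeForce) {
    mag <- sqrt(fu^2 + fv^2)
    mag[mag < 1e-8] <- 1e-8
    fu <- fu / mag; fv <- fv / mag
  }
  h <- nrow(fu); w <- ncol(fu)
  it <- 0L; disp <- Inf
  while (it < p@maxIter) {
    it <- it + 1L
    Fu <- .bilinear(fu, x[, 1], x[, 2])
    Fv <- .bilinear(fv, x[, 1], x[, 2])
    xn <- cbind(Ainv %*% (x[, 1] + p@gamma * p@kappa * Fu),
                Ainv %*% (x[, 2] + p@gamma * p@kappa * Fv))
    xn[, 1] <- pmin(pmax(xn[, 1], 0), w - 1)
    xn[, 2] <- pmin(pmax(xn[, 2], 0), h - 1)
    disp <- mean(sqrt(rowSums((xn - x)^2)))
    x <- xn
    if (abs(.shoelace(x)) < 20 || nrow(x) < 8L)
      .stopStage("snake", "contour collapse")
    if (it %% 10L == 0L) x <- .resampleClosed(x, n)
    if (disp < p@tolPx) break
  }
  structure(x, iterations = it, finalDisplacement = disp)
}

# (I + gamma K)^{-1} for the cyclic finite-difference stiffness matrix
.snakeSystemInverse <- function(n, p) {
  D2 <- matrix(0, n, n)                   # -x'' operator (positive semidef.)
  for (i in seq_len(n)) {
    D2[i, i] <- 2
    D2[i, i %% n + 1] <- -1
    D2[i, (i - 2) %% n + 1] <- -1
  }
  K <- p@alpha * D2 + p@beta * (D2 %*% D2)
  solve(diag(n) + p@gamma * K)
}

# internal + external snake energy (used by property tests / diagnostics):
# sum(alpha |x'|^2 + beta |x''|^2) - kappa * sum f(x_i)
snakeEnergy <- function(x, f, p) {
  n <- nrow(x)
  nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
  d1 <- x[nxt, ] - x
  d2 <- x[nxt, ] - 2 * x + x[prv, ]
  internal <- sum(p@alpha * rowSums(d1^2) + p@beta * rowSums(d2^2))
  fm <- if (is(f, "EdgeMap")) f@f else f
  internal - p@kappa * sum(.bilinear(fm, x[, 1], x[, 2]))
}

#' Segment the wound in a rectified, normalized image
#'
#' Orchestrates the automatic segmentation: k-means initial contour,
#' edge map, gradient vector flow, snake evolution.  Deterministic for a
#' given seed.  The patch region never attracts the snake (it is painted
#' with the border-median color before the edge map is built).  For speed
#' the force field is computed on a window around the initial contour
#' (margin 25\% of its diameter); the snake cannot leave this window
#' because GVF forces vanish far from edges.
#'
#' @param rect a [RectifiedImage-class].
#' @param sp a [SnakeParams-class].
#' @param gp a [GVFParams-class].
#' @param seed RNG seed (k-means).
#' @param k number of k-means clusters.
#' @param edgeSigma edge-map Gaussian sigma (px).
#' @param initContour optional n x 2 contour to bypass the k-means stage.
#' @return Final contour (n x 2, rectified-frame 0-based px) with
#'   attributes \code{iterations}, \code{finalDisplacement}.
#' @export
segmentWound <- function(rect, sp = snakeParams(), gp = gvfParams(),
                         seed = 1L, k = 2L, edgeSigma = 1.0,
                         initContour = NULL) {
  stopifnot(is(rect, "RectifiedImage"))
  init <- if (is.null(initContour)) kmeansInitContour(rect, k = k, seed = seed)
          else as.matrix(initContour)
  img <- .maskedImage(rect)
  h <- dim(img)[1]; w <- dim(img)[2]
  # working window around the initial contour
  rng <- apply(init, 2, range)
  diam <- max(rng[2, ] - rng[1, ])
  m <- max(15, 0.25 * diam)
  x0 <- max(0, floor(rng[1, 1] - m)); x1 <- min(w - 1, ceiling(rng[2, 1] + m))
  y0 <- max(0, floor(rng[1, 2] - m)); y1 <- min(h - 1, ceiling(rng[2, 2] + m))
  sub <- img[(y0:y1) + 1, (x0:x1) + 1, , drop = FALSE]
  em <- computeEdgeMap(sub, sigma = edgeSigma)
  gvf <- computeGVF(em, gp)
  initLoc <- cbind(init[, 1] - x0, init[, 2] - y0)
  out <- evolveSnake(initLoc, gvf, sp)
  res <- cbind(out[, 1] + x0, out[, 2] + y0)
  structure(res, iterations = attr(out, "iterations"),
            finalDisplacement = attr(out, "finalDisplacement"))
}
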