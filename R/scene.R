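#' Construct a synthetic scene specification
#'
#' Describes a planar scene holding one wound of known analytic area and the
#' fiducial color patch, coplanar with the wound.  Plane coordinates are in
#' cm, origin at the wound center, +y up.
#'
#' @param woundShape "circle", "ellipse" or "blob".
#' @param r circle radius, cm (circle only).  The default, r = 2, gives the
#'   12.57 cm^2 reference defect model used by the validation study.
#' @param a,b ellipse semi-axes, cm; \code{thetaRad} rotates the ellipse.
#' @param vertices n x 2 closed polygon, cm (blob only); see
#'   [blobPolygon()].
#' @param woundColor,skinColor sRGB triples in [0,1].
#' @param patch a [PatchSpec-class]; default [defaultPatchSpec()].
#' @param patchOffsetCm plane position (cm) of the patch's lower-left
#'   corner.
#' @param illumination per-channel multiplicative gains (global tint).
#' @param noiseSigma Gaussian pixel-noise standard deviation.
#' @param seed integer seed used when rendering.
#' @return A [SceneSpec-class].
#' @examples
#' sc <- sceneSpec()          # 2 cm radius circular defect, 12.57 cm^2
#' truthArea(sc)
#' @export
sceneSpec <- function(woundShape = c("circle", "ellipse", "blob"),
                      r = 2, a = 2, b = 1, thetaRad = 0, vertices = NULL,
                      woundColor = c(0.55, 0.18, 0.16),
                      skinColor = c(0.80, 0.62, 0.50),
                      patch = defaultPatchSpec(),
                      patchOffsetCm = c(2.5, -1.05),
                      illumination = c(1, 1, 1),
                      noiseSigma = 0, seed = 1L) {
  woundShape <- match.arg(woundShape)
  sp <- switch(woundShape,
    circle = list(r = r),
    ellipse = list(a = a, b = b, theta = thetaRad),
    blob = {
      if (is.null(vertices)) stop("blob shape requires `vertices`")
      list(vertices = as.matrix(vertices))
    })
  area <- .analyticArea(woundShape, sp)
  new("SceneSpec", woundShape = woundShape, shapeParams = sp,
      woundAreaCm2 = area, woundColor = woundColor, skinColor = skinColor,
      patch = patch, patchOffsetCm = patchOffsetCm,
      illumination = illumination, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

#' Construct a camera capture configuration
#'
#' An ideal pinhole camera at distance \code{distanceCm} from the point
#' where its optical axis meets the wound plane, at elevation
#' \code{angleDeg} between axis and plane (90 = perpendicular capture).
#' The axis always targets the plane origin (the wound center).
#'
#' @param distanceCm camera distance along the optical axis, cm.
#' @param angleDeg elevation angle in (0, 90].
#' @param focalPx focal length in pixels.
#' @param widthPx,heightPx sensor size in pixels.
#' @return A [CaptureConfig-class].
#' @export
captureConfig <- function(distanceCm = 30, angleDeg = 90, focalPx = 1600,
                          widthPx = 640L, heightPx = 480L) {
  new("CaptureConfig", distanceCm = distanceCm, angleDeg = angleDeg,
      focalPx = focalPx, widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx))
}

#' Smooth irregular ("blob") wound outline
#'
#' Radial polygon r(phi) = rBase * (1 + sum of low-order cosine harmonics
#' with random amplitude and phase); always star-shaped about the origin,
#' hence simple.
#'
#' @param rBase mean radius, cm.
#' @param nVertices polygon resolution.
#' @param irregularity total relative amplitude of the harmonics in [0, 0.5).
#' @param seed RNG seed.
#' @return nVertices x 2 matrix of polygon vertices (closed implicitly).
#' @export
blobPolygon <- function(rBase = 2, nVertices = 64L, irregularity = 0.25,
                        seed = 1L) {
  stopifnot(irregularity >= 0, irregularity < 0.5)
  withSeed(seed, {
    phi <- seq(0, 2 * pi, length.out = nVertices + 1L)[seq_len(nVertices)]
    amp <- stats::runif(3, 0, 1)
    amp <- amp / sum(amp) * irregularity
    pha <- stats::runif(3, 0, 2 * pi)
    rr <- rBase * (1 + amp[1] * cos(2 * phi + pha[1]) +
                     amp[2] * cos(3 * phi + pha[2]) +
                     amp[3] * cos(5 * phi + pha[3]))
    cbind(rr * cos(phi), rr * sin(phi))
  })
}

.analyticArea <- function(shape, sp) {
  switch(shape,
    circle = pi * sp$r^2,
    ellipse = pi * sp$a * sp$b,
    blob = abs(.shoelace(sp$vertices)),
    stop(sprintf("unsupported wound shape '%s'", shape))
  )
}

#' Analytic ground-truth wound area of a scene
#'
#' Circle: pi r^2; ellipse: pi a b; blob: polygon shoelace area.
#'
#' @param scene a [SceneSpec-class].
#' @return Area in cm^2.
#' @export
truthArea <- function(scene) {
  stopifnot(is(scene, "SceneSpec"))
  .analyticArea(scene@woundShape, scene@shapeParams)
}

# Plane(cm, +y up) -> image(px) homography of the pinhole camera.
# Camera center at d*(0, -cos(theta), sin(theta)), optical axis through the
# plane origin; principal point at the image center.
.cameraHomography <- function(cam) {
  th <- cam@angleDeg * pi / 180
  s <- sin(th); cs <- cos(th)
  f <- cam@focalPx
  cx <- (cam@widthPx - 1) / 2
  cy <- (cam@heightPx - 1) / 2
  K <- matrix(c(f, 0, cx, 0, f, cy, 0, 0, 1), 3, 3, byrow = TRUE)
  E <- matrix(c(1, 0, 0,
                0, -s, 0,
                0, cs, cam@distanceCm), 3, 3, byrow = TRUE)
  H <- K %*% E
  H / H[3, 3]
}

# TRUE where plane points (X, Y) fall inside the wound footprint.
.insideWound <- function(scene, X, Y) {
  sp <- scene@shapeParams
  switch(scene@woundShape,
    circle = X^2 + Y^2 <= sp$r^2,
    ellipse = {
      th <- if (is.null(sp$theta)) 0 else sp$theta
      xr <- X * cos(th) + Y * sin(th)
      yr <- -X * sin(th) + Y * cos(th)
      (xr / sp$a)^2 + (yr / sp$b)^2 <= 1
    },
    blob = .pointInPolygon(X, Y, sp$vertices)
  )
}

# class id of plane points: 0 skin, 1 wound, 2..(1+nCells) patch cell
.sceneClassAt <- function(scene, X, Y) {
  g <- grossSideCm(scene@patch)
  ox <- scene@patchOffsetCm[1]; oy <- scene@patchOffsetCm[2]
  cls <- integer(length(X))
  inPatch <- X >= ox & X < ox + g & Y >= oy & Y < oy + g
  if (any(inPatch)) {
    cell <- scene@patch@cellSideCm
    ci <- pmin(floor((X[inPatch] - ox) / cell), scene@patch@gridCols - 1)
    ri <- pmin(floor((oy + g - Y[inPatch]) / cell), scene@patch@gridRows - 1)
    cls[inPatch] <- 2L + ri * scene@patch@gridCols + ci
  }
  cls[.insideWound(scene, X, Y)] <- 1L
  cls
}

#' Render a synthetic wound photograph with ground truth
#'
#' Projects the scene plane through an ideal pinhole camera and paints
#' skin, wound and the nine patch cells with adaptive antialiasing: pixels
#' whose corners all see the same scene element are filled directly, while
#' boundary-straddling pixels are area-averaged over a
#' \code{supersample} x \code{supersample} subgrid.  A Gaussian optical
#' PSF is then applied, the global illumination gains multiply each
#' channel, i.i.d. Gaussian pixel noise is added and values are clamped
#' to [0,1].  Identical (scene, cam, seed) gives bit-identical output.
#'
#' @param scene a [SceneSpec-class].
#' @param cam a [CaptureConfig-class].
#' @param seed RNG seed for the pixel noise; defaults to \code{scene@seed}.
#' @param supersample subgrid resolution for boundary pixels (>= 2;
#'   boundary coverage is resolved to 1/supersample^2).
#' @param psfSigma optical point-spread sigma in sensor pixels (0
#'   disables).  Real lenses always blur slightly; without this, rendered
#'   edges are staircases phase-locked to the pixel grid, which no camera
#'   produces.
#' @return A [RenderedScene-class] holding the image, the wound truth mask,
#'   the analytic truth area and the projected physical patch corners.
#' @examples
#' rs <- renderScene(sceneSpec(), captureConfig())
#' dim(rs@image)
#' @export
renderScene <- function(scene, cam, seed = scene@seed, supersample = 8L,
                        psfSigma = 0.5) {
  validObject(scene); validObject(cam)
  ss <- as.integer(supersample)
  stopifnot(ss >= 2L)
  H <- .cameraHomography(cam)
  g <- grossSideCm(scene@patch)
  ox <- scene@patchOffsetCm[1]; oy <- scene@patchOffsetCm[2]

  # physical patch corners, canonical order TL,TR,BR,BL (top = +y in plane)
  patchPlane <- rbind(c(ox, oy + g), c(ox + g, oy + g),
                      c(ox + g, oy), c(ox, oy))
  patchImg <- applyHomography(H, patchPlane)
  w <- cam@widthPx; h <- cam@heightPx
  .inFrame <- function(p) all(p[, 1] >= 0 & p[, 1] <= w - 1 &
                              p[, 2] >= 0 & p[, 2] <= h - 1)
  if (!.inFrame(patchImg))
    stop("patch projects partially outside the frame; move the camera back or recenter")
  bb <- .woundBBox(scene)
  woundCornersImg <- applyHomography(H, rbind(c(bb[1], bb[2]), c(bb[3], bb[2]),
                                              c(bb[3], bb[4]), c(bb[1], bb[4])))
  if (!.inFrame(woundCornersImg))
    stop("wound projects partially outside the frame; move the camera back or recenter")

  Hi <- solve(H)
  planeAt <- function(px, py) {
    d <- Hi %*% rbind(px, py, 1)
    list(X = d[1, ] / d[3, ], Y = d[2, ] / d[3, ])
  }
  classColors <- rbind(scene@skinColor, scene@woundColor,
                       scene@patch@referenceColors)

  # scene class at the (h+1) x (w+1) pixel-corner grid
  cxs <- seq_len(w + 1) - 1.5       # pixel x - 0.5, 0-based centers
  cys <- seq_len(h + 1) - 1.5
  pc <- planeAt(rep(cxs, each = h + 1), rep(cys, times = w + 1))
  Cgrid <- matrix(.sceneClassAt(scene, pc$X, pc$Y), h + 1, w + 1)
  sameRight <- Cgrid[, -(w + 1)] == Cgrid[, -1]
  flat <- sameRight[-(h + 1), ] & sameRight[-1, ] &
    (Cgrid[-(h + 1), -(w + 1)] == Cgrid[-1, -(w + 1)])
  baseCls <- Cgrid[-(h + 1), -(w + 1)]

  img <- array(0, c(h, w, 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(classColors[baseCls + 1L, ch], h, w)
  woundCov <- matrix(as.numeric(baseCls == 1L), h, w)

  mixed <- which(!flat)
  if (length(mixed)) {
    ai <- arrayInd(mixed, c(h, w))
    off <- (seq_len(ss) - 0.5) / ss - 0.5
    subx <- rep(off, each = ss); suby <- rep(off, times = ss)
    nM <- length(mixed)
    px <- rep(ai[, 2] - 1, times = ss * ss) +
      rep(subx, each = nM)
    py <- rep(ai[, 1] - 1, times = ss * ss) + rep(suby, each = nM)
    pp <- planeAt(px, py)
    cls <- .sceneClassAt(scene, pp$X, pp$Y)
    cm <- matrix(cls, nM, ss * ss)
    for (ch in 1:3)
      img[, , ch][mixed] <- rowMeans(matrix(classColors[cls + 1L, ch],
                                            nM, ss * ss))
    woundCov[mixed] <- rowMeans(cm == 1L)
  }

  for (ch in 1:3) {
    m <- if (psfSigma > 0) .gaussBlur(img[, , ch], psfSigma) else img[, , ch]
    img[, , ch] <- m * scene@illumination[ch]
  }
  if (scene@noiseSigma > 0) {
    img <- withSeed(seed,
      img + array(stats::rnorm(length(img), 0, scene@noiseSigma), dim(img)))
  }
  img[img < 0] <- 0; img[img > 1] <- 1

  mask <- matrix(as.numeric(woundCov >= 0.5), h, w)

  new("RenderedScene", image = img, truthMask = mask,
      truthAreaCm2 = scene@woundAreaCm2, patchCorners = patchImg,
      scene = scene, camera = cam)
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %s wound, %.3f cm^2, noise sigma %.3f, seed %d\n",
              object@woundShape, object@woundAreaCm2, object@noiseSigma,
              object@seed))
})

setMethod("show", "RenderedScene", function(object) {
  d <- dim(object@image)
  cat(sprintf(
    "RenderedScene: %d x %d px, truth area %.3f cm^2 (d = %g cm, theta = %g deg)\n",
    d[2], d[1], object@truthAreaCm2, object@camera@distanceCm,
    object@camera@angleDeg))
})
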