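#' PatchSpec: physical geometry and reference colors of the fiducial patch
#'
#' Describes the printed calibration patch placed in the wound plane: a
#' \code{gridRows} x \code{gridCols} grid of colored cells, each
#' \code{cellSideCm} cm on a side, together with the sRGB reference color of
#' every cell (row-major, values in [0,1]).  The patch provides both the
#' physical scale (known cell size) and the color references used for
#' device/illumination normalization.
#'
#' Validity requires all pairwise reference-color distances to be at least
#' 0.2 (so cells are identifiable under moderate noise) and the arrangement
#' to be asymmetric under in-plane rotation by 90/180/270 degrees (so the
#' patch orientation, and hence corner ordering, is unambiguous).
#'
#' @slot gridRows,gridCols integer grid dimensions (default patch: 3 x 3).
#' @slot cellSideCm side length of one cell in cm (default patch: 0.7).
#' @slot referenceColors numeric matrix (nCells x 3) of sRGB references.
#' @seealso [defaultPatchSpec()], [patchSpec()]
#' @export
setClass("PatchSpec",
  representation(
    gridRows = "integer",
    gridCols = "integer",
    cellSideCm = "numeric",
    referenceColors = "matrix"
  )
)

setValidity("PatchSpec", function(object) {
  n <- object@gridRows * object@gridCols
  rc <- object@referenceColors
  if (object@gridRows < 2L || object@gridCols < 2L)
    return("grid must be at least 2 x 2")
  if (length(object@cellSideCm) != 1L || object@cellSideCm <= 0)
    return("cellSideCm must be a positive scalar")
  if (!is.numeric(rc) || nrow(rc) != n || ncol(rc) != 3L)
    return(sprintf("referenceColors must be a %d x 3 matrix", n))
  if (any(rc < 0) || any(rc > 1))
    return("reference colors must lie in [0,1]")
  d <- as.matrix(stats::dist(rc))
  diag(d) <- Inf
  if (min(d) < 0.2)
    return("reference colors must have pairwise Euclidean distance >= 0.2")
  if (.patchRotationAmbiguous(rc, object@gridRows, object@gridCols))
    return("reference color arrangement is rotationally symmetric; orientation would be ambiguous")
  TRUE
})

# TRUE if rotating the cell-color arrangement by 90/180/270 deg reproduces it
.patchRotationAmbiguous <- function(rc, nr, nc) {
  if (nr != nc) return(FALSE)            # rectangular grids cannot alias under 90 deg
  idx <- matrix(seq_len(nr * nc), nr, nc, byrow = TRUE)
  rot <- idx
  for (k in 1:3) {
    rot <- t(rot)[, seq_len(nr), drop = FALSE][, nr:1, drop = FALSE]  # rotate 90 deg
    if (max(abs(rc[as.vector(t(rot)), , drop = FALSE] - rc)) < 1e-9) return(TRUE)
  }
  FALSE
}

#' SceneSpec: description of a synthetic wound scene
#'
#' A planar scene (the wound plane, z = 0, coordinates in cm, +y up) holding
#' one wound of known analytic area and one fiducial color patch.  Used by
#' [renderScene()] to produce ground-truth-known photographs.
#'
#' @slot woundShape one of "circle", "ellipse", "blob".
#' @slot shapeParams list of shape parameters in cm: circle \code{r};
#'   ellipse \code{a}, \code{b} (semi-axes) and optional \code{theta}
#'   rotation (radians); blob \code{vertices} (n x 2 closed polygon).
#' @slot woundAreaCm2 analytic wound area (ground truth).
#' @slot woundColor,skinColor sRGB triples in [0,1].
#' @slot patch a [PatchSpec-class].
#' @slot patchOffsetCm scene-plane position (cm) of the patch's lower-left
#'   corner; the patch is coplanar with the wound.
#' @slot illumination per-channel multiplicative gains (> 0) applied to the
#'   whole rendered frame (global tint).
#' @slot noiseSigma standard deviation of i.i.d. Gaussian pixel noise.
#' @slot seed integer RNG seed used when rendering.
#' @seealso [sceneSpec()], [renderScene()], [truthArea()]
#' @export
setClass("SceneSpec",
  representation(
    woundShape = "character",
    shapeParams = "list",
    woundAreaCm2 = "numeric",
    woundColor = "numeric",
    skinColor = "numeric",
    patch = "PatchSpec",
    patchOffsetCm = "numeric",
    illumination = "numeric",
    noiseSigma = "numeric",
    seed = "integer"
  )
)

setValidity("SceneSpec", function(object) {
  if (!object@woundShape %in% c("circle", "ellipse", "blob"))
    return("woundShape must be one of circle, ellipse, blob")
  if (length(object@woundAreaCm2) != 1L || !is.finite(object@woundAreaCm2) ||
      object@woundAreaCm2 <= 0)
    return("woundAreaCm2 must be a positive scalar")
  for (s in c("woundColor", "skinColor"))
    if (length(slot(object, s)) != 3L || any(slot(object, s) < 0) ||
        any(slot(object, s) > 1))
      return(sprintf("%s must be an RGB triple in [0,1]", s))
  if (length(object@patchOffsetCm) != 2L)
    return("patchOffsetCm must be a 2-vector")
  if (length(object@illumination) != 3L || any(object@illumination <= 0))
    return("illumination gains must be three positive reals")
  if (object@noiseSigma < 0)
    return("noiseSigma must be non-negative")
  if (.sceneFootprintsOverlap(object))
    return("wound and patch footprints overlap")
  TRUE
})

# overlap test: exact circle-to-rectangle distance for circles, wound
# bounding box vs patch square otherwise (conservative)
.sceneFootprintsOverlap <- function(scene) {
  g <- scene@patch@gridRows * scene@patch@cellSideCm
  px0 <- scene@patchOffsetCm[1]; py0 <- scene@patchOffsetCm[2]
  if (scene@woundShape == "circle") {
    dx <- max(px0 - 0, 0 - (px0 + g), 0)
    dy <- max(py0 - 0, 0 - (py0 + g), 0)
    return(sqrt(dx^2 + dy^2) < scene@shapeParams$r)
  }
  bb <- .woundBBox(scene)
  !(bb[3] <= px0 || bb[1] >= px0 + g || bb[4] <= py0 || bb[2] >= py0 + g)
}

#' CaptureConfig: pinhole camera placement and intrinsics
#'
#' The camera sits at distance \code{distanceCm} from the point where its
#' optical axis meets the wound plane; \code{angleDeg} is the elevation angle
#' between the optical axis and the plane, so 90 degrees is a perpendicular
#' (fronto-parallel) capture.
#'
#' @slot distanceCm camera-to-plane distance along the optical axis, cm.
#' @slot angleDeg elevation angle in (0, 90].
#' @slot focalPx focal length in pixels.
#' @slot widthPx,heightPx image dimensions in pixels.
#' @seealso [captureConfig()], [renderScene()]
#' @export
setClass("CaptureConfig",
  representation(
    distanceCm = "numeric",
    angleDeg = "numeric",
    focalPx = "numeric",
    widthPx = "integer",
    heightPx = "integer"
  )
)

setValidity("CaptureConfig", function(object) {
  if (object@distanceCm <= 0) return("distanceCm must be positive")
  if (object@angleDeg <= 0 || object@angleDeg > 90)
    return("angleDeg must lie in (0, 90]")
  if (object@focalPx <= 0) return("focalPx must be positive")
  if (object@widthPx < 8L || object@heightPx < 8L)
    return("image dimensions too small")
  TRUE
})

#' RenderedScene: a synthetic photograph with ground truth
#'
#' @slot image h x w x 3 array, sRGB in [0,1].
#' @slot truthMask h x w binary matrix of wound pixels (1 = wound).
#' @slot truthAreaCm2 analytic wound area in cm^2.
#' @slot patchCorners 4 x 2 matrix of projected physical patch corners in
#'   image coordinates (0-based pixel centers), canonical order TL, TR, BR,
#'   BL as seen on the physical patch.
#' @slot scene,camera the inputs that produced the render.
#' @export
setClass("RenderedScene",
  representation(
    image = "array",
    truthMask = "matrix",
    truthAreaCm2 = "numeric",
    patchCorners = "matrix",
    scene = "SceneSpec",
    camera = "CaptureConfig"
  )
)

#' PatchDetection: located fiducial patch in an image
#'
#' @slot corners 4 x 2 matrix of outer patch corners in image coordinates,
#'   canonical order (TL, TR, BR, BL of the physical patch; the 4-fold
#'   rotation ambiguity is resolved by matching cell colors).
#' @slot cellColors nCells x 3 observed mean cell colors, row-major physical
#'   order; rows of undetected cells are NA.
#' @slot cellCentroids nCells x 2 observed cell centroids (NA where missing).
#' @slot confidence fraction of detected cells whose observed mean color is
#'   nearest its own reference.
#' @export
setClass("PatchDetection",
  representation(
    corners = "matrix",
    cellColors = "matrix",
    cellCentroids = "matrix",
    confidence = "numeric"
  )
)

setValidity("PatchDetection", function(object) {
  if (nrow(object@corners) != 4L || ncol(object@corners) != 2L)
    return("corners must be 4 x 2")
  if (!.isConvexQuad(object@corners))
    return("corners must form a convex, non-degenerate quadrilateral")
  TRUE
})

#' Homography: 3 x 3 planar projective map
#'
#' Normalized so the bottom-right entry is 1.  \code{scaleCmPerPx} is the
#' physical scale of the rectified frame and is populated by
#' [rectifyImage()]; it is NA for a bare point-map homography.
#'
#' @slot H 3 x 3 matrix, \code{H[3,3] == 1}.
#' @slot scaleCmPerPx cm per rectified pixel, or NA.
#' @export
setClass("Homography",
  representation(H = "matrix", scaleCmPerPx = "numeric"),
  prototype(scaleCmPerPx = NA_real_)
)

setValidity("Homography", function(object) {
  if (any(dim(object@H) != c(3L, 3L))) return("H must be 3 x 3")
  if (abs(object@H[3, 3] - 1) > 1e-12) return("H must be normalized to H[3,3] = 1")
  if (abs(det(object@H)) < 1e-12) return("H must be invertible")
  TRUE
})

#' RectifiedImage: fronto-parallel view of the wound plane
#'
#' Produced by [rectifyImage()].  Pixel (x, y) corresponds to the plane
#' point \code{offsetCm + scaleCmPerPx * c(x, y)} in the canonical frame
#' whose origin is the patch's top-left corner, x rightward, y downward.
#'
#' @slot image h x w x 3 array in [0,1].
#' @slot scaleCmPerPx physical scale of the frame.
#' @slot patchRegion c(x0, y0, x1, y1), 0-based pixel rectangle occupied by
#'   the patch (excluded from segmentation).
#' @slot offsetCm canonical-frame cm coordinates of pixel (0, 0).
#' @slot homography the image-to-canonical-cm [Homography-class].
#' @export
setClass("RectifiedImage",
  representation(
    image = "array",
    scaleCmPerPx = "numeric",
    patchRegion = "numeric",
    offsetCm = "numeric",
    homography = "Homography"
  )
)

#' ColorCorrection: affine device/illumination color map
#'
#' Per output channel an affine function of the input RGB:
#' \code{out = M[, 1:3] \%*\% in + M[, 4]}.
#'
#' @slot M 3 x 4 matrix (3 x 3 gain block, 4th column offsets).
#' @slot fitResidualRms RMS residual of the reference fit.
#' @export
setClass("ColorCorrection",
  representation(M = "matrix", fitResidualRms = "numeric")
)

setValidity("ColorCorrection", function(object) {
  if (any(dim(object@M) != c(3L, 4L))) return("M must be 3 x 4")
  if (abs(det(object@M[, 1:3])) < 1e-12) return("gain block must be invertible")
  TRUE
})

#' SnakeParams: active-contour evolution parameters
#'
#' \code{alpha} weights the first-derivative (elasticity) internal term,
#' \code{beta} the second-derivative (rigidity) term, \code{gamma} is the
#' evolution step size and \code{kappa} the external (GVF) force weight.
#' Defaults are the fixed values used throughout: 0.2, 0.2, 1.0, 0.5.
#'
#' @slot alpha,beta,gamma,kappa positive reals.
#' @slot maxIter iteration cap.
#' @slot tolPx convergence threshold on mean vertex displacement (px).
#' @seealso [snakeParams()], [evolveSnake()]
#' @export
setClass("SnakeParams",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 kappa = "numeric", maxIter = "integer", tolPx = "numeric")
)

setValidity("SnakeParams", function(object) {
  if (object@alpha <= 0 || object@beta <= 0 || object@gamma <= 0 ||
      object@kappa <= 0)
    return("alpha, beta, gamma, kappa must all be positive")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (object@tolPx <= 0) return("tolPx must be positive")
  TRUE
})

#' GVFParams: gradient-vector-flow diffusion parameters
#'
#' @slot mu regularization weight of the diffusion term.
#' @slot nIter iteration count; NA means scale with image size
#'   (80 * max(side) / 64, the package default).
#' @slot dt explicit-scheme time step; stability requires dt <= 1/(4*mu).
#' @seealso [gvfParams()], [computeGVF()]
#' @export
setClass("GVFParams",
  representation(mu = "numeric", nIter = "integer", dt = "numeric")
)

setValidity("GVFParams", function(object) {
  if (object@mu <= 0) return("mu must be positive")
  if (object@dt <= 0) return("dt must be positive")
  if (object@dt > 1 / (4 * object@mu) + 1e-12)
    return("stability requires dt <= 1/(4*mu)")
  if (!is.na(object@nIter) && object@nIter < 1L)
    return("nIter must be >= 1 (or NA for size-scaled default)")
  TRUE
})

#' EdgeMap: normalized gradient-magnitude edge strength
#'
#' @slot f h x w matrix in [0,1] (min-max normalized gradient magnitude of
#'   the Gaussian-smoothed luma).
#' @slot sigma smoothing sigma (px) used to build the map.
#' @export
setClass("EdgeMap", representation(f = "matrix", sigma = "numeric"))

setValidity("EdgeMap", function(object) {
  if (any(object@f < -1e-12) || any(object@f > 1 + 1e-12))
    return("edge map values must lie in [0,1]")
  TRUE
})

#' GVFField: gradient-vector-flow external force field
#'
#' @slot u,v h x w matrices, the x and y force components.
#' @slot residual max component update of the final diffusion iteration.
#' @slot iterations diffusion iterations actually run.
#' @export
setClass("GVFField",
  representation(u = "matrix", v = "matrix", residual = "numeric",
                 iterations = "integer")
)

#' WoundMeasurement: result of the full per-image pipeline
#'
#' @slot areaCm2 wound area from the sub-pixel contour polygon, cm^2.
#' @slot lwAreaCm2 conventional length x width baseline, cm^2.
#' @slot contour closed wound contour (n x 2, rectified-frame px).
#' @slot scaleCmPerPx rectified-frame scale.
#' @slot stageReport named list of per-stage status, parameters, diagnostics.
#' @slot capture passthrough capture metadata list.
#' @export
setClass("WoundMeasurement",
  representation(
    areaCm2 = "numeric",
    lwAreaCm2 = "numeric",
    contour = "matrix",
    scaleCmPerPx = "numeric",
    stageReport = "list",
    capture = "list"
  )
)

#' WoundSeries: dated area measurements for one patient
#'
#' @slot patientId identifier.
#' @slot siteClass "facial" or "non_facial".
#' @slot days strictly increasing observation days; first day is 0
#'   (start of dressing).
#' @slot areasCm2 positive wound/scar areas, one per day.
#' @seealso [woundSeries()], [summarizeSeries()]
#' @export
setClass("WoundSeries",
  representation(patientId = "character", siteClass = "character",
                 days = "numeric", areasCm2 = "numeric")
)

setValidity("WoundSeries", function(object) {
  if (length(object@days) < 1L) return("at least one observation required")
  if (length(object@days) != length(object@areasCm2))
    return("days and areasCm2 must have equal length")
  if (object@days[1] != 0) return("first observation day must be 0")
  if (any(diff(object@days) <= 0)) return("days must be strictly increasing")
  if (any(object@areasCm2 <= 0)) return("areas must be positive")
  if (!object@siteClass %in% c("facial", "non_facial"))
    return("siteClass must be 'facial' or 'non_facial'")
  TRUE
})

#' HealingSummary: per-patient healing statistics
#'
#' @slot patientId,siteClass passthrough identifiers.
#' @slot initialAreaCm2,finalAreaCm2 first and last observed areas.
#' @slot decreaseRatePct 100 * (initial - final) / initial.
#' @slot halfDecrementDay first day the area reaches the initial area minus
#'   half the total decrement (linear interpolation between visits); NA when
#'   undefined (single visit or no net decrease).
#' @slot nObservations,followUpDays series length and last observation day.
#' @export
setClass("HealingSummary",
  representation(
    patientId = "character", siteClass = "character",
    initialAreaCm2 = "numeric", finalAreaCm2 = "numeric",
    decreaseRatePct = "numeric", halfDecrementDay = "numeric",
    nObservations = "integer", followUpDays = "numeric"
  )
)
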