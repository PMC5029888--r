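#' Detect the fiducial color patch in a photograph
#'
#' Pixels are classified against the patch's reference colors; each
#' reference keeps its best-matching connected component (nearest mean
#' color, plausible size).  The located cell centroids, whose physical
#' identities are known from their colors, are fitted by a least-squares
#' homography to the canonical cell centers — this simultaneously resolves
#' the 4-fold rotation ambiguity — and the outer corners are read off the
#' fitted map.  Gross centroid outliers are dropped and the fit repeated.
#'
#' @param image h x w x 3 array in [0,1], or a [RenderedScene-class].
#' @param spec the [PatchSpec-class] to look for.
#' @param maxColorDist maximum RGB distance for a pixel to count as a cell
#'   candidate.
#' @param minCellPx minimum component size (px) for a candidate cell.
#' @param refine subpixel-refine the homography on the patch's grid lines
#'   (gradient-peak localization in a high-resolution rectified patch
#'   window, refit on the 16 grid intersections).  The fiducial is small,
#'   so the perspective terms estimated from cell centroids alone carry
#'   pixel-quantization error that amplifies with distance from the patch;
#'   refinement suppresses this and is on by default.
#' @return A [PatchDetection-class] with canonical-order outer corners,
#'   observed cell colors/centroids, and a confidence score (fraction of
#'   detected cells whose mean color is nearest its own reference).
#' @section Errors: "patch not detected" when fewer than 7 of the 9 cells
#'   are found, or when the found centroids are inconsistent with a single
#'   planar homography.
#' @export
detectPatch <- function(image, spec = defaultPatchSpec(),
                        maxColorDist = 0.3, minCellPx = 15L,
                        refine = TRUE) {
  if (is(image, "RenderedScene")) image <- image@image
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  nCells <- nrow(spec@referenceColors)
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))

  # nearest reference per pixel
  d2 <- sapply(seq_len(nCells), function(k) {
    rc <- spec@referenceColors[k, ]
    (px[, 1] - rc[1])^2 + (px[, 2] - rc[2])^2 + (px[, 3] - rc[3])^2
  })
  assign <- max.col(-d2)
  mind2 <- d2[cbind(seq_len(nrow(d2)), assign)]
  candidate <- mind2 < maxColorDist^2

  centroids <- matrix(NA_real_, nCells, 2)
  cellCols <- matrix(NA_real_, nCells, 3)
  maxCellPx <- 0.05 * h * w
  for (k in seq_len(nCells)) {
    mk <- matrix(as.numeric(candidate & assign == k), h, w)
    if (!any(mk > 0)) next
    lab <- EBImage::bwlabel(mk)
    sizes <- tabulate(lab[lab > 0])
    ok <- which(sizes >= minCellPx & sizes <= maxCellPx)
    if (!length(ok)) next
    best <- NULL; bestD <- Inf
    for (li in ok) {
      idx <- which(lab == li)
      mc <- c(mean(image[, , 1][idx]), mean(image[, , 2][idx]),
              mean(image[, , 3][idx]))
      dd <- sum((mc - spec@referenceColors[k, ])^2)
      if (dd < bestD) { bestD <- dd; best <- list(idx = idx, col = mc) }
    }
    # centroid over the eroded interior: antialiased boundary pixels pass
    # the color threshold asymmetrically and would bias the centroid
    comp <- matrix(FALSE, h, w); comp[best$idx] <- TRUE
    interior <- comp &
      rbind(FALSE, comp[-h, ]) & rbind(comp[-1, ], FALSE) &
      cbind(FALSE, comp[, -w]) & cbind(comp[, -1], FALSE)
    use <- if (sum(interior) >= 5L) which(interior) else best$idx
    ai <- arrayInd(use, c(h, w))
    centroids[k, ] <- c(mean(ai[, 2]) - 1, mean(ai[, 1]) - 1)  # (x, y), 0-based
    cellCols[k, ] <- c(mean(image[, , 1][use]), mean(image[, , 2][use]),
                       mean(image[, , 3][use]))
  }

  found <- which(!is.na(centroids[, 1]))
  if (length(found) < 7L)
    .stopStage("detect", sprintf(
      "patch not detected (%d of %d cells matched)", length(found), nCells))

  canon <- .canonicalCellCenters(spec)
  fitIdx <- found
  H <- estimateHomography(canon[fitIdx, , drop = FALSE],
                          centroids[fitIdx, , drop = FALSE])
  # drop gross outliers (misclassified background components) and refit
  repeat {
    pred <- applyHomography(H, canon[fitIdx, , drop = FALSE])
    res <- sqrt(rowSums((pred - centroids[fitIdx, , drop = FALSE])^2))
    cellPx <- spec@cellSideCm / .localScaleCmPerPx(H, canon[fitIdx[1], ])
    if (max(res) <= 0.25 * cellPx || length(fitIdx) <= 6L) break
    fitIdx <- fitIdx[-which.max(res)]
    H <- estimateHomography(canon[fitIdx, , drop = FALSE],
                            centroids[fitIdx, , drop = FALSE])
  }
  pred <- applyHomography(H, canon[fitIdx, , drop = FALSE])
  res <- sqrt(rowSums((pred - centroids[fitIdx, , drop = FALSE])^2))
  cellPx <- spec@cellSideCm / .localScaleCmPerPx(H, canon[fitIdx[1], ])
  if (length(fitIdx) < 6L || mean(res) > 0.25 * cellPx)
    .stopStage("detect",
               "patch not detected (cell layout inconsistent with a planar homography)")

  if (refine)
    for (pass in 1:2)
      H <- tryCatch(.refinePatchHomography(image, spec, H@H, cellCols),
                    error = function(e) H)
  corners <- applyHomography(H, .canonicalCorners(spec))
  conf <- mean(sapply(found, function(k) {
    dd <- colSums((t(spec@referenceColors) - cellCols[k, ])^2)
    which.min(dd) == k
  }))
  new("PatchDetection", corners = corners, cellColors = cellCols,
      cellCentroids = centroids, confidence = conf)
}

# Subpixel homography refinement on the patch's grid lines.
# H0 maps canonical cm -> image px.  The patch neighborhood is resampled at
# high resolution through H0; each grid line (cell boundary) is localized
# per sample row as the midpoint crossing of the color-blend coordinate
# t = (c - A).(B - A)/|B - A|^2 between the two adjacent cell colors A, B
# (exact for a linearly antialiased edge ramp; median over rows), and the
# 16 refined grid intersections are refit against their canonical
# positions.
.refinePatchHomography <- function(image, spec, H0, cellCols = NULL,
                                   pxPerCm = 60, returnNodes = FALSE) {
  g <- grossSideCm(spec)
  cell <- spec@cellSideCm
  nr <- spec@gridRows; nc <- spec@gridCols
  if (is.null(cellCols)) cellCols <- spec@referenceColors
  miss <- !is.finite(cellCols[, 1])
  cellCols[miss, ] <- spec@referenceColors[miss, , drop = FALSE]
  skin <- .borderMedian(image)
  pad <- 0.4 * cell
  s <- 1 / pxPerCm
  coords <- seq(-pad, g + pad, by = s)
  n <- length(coords)
  P <- H0 %*% rbind(rep(coords, times = n), rep(coords, each = n), 1)
  ix <- P[1, ] / P[3, ]; iy <- P[2, ] / P[3, ]
  win <- array(0, c(n, n, 3))     # [row = canonical y, col = canonical x]
  for (ch in 1:3)
    win[, , ch] <- matrix(.bilinear(image[, , ch], ix, iy), n, n, byrow = TRUE)

  cellColor <- function(r, cc) {   # 1-based; outside the grid -> skin
    if (r < 1 || r > nr || cc < 1 || cc > nc) skin
    else cellCols[(r - 1) * nc + cc, ]
  }
  # rows (indices into coords) well inside each cell band, with their band
  bandIdx <- lapply(seq_len(nr), function(r)
    which(coords > (r - 1) * cell + 0.25 * cell &
          coords < r * cell - 0.25 * cell))
  wHalf <- max(3L, round(0.15 * cell / s))
  # edge position as the first moment of the blend-profile derivative:
  # t(x) ramps 0 -> 1 across the edge, so sum(dt * x_mid) / sum(dt) is the
  # profile-symmetric edge location, robust to sampling phase (a midpoint
  # crossing by linear interpolation carries a phase-systematic bias that,
  # amplified by extrapolation away from the small fiducial, is visible in
  # the recovered scale)
  crossAt <- function(profile, A, B, js) {
    # channels whose endpoints sit at the sensor rails may have been
    # clipped, kinking the blend profile; use only reliably linear ones
    valid <- A > 0.004 & A < 0.996 & B > 0.004 & B < 0.996
    if (!any(valid)) {
      valid <- rep(TRUE, 3)   # all-rail pair (e.g. skin|white): keep all
    }
    A <- A[valid]; B <- B[valid]
    profile <- profile[, valid, drop = FALSE]
    BA <- B - A
    den <- sum(BA^2)
    if (den < 1e-3) return(NA_real_)
    tv <- as.numeric((profile %*% BA - sum(A * BA)) / den)
    dt <- diff(tv)
    tot <- sum(dt)
    if (!is.finite(tot) || abs(tot) < 0.5) return(NA_real_)
    xm <- (coords[js[-length(js)]] + coords[js[-1]]) / 2
    sum(dt * xm) / tot
  }
  # each grid line is fitted as a straight line (cross-position regressed
  # on the along-coordinate), since residual error in H0 leaves the lines
  # slightly slanted in the rectified window
  locateLine <- function(k, vertical) {  # grid line k in 0..nc (or nr)
    cI <- which.min(abs(coords - k * cell))
    js <- max(1, cI - wHalf):min(n, cI + wHalf)
    pts <- do.call(rbind, lapply(seq_len(if (vertical) nr else nc),
                                 function(band) {
      A <- if (vertical) cellColor(band, k) else cellColor(k, band)
      B <- if (vertical) cellColor(band, k + 1) else cellColor(k + 1, band)
      cross <- vapply(bandIdx[[band]], function(ri) {
        prof <- if (vertical) win[ri, js, ] else win[js, ri, ]
        crossAt(matrix(prof, ncol = 3), A, B, js)
      }, numeric(1))
      cbind(along = coords[bandIdx[[band]]], cross = cross)
    }))
    pts <- pts[is.finite(pts[, 2]), , drop = FALSE]
    if (nrow(pts) < 5L) stop("grid-line localization failed")
    stats::coef(stats::lm.fit(cbind(1, pts[, 1]), pts[, 2]))  # (intercept, slope)
  }
  V <- vapply(0:nc, function(k) locateLine(k, TRUE), numeric(2))   # x = a + b y
  Hh <- vapply(0:nr, function(k) locateLine(k, FALSE), numeric(2)) # y = a + b x
  obsC <- NULL; canC <- NULL
  for (j in 0:nr) for (k in 0:nc) {
    av <- V[1, k + 1]; bv <- V[2, k + 1]
    ah <- Hh[1, j + 1]; bh <- Hh[2, j + 1]
    x <- (av + bv * ah) / (1 - bv * bh)
    y <- ah + bh * x
    obsC <- rbind(obsC, c(x, y))
    canC <- rbind(canC, c(k * cell, j * cell))
  }
  if (any(!is.finite(obsC))) stop("grid-line localization failed")
  obsImg <- applyHomography(H0, obsC)
  if (returnNodes) return(list(nodes = obsImg, canonical = canC))
  estimateHomography(canC, obsImg)
}

#' Measure the patch cell side from a rectified image
#'
#' Locates the patch's grid lines in the rectified frame (subpixel
#' blend-profile localization, straight-line fits) and reports the mean
#' spacing of adjacent grid intersections converted to cm via the
#' recovered scale.  For a correct calibration this recovers the physical
#' cell side (0.7 cm for the default patch).
#'
#' @param rect a [RectifiedImage-class].
#' @param spec the [PatchSpec-class].
#' @return list(cellSideCm = mean measured side, n = number of adjacent
#'   intersection pairs used).
#' @export
measureCellSideCm <- function(rect, spec = defaultPatchSpec()) {
  stopifnot(is(rect, "RectifiedImage"))
  s <- rect@scaleCmPerPx
  H0 <- matrix(c(1 / s, 0, -rect@offsetCm[1] / s,
                 0, 1 / s, -rect@offsetCm[2] / s,
                 0, 0, 1), 3, 3, byrow = TRUE)   # canonical cm -> rectified px
  obs <- tryCatch(sampleCellColors(rect, spec), error = function(e) NULL)
  nd <- .refinePatchHomography(rect@image, spec, H0, cellCols = obs,
                               pxPerCm = max(60, 1.2 / s),
                               returnNodes = TRUE)
  nc1 <- spec@gridCols + 1L
  nr1 <- spec@gridRows + 1L
  # nodes are ordered j (rows) outer, k (cols) inner
  idx <- function(k, j) j * nc1 + k + 1L
  spac <- c()
  for (j in 0:(nr1 - 1L)) for (k in 0:(nc1 - 2L))
    spac <- c(spac, sqrt(sum((nd$nodes[idx(k + 1L, j), ] -
                              nd$nodes[idx(k, j), ])^2)))
  for (j in 0:(nr1 - 2L)) for (k in 0:(nc1 - 1L))
    spac <- c(spac, sqrt(sum((nd$nodes[idx(k, j + 1L), ] -
                              nd$nodes[idx(k, j), ])^2)))
  list(cellSideCm = mean(spac) * s, n = length(spac))
}

# local cm-per-pixel scale of a canonical(cm)->image homography near a point
.localScaleCmPerPx <- function(H, at) {
  e <- 0.05
  p <- applyHomography(H, rbind(at, at + c(e, 0), at + c(0, e)))
  px <- mean(c(sqrt(sum((p[2, ] - p[1, ])^2)), sqrt(sum((p[3, ] - p[1, ])^2))))
  e / px
}

setMethod("show", "PatchDetection", function(object) {
  cat(sprintf("PatchDetection: %d/%d cells, confidence %.2f\n",
              sum(!is.na(object@cellCentroids[, 1])),
              nrow(object@cellCentroids), object@confidence))
  cat("  corners (TL,TR,BR,BL):\n")
  print(round(object@corners, 2))
})
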