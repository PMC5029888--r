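#' Fit an affine color correction from observed patch colors
#'
#' Least-squares affine map (3 x 3 gain block + per-channel offset) sending
#' the observed cell colors to the patch's reference colors.  Nine
#' well-separated observations determine the 12 parameters with slack, and
#' the affine form captures channel cross-talk that a diagonal gain cannot.
#' Colors are processed in the image's native sRGB encoding.
#'
#' @param observed n x 3 matrix of observed cell colors (n >= 4).
#' @param reference n x 3 matrix of the corresponding reference colors.
#' @param robust downweight outlying observations (2 rounds of Huber
#'   reweighting per channel).  Cells driven into sensor saturation by a
#'   strong tint violate the affine model; the robust fit recovers the
#'   correction from the unclipped cells.
#' @return A [ColorCorrection-class] with the fitted matrix and the
#'   (unweighted) RMS residual of the fit.
#' @section Errors: "degenerate color set" when the observed colors do not
#'   span three dimensions (e.g. all gray).
#' @examples
#' refs <- referenceColors(defaultPatchSpec())
#' corr <- fitColorCorrection(refs * 0.5, refs)
#' corr@M[, 1:3]          # 2 * identity
#' @export
fitColorCorrection <- function(observed, reference, robust = TRUE) {
  observed <- as.matrix(observed); reference <- as.matrix(reference)
  stopifnot(ncol(observed) == 3L, ncol(reference) == 3L,
            nrow(observed) == nrow(reference))
  if (nrow(observed) < 4L)
    stop("at least 4 color correspondences required")
  A <- cbind(observed, 1)
  if (qr(A)$rank < 4L)
    .stopStage("normalize", "degenerate color set (observed colors do not span 3 dimensions)")
  M <- matrix(0, 3, 4)
  for (ch in 1:3) {
    wts <- rep(1, nrow(A))
    for (pass in 1:(if (robust) 3 else 1)) {
      fit <- stats::lm.wfit(A, reference[, ch], wts)
      if (pass == 3 || !robust) break
      r <- abs(fit$residuals)
      k <- max(0.02, 1.5 * stats::median(r))      # Huber threshold
      wts <- ifelse(r <= k, 1, k / r)
    }
    M[ch, ] <- fit$coefficients
  }
  resid <- A %*% t(M) - reference
  new("ColorCorrection", M = M, fitResidualRms = sqrt(mean(resid^2)))
}

#' Apply a color correction to an image
#'
#' Per-pixel affine transform, clamped to [0,1].  The identity correction
#' returns the input bit-identically (for in-range input).
#'
#' @param image h x w x 3 array in [0,1], or a [RectifiedImage-class]
#'   (returned with its image replaced).
#' @param corr a [ColorCorrection-class].
#' @return Same container as \code{image}.
#' @export
applyColorCorrection <- function(image, corr) {
  if (is(image, "RectifiedImage")) {
    image@image <- applyColorCorrection(image@image, corr)
    return(image)
  }
  d <- dim(image)
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  out <- px %*% t(corr@M[, 1:3, drop = FALSE])
  out <- sweep(out, 2, corr@M[, 4], `+`)
  out[out < 0] <- 0; out[out > 1] <- 1
  array(out, d)
}

#' Sample the observed cell colors from a rectified image
#'
#' The patch occupies a known axis-aligned square in the rectified frame,
#' so each cell's color is read as the mean over the central
#' \code{innerFrac} of the cell (avoiding edge bleed from interpolation).
#'
#' @param rect a [RectifiedImage-class].
#' @param spec the [PatchSpec-class].
#' @param innerFrac linear fraction of the cell side sampled (default 0.6).
#' @return nCells x 3 matrix of mean colors, row-major physical order.
#' @export
sampleCellColors <- function(rect, spec = defaultPatchSpec(),
                             innerFrac = 0.6) {
  stopifnot(is(rect, "RectifiedImage"), innerFrac > 0, innerFrac <= 1)
  s <- rect@scaleCmPerPx
  cellPx <- spec@cellSideCm / s
  x0 <- rect@patchRegion[1]; y0 <- rect@patchRegion[2]
  h <- dim(rect@image)[1]; w <- dim(rect@image)[2]
  out <- matrix(NA_real_, spec@gridRows * spec@gridCols, 3)
  half <- innerFrac / 2
  k <- 0L
  for (r in seq_len(spec@gridRows)) {
    for (cc in seq_len(spec@gridCols)) {
      k <- k + 1L
      cx <- x0 + (cc - 0.5) * cellPx
      cy <- y0 + (r - 0.5) * cellPx
      xs <- max(0, round(cx - half * cellPx)):min(w - 1, round(cx + half * cellPx))
      ys <- max(0, round(cy - half * cellPx)):min(h - 1, round(cy + half * cellPx))
      out[k, ] <- sapply(1:3, function(ch)
        mean(rect@image[ys + 1, xs + 1, ch]))
    }
  }
  out
}

#' Fit and apply patch-based color normalization to a rectified image
#'
#' Convenience wrapper: samples the rectified patch cells, fits the affine
#' correction against the patch references, applies it.
#'
#' @param rect a [RectifiedImage-class].
#' @param spec the [PatchSpec-class].
#' @return list(rect = corrected [RectifiedImage-class],
#'   correction = [ColorCorrection-class]).
#' @export
normalizeColors <- function(rect, spec = defaultPatchSpec()) {
  obs <- sampleCellColors(rect, spec)
  corr <- fitColorCorrection(obs, spec@referenceColors)
  list(rect = applyColorCorrection(rect, corr), correction = corr)
}

setMethod("show", "ColorCorrection", function(object) {
  cat(sprintf("ColorCorrection (affine 3 x 4), fit RMS residual %.5f\n",
              object@fitResidualRms))
  print(round(object@M, 4))
})
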