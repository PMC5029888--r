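#' Rectify a photograph to the fronto-parallel wound plane
#'
#' Estimates the image-to-plane homography from the four detected patch
#' corners (the patch's physical size is known, so the rectified frame has
#' an absolute scale) and warps the image by bilinear interpolation so the
#' wound plane appears fronto-parallel.  In the rectified frame pixel area
#' is proportional to physical area: \code{scaleCmPerPx = 1 / targetPxPerCm}.
#'
#' The output frame covers the warped footprint of the input image,
#' intersected with a window of half-extent \code{maxExtentCm} around the
#' patch (oblique captures can back-project to arbitrarily distant plane
#' points, which carry no usable detail).  Pixels that fall outside the
#' input frame are filled with the input's border-median color.
#'
#' @param image h x w x 3 array in [0,1], or a [RenderedScene-class].
#' @param det a [PatchDetection-class] for this image.
#' @param spec the [PatchSpec-class] that was detected.
#' @param targetPxPerCm rectified sampling density (px per cm).
#' @param maxExtentCm half-extent (cm) of the kept window around the patch.
#' @param maxRasterPx error threshold on output pixel count.
#' @return A [RectifiedImage-class].
#' @export
rectifyImage <- function(image, det, spec = defaultPatchSpec(),
                         targetPxPerCm = 100, maxExtentCm = 12,
                         maxRasterPx = 3e7) {
  if (is(image, "RenderedScene")) image <- image@image
  stopifnot(targetPxPerCm > 0)
  h <- dim(image)[1]; w <- dim(image)[2]
  canon <- .canonicalCorners(spec)
  Hic <- estimateHomography(det@corners, canon)     # image px -> canonical cm

  # warped footprint of the input frame, in canonical cm
  t1 <- seq(0, 1, length.out = 25)
  edge <- function(a, b) cbind(a[1] + t1 * (b[1] - a[1]),
                               a[2] + t1 * (b[2] - a[2]))
  fc <- rbind(c(0, 0), c(w - 1, 0), c(w - 1, h - 1), c(0, h - 1))
  bnd <- rbind(edge(fc[1, ], fc[2, ]), edge(fc[2, ], fc[3, ]),
               edge(fc[3, ], fc[4, ]), edge(fc[4, ], fc[1, ]))
  P <- Hic@H %*% rbind(t(bnd), 1)
  keep <- P[3, ] * (Hic@H %*% c(det@corners[1, ], 1))[3] > 1e-9   # same side of the vanishing line as the patch
  if (sum(keep) < 4L) keep <- rep(TRUE, ncol(P))
  cm <- t(P[1:2, keep, drop = FALSE] / rep(P[3, keep], each = 2))
  g <- grossSideCm(spec)
  ctr <- c(g / 2, g / 2)
  x0 <- max(min(cm[, 1]), ctr[1] - maxExtentCm)
  x1 <- min(max(cm[, 1]), ctr[1] + maxExtentCm)
  y0 <- max(min(cm[, 2]), ctr[2] - maxExtentCm)
  y1 <- min(max(cm[, 2]), ctr[2] + maxExtentCm)
  s <- 1 / targetPxPerCm
  outW <- ceiling((x1 - x0) / s) + 1L
  outH <- ceiling((y1 - y0) / s) + 1L
  if (as.numeric(outW) * outH > maxRasterPx)
    stop(sprintf(
      "rectified raster would be %d x %d px; lower target_px_per_cm or maxExtentCm",
      outW, outH))

  # inverse warp: output pixel -> canonical cm -> input image px
  Hci <- solve(Hic@H)
  gx <- rep(seq_len(outW) - 1, each = outH) * s + x0
  gy <- rep(seq_len(outH) - 1, times = outW) * s + y0
  Q <- Hci %*% rbind(gx, gy, 1)
  ix <- Q[1, ] / Q[3, ]; iy <- Q[2, ] / Q[3, ]
  valid <- is.finite(ix) & is.finite(iy) &
    ix >= 0 & ix <= w - 1 & iy >= 0 & iy <= h - 1 & Q[3, ] * Hci[3, 3] > 0
  fill <- .borderMedian(image)
  out <- array(0, c(outH, outW, 3))
  for (ch in 1:3) {
    v <- .bilinear(image[, , ch], ix, iy)
    v[!valid] <- fill[ch]
    out[, , ch] <- matrix(v, outH, outW)
  }
  patchRegion <- c((0 - x0) / s, (0 - y0) / s, (g - x0) / s, (g - y0) / s)
  Hic@scaleCmPerPx <- s
  new("RectifiedImage", image = out, scaleCmPerPx = s,
      patchRegion = patchRegion, offsetCm = c(x0, y0), homography = Hic)
}

setMethod("show", "RectifiedImage", function(object) {
  d <- dim(object@image)
  cat(sprintf("RectifiedImage: %d x %d px at %.4f cm/px\n",
              d[2], d[1], object@scaleCmPerPx))
  cat(sprintf("  patch region (px): [%.1f, %.1f] - [%.1f, %.1f]\n",
              object@patchRegion[1], object@patchRegion[2],
              object@patchRegion[3], object@patchRegion[4]))
})
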