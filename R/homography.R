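#' Estimate a planar homography from four point correspondences
#'
#' Solves the exactly-determined direct linear transform: the 3x3 projective
#' matrix H mapping \code{src} points to \code{dst} points, normalized so
#' \code{H[3,3] = 1}.  With exact inputs the reprojection residual is at the
#' level of floating-point round-off.
#'
#' @param src,dst 4 x 2 matrices of corresponding points (e.g. detected
#'   patch corners and canonical patch corners).
#' @return A [Homography-class].
#' @examples
#' sq <- rbind(c(0,0), c(1,0), c(1,1), c(0,1))
#' H <- estimateHomography(sq, sq * 2)
#' applyHomography(H, c(0.5, 0.5))   # (1, 1)
#' @export
estimateHomography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst) || ncol(src) != 2L || ncol(dst) != 2L)
    stop("src and dst must be n x 2 matrices of equal length")
  if (nrow(src) < 4L) stop("at least 4 correspondences required")
  if (nrow(src) == 4L &&
      (.hasCollinearTriple(src) || .hasCollinearTriple(dst)))
    stop("degenerate configuration: 3 collinear points")
  n <- nrow(src)
  A <- matrix(0, 2 * n, 8)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  h <- if (n == 4L) solve(A, b) else qr.solve(A, b)   # exact or least-squares
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  new("Homography", H = H)
}

.hasCollinearTriple <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(FALSE)
  cmb <- utils::combn(n, 3)
  scale2 <- max(stats::dist(p))^2
  for (k in seq_len(ncol(cmb))) {
    a <- p[cmb[1, k], ]; b <- p[cmb[2, k], ]; c <- p[cmb[3, k], ]
    cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(cross) < 1e-9 * scale2) return(TRUE)
  }
  FALSE
}

#' Apply a homography to points
#'
#' @param h a [Homography-class] or a plain 3 x 3 matrix.
#' @param pts n x 2 matrix (or length-2 vector) of points.
#' @return n x 2 matrix of mapped points.
#' @export
applyHomography <- function(h, pts) {
  H <- if (is(h, "Homography")) h@H else h
  if (is.null(dim(pts))) pts <- matrix(pts, 1)
  P <- H %*% rbind(t(pts), 1)
  t(P[1:2, , drop = FALSE] / rep(P[3, ], each = 2))
}

#' Invert a homography
#' @param h a [Homography-class].
#' @return The inverse map, renormalized so \code{H[3,3] = 1}.
#' @export
invertHomography <- function(h) {
  Hi <- solve(h@H)
  new("Homography", H = Hi / Hi[3, 3])
}

setMethod("show", "Homography", function(object) {
  cat("Homography (3 x 3, H[3,3] = 1)\n")
  print(round(object@H, 6))
  if (!is.na(object@scaleCmPerPx))
    cat(sprintf("  scale: %.5f cm/px\n", object@scaleCmPerPx))
})
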