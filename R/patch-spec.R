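#' Construct a PatchSpec
#'
#' @param referenceColors nCells x 3 numeric matrix of sRGB reference colors
#'   in [0,1], row-major physical order (top-left cell first).
#' @param cellSideCm physical side of one cell in cm.
#' @param gridRows,gridCols grid dimensions.
#' @return A [PatchSpec-class] object.
#' @examples
#' spec <- defaultPatchSpec()
#' grossSideCm(spec)   # 2.1
#' @export
patchSpec <- function(referenceColors, cellSideCm = 0.7,
                      gridRows = 3L, gridCols = 3L) {
  new("PatchSpec", gridRows = as.integer(gridRows),
      gridCols = as.integer(gridCols), cellSideCm = cellSideCm,
      referenceColors = as.matrix(referenceColors))
}

#' Default fiducial patch: nine well-separated sRGB colors
#'
#' The default 3x3 patch uses maximally separated primaries and neutrals
#' (white, red, green / blue, black, cyan / magenta, yellow, mid-gray,
#' row-major).  The arrangement has no rotational symmetry, so the patch
#' orientation in a photograph is always recoverable from the cell colors.
#' Cell side 0.7 cm, gross side 2.1 cm.
#'
#' @return A [PatchSpec-class].
#' @export
defaultPatchSpec <- function() {
  cols <- rbind(
    c(1, 1, 1), c(1, 0, 0), c(0, 1, 0),
    c(0, 0, 1), c(0, 0, 0), c(0, 1, 1),
    c(1, 0, 1), c(1, 1, 0), c(0.5, 0.5, 0.5)
  )
  rownames(cols) <- c("white", "red", "green", "blue", "black", "cyan",
                      "magenta", "yellow", "gray")
  patchSpec(cols)
}

#' Gross physical side length of a patch, in cm
#' @param spec a [PatchSpec-class].
#' @return \code{gridRows * cellSideCm} (the patch is square for the
#'   default 3x3 spec: 2.1 cm).
#' @export
grossSideCm <- function(spec) {
  stopifnot(is(spec, "PatchSpec"))
  spec@gridRows * spec@cellSideCm
}

#' Reference colors of a patch
#' @param spec a [PatchSpec-class].
#' @return nCells x 3 matrix, row-major physical order.
#' @export
referenceColors <- function(spec) {
  stopifnot(is(spec, "PatchSpec"))
  spec@referenceColors
}

# Canonical cm coordinates (x right, y down, origin = patch top-left corner)
# of the four outer corners, order TL, TR, BR, BL.
.canonicalCorners <- function(spec) {
  g <- grossSideCm(spec)
  rbind(c(0, 0), c(g, 0), c(g, g), c(0, g))
}

# Canonical cm coordinates of all cell centers, row-major.
.canonicalCellCenters <- function(spec) {
  s <- spec@cellSideCm
  centers <- expand.grid(col = seq_len(spec@gridCols) - 0.5,
                         row = seq_len(spec@gridRows) - 0.5)
  cbind(centers$col * s, centers$row * s)   # row-major: col varies fastest
}

setMethod("show", "PatchSpec", function(object) {
  cat(sprintf("PatchSpec: %d x %d grid, cell %.2f cm, gross %.2f cm\n",
              object@gridRows, object@gridCols, object@cellSideCm,
              grossSideCm(object)))
  cat(sprintf("  %d reference colors, min pairwise distance %.3f\n",
              nrow(object@referenceColors),
              {d <- as.matrix(stats::dist(object@referenceColors));
               diag(d) <- Inf; min(d)}))
})
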