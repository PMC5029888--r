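#' Read a photograph into a float RGB array
#'
#' Decodes PNG/JPEG/TIFF to an h x w x 3 array in [0,1] (16-bit inputs are
#' scaled by 1/65535 by the decoder).  Grayscale images are promoted to
#' RGB; an alpha channel is dropped.  For JPEGs the EXIF orientation tag is
#' honored.
#'
#' @param path image file path.
#' @return h x w x 3 numeric array, values in [0,1].
#' @export
readCapturedImage <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: %s", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop(sprintf("unreadable or unsupported image '%s': %s",
                                 path, conditionMessage(e))))
  a <- EBImage::imageData(img)            # EBImage stores [x, y, (ch)]
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3), c(dim(a)[1:2], 3L))
  out <- aperm(a, c(2, 1, 3))             # -> [y, x, ch]
  out[out < 0] <- 0; out[out > 1] <- 1
  orient <- if (grepl("\\.jpe?g$", path, ignore.case = TRUE))
    .jpegExifOrientation(path) else 1L
  .applyExifOrientation(out, orient)
}

# minimal EXIF reader: returns the orientation tag (1 when absent/unknown)
.jpegExifOrientation <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = 128 * 1024)
  if (length(bytes) < 4 || bytes[1] != as.raw(0xFF) || bytes[2] != as.raw(0xD8))
    return(1L)
  i <- 3L
  while (i + 4 <= length(bytes)) {
    if (bytes[i] != as.raw(0xFF)) return(1L)
    marker <- as.integer(bytes[i + 1])
    segLen <- as.integer(bytes[i + 2]) * 256L + as.integer(bytes[i + 3])
    if (marker == 0xE1) {                 # APP1
      seg <- bytes[(i + 4):min(length(bytes), i + 1 + segLen)]
      if (length(seg) > 14 && rawToChar(seg[1:4]) == "Exif")
        return(.parseTiffOrientation(seg[-(1:6)]))
      return(1L)
    }
    if (marker == 0xDA) return(1L)        # start of scan; no EXIF
    i <- i + 2L + segLen
  }
  1L
}

.parseTiffOrientation <- function(tiff) {
  if (length(tiff) < 14) return(1L)
  le <- rawToChar(tiff[1:2]) == "II"
  u16 <- function(off) {
    b <- as.integer(tiff[off + (1:2)])
    if (le) b[1] + 256L * b[2] else b[2] + 256L * b[1]
  }
  u32 <- function(off) {
    b <- as.integer(tiff[off + (1:4)])
    if (le) sum(b * 256^(0:3)) else sum(b * 256^(3:0))
  }
  ifd <- u32(4)
  if (ifd + 2 > length(tiff)) return(1L)
  n <- u16(ifd)
  for (k in seq_len(n)) {
    off <- ifd + 2 + (k - 1) * 12
    if (off + 12 > length(tiff)) return(1L)
    if (u16(off) == 0x0112) {
      v <- u16(off + 8)
      if (v >= 1 && v <= 8) return(as.integer(v))
      return(1L)
    }
  }
  1L
}

.applyExifOrientation <- function(img, orient) {
  flipH <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
  flipV <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  rot90cw <- function(a) aperm(flipV(a), c(2, 1, 3))
  switch(orient,
         img,                       # 1: upright
         flipH(img),                # 2
         flipV(flipH(img)),         # 3: 180
         flipV(img),                # 4
         aperm(img, c(2, 1, 3)),    # 5: transpose
         rot90cw(img),              # 6: 90 CW
         flipH(aperm(img, c(2, 1, 3))),  # 7
         flipH(rot90cw(flipH(img))) # 8: 90 CCW
  )
}

#' Write a synthetic render (or any RGB array) as PNG
#' @param image h x w x 3 array or [RenderedScene-class].
#' @param path output PNG path.
#' @export
writeImagePNG <- function(image, path) {
  if (is(image, "RenderedScene")) image <- image@image
  EBImage::writeImage(EBImage::Image(aperm(image, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write a measurement or summary report
#'
#' Measurements are written as JSON (fields: area_cm2, lw_area_cm2,
#' scale_cm_per_px, homography, color_residual, stages, seed; floats at 4
#' decimals, deterministic field order).  Healing summaries (a list of
#' [HealingSummary-class] or a [WoundMeasurement-class]) can be written as
#' CSV.
#'
#' @param x a [WoundMeasurement-class] or list of [HealingSummary-class].
#' @param path output file.
#' @param format "json" or "csv".
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (is(x, "WoundMeasurement")) {
    if (format != "json") stop("measurements are reported as JSON")
    r4 <- function(v) if (is.numeric(v)) round(v, 4) else v
    H <- x@stageReport$homography
    rep <- list(
      area_cm2 = r4(x@areaCm2),
      lw_area_cm2 = r4(x@lwAreaCm2),
      scale_cm_per_px = r4(x@scaleCmPerPx),
      homography = if (!is.null(H)) r4(H) else NULL,
      color_residual = r4(x@stageReport$normalize$fit_residual_rms),
      stages = lapply(x@stageReport[intersect(names(x@stageReport),
        c("detect", "rectify", "normalize", "segment", "measure", "error"))],
        function(s) lapply(s, r4)),
      seed = x@stageReport$seed,
      capture = x@capture)
    jsonlite::write_json(rep[!vapply(rep, is.null, logical(1))], path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    df <- summaryTable(x)
    if (format == "json")
      jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                           pretty = TRUE)
    else utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Tabulate healing summaries
#' @param summaries list of [HealingSummary-class].
#' @return data.frame with columns patient_id, site_class,
#'   initial_area_cm2, final_area_cm2, decrease_rate_pct,
#'   half_decrement_day, n_obs, follow_up_days (floats at 4 decimals).
#' @export
summaryTable <- function(summaries) {
  if (is(summaries, "HealingSummary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) data.frame(
    patient_id = s@patientId, site_class = s@siteClass,
    initial_area_cm2 = round(s@initialAreaCm2, 4),
    final_area_cm2 = round(s@finalAreaCm2, 4),
    decrease_rate_pct = round(s@decreaseRatePct, 4),
    half_decrement_day = round(s@halfDecrementDay, 4),
    n_obs = s@nObservations, follow_up_days = s@followUpDays)))
}

#' Process a longitudinal manifest
#'
#' The manifest CSV needs columns patient_id, site_class, day, and either
#' area_cm2 (precomputed areas) or image_path (areas measured via
#' [measureImage()]).
#'
#' @param manifest path to the manifest CSV, or a data.frame.
#' @param patch [PatchSpec-class] used when measuring images.
#' @param config pipeline configuration.
#' @param halfMode "interp" or "nearest", see [halfDecrementDay()].
#' @param seed master seed for image measurement.
#' @return list of [HealingSummary-class], one per patient.
#' @export
processManifest <- function(manifest, patch = defaultPatchSpec(),
                            config = defaultRunConfig(),
                            halfMode = "interp", seed = 1L) {
  df <- if (is.character(manifest))
    utils::read.csv(manifest, stringsAsFactors = FALSE) else manifest
  need <- c("patient_id", "site_class", "day")
  if (!all(need %in% names(df)))
    stop("manifest must have columns patient_id, site_class, day and area_cm2 or image_path")
  if (!"area_cm2" %in% names(df)) {
    if (!"image_path" %in% names(df))
      stop("manifest needs an area_cm2 or image_path column")
    df$area_cm2 <- vapply(seq_len(nrow(df)), function(i)
      measureImage(df$image_path[i], patch = patch, config = config,
                   seed = seed, onError = "stop")@areaCm2, numeric(1))
  }
  lapply(split(df, df$patient_id), function(p) {
    p <- p[order(p$day), ]
    summarizeSeries(
      woundSeries(p$patient_id[1], p$day, p$area_cm2, p$site_class[1]),
      halfMode = halfMode)
  })
}
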