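#' Construct a B-scan-like image from a matrix
#'
#' @param pixels numeric matrix of intensities (rows x columns).
#' @param provenance free-text origin tag, default "synthetic".
#' @return a [BScanImage-class] object.
#' @export
bScanImage <- function(pixels, provenance = "synthetic") {
  new("BScanImage", pixels = pixels, provenance = as.character(provenance))
}

#' Read a grayscale PNG or TIFF as a B-scan image
#'
#' Multi-channel images are averaged to grayscale. Intensities are kept on
#' the [0, 1] scale the readers return.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return a [BScanImage-class] object.
#' @export
readBScan <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  bScanImage(arr, provenance = path)
}

#' Write a B-scan image to PNG or TIFF
#'
#' Intensities are rescaled to [0, 1] for the writer.
#'
#' @param image a [BScanImage-class] object.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
writeBScan <- function(image, path) {
  stopifnot(is(image, "BScanImage"))
  px <- image@pixels
  rng <- range(px)
  px <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Extract an RPE trace from a bright-band image
#'
#' For each image column the band row is estimated as the
#' intensity-weighted centroid of the rows inside a window around that
#' column's brightest pixel; the per-column estimates are then median
#' smoothed. This automates, for synthetic images, what is done manually
#' on clinical B-scans, so the pipeline is testable end to end.
#'
#' Columns that are entirely zero are omitted; if more than 10% of the
#' columns are omitted the extraction fails.
#'
#' @param image a [BScanImage-class] object with one dominant bright band
#'   per column.
#' @param smoothingHalfwidth halfwidth (columns) of the running-median
#'   smoother; 0 disables smoothing.
#' @param windowHalfwidth halfwidth (rows) of the centroid window around
#'   the per-column argmax.
#' @param eyeId identifier for the returned trace.
#' @return an [RPETrace-class] object with one point per retained column.
#' @export
extractRPE <- function(image, smoothingHalfwidth = 2L,
                       windowHalfwidth = 8L, eyeId = "extracted") {
  stopifnot(is(image, "BScanImage"))
  px <- image@pixels
  nr <- nrow(px); nc <- ncol(px)
  ys <- rep(NA_real_, nc)
  rows <- seq_len(nr)
  for (j in seq_len(nc)) {
    col <- px[, j]
    if (all(col <= 0)) next
    peak <- which.max(col)
    win <- max(1L, peak - windowHalfwidth):min(nr, peak + windowHalfwidth)
    w <- col[win]
    ys[j] <- sum((rows[win] - 1) * w) / sum(w)  # 0-based row coordinate
  }
  keep <- !is.na(ys)
  if (sum(!keep) > 0.10 * nc)
    stop(sprintf("extraction failed: %d of %d columns are empty",
                 sum(!keep), nc))
  y <- ys[keep]
  if (smoothingHalfwidth > 0) {
    k <- 2L * as.integer(smoothingHalfwidth) + 1L
    if (k < length(y)) y <- stats::runmed(y, k, endrule = "median")
  }
  rpeTrace(x = (which(keep) - 1), y = as.numeric(y), scanWidth = nc,
           eyeId = eyeId)
}
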