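#' RPETrace: the plotted course of the RPE along an unrolled circle scan
#'
#' Ordered pixel coordinates of the retinal pigment epithelium (RPE) along
#' one circumpapillary OCT B-scan. `x` is the column index along the
#' unrolled 3.4 mm scan circle (both scan ends are nasal, the centre
#' temporal); `y` is the image row, increasing downward as in standard
#' raster coordinates.
#'
#' Validity requires strictly increasing `x` within `[0, scanWidth)` and
#' finite non-negative `y`. A minimum of 8 points is required only at fit
#' time, not here, so sparse manually plotted traces remain loadable.
#'
#' @slot x numeric, strictly increasing column positions (pixels).
#' @slot y numeric, row positions (pixels, larger = lower in the image).
#' @slot scanWidth single numeric, total columns of the source B-scan.
#' @slot eyeId single character identifier.
#' @export
setClass("RPETrace",
  representation(x = "numeric", y = "numeric", scanWidth = "numeric",
                 eyeId = "character"))

setValidity("RPETrace", function(object) {
  msg <- character()
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have equal length")
  if (length(object@x) < 1L)
    msg <- c(msg, "trace must contain at least one point")
  if (length(object@scanWidth) != 1L || !is.finite(object@scanWidth) ||
      object@scanWidth <= 0)
    msg <- c(msg, "scanWidth must be a single positive number")
  if (anyNA(object@x) || any(!is.finite(object@x)))
    msg <- c(msg, "x must be finite")
  if (length(object@x) > 1L && any(diff(object@x) <= 0)) {
    dup <- object@x[which(diff(object@x) <= 0)[1] + 1L]
    msg <- c(msg, sprintf(
      "x must be strictly increasing (offending value: x = %g)", dup))
  }
  if (length(object@x) && (min(object@x) < 0 ||
                           max(object@x) >= object@scanWidth))
    msg <- c(msg, "x must lie in [0, scanWidth)")
  if (anyNA(object@y) || any(!is.finite(object@y)) || any(object@y < 0))
    msg <- c(msg, "y must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' CenteredTrace: an RPE trace with the wave centre at the origin
#'
#' The coordinate conversion applied before sine fitting: `u` is `x` minus
#' the x-midpoint `(min(x)+max(x))/2`, and `v` is `y` minus `mean(y)`.
#' Mean-centering `v` stands in for the missing intercept term of the sine
#' model, so fitting accepts only this class.
#'
#' @slot u numeric, centred column positions (pixels).
#' @slot v numeric, mean-centred row positions (pixels).
#' @slot scanWidth single numeric, carried from the source trace.
#' @slot eyeId single character identifier.
#' @export
setClass("CenteredTrace",
  representation(u = "numeric", v = "numeric", scanWidth = "numeric",
                 eyeId = "character"))

setValidity("CenteredTrace", function(object) {
  msg <- character()
  if (length(object@u) != length(object@v))
    msg <- c(msg, "u and v must have equal length")
  if (length(object@scanWidth) != 1L || object@scanWidth <= 0)
    msg <- c(msg, "scanWidth must be a single positive number")
  if (length(object@v) &&
      abs(mean(object@v)) > 1e-6 * max(1, max(abs(object@v))))
    msg <- c(msg, "v must be mean-centred")
  if (length(msg)) msg else TRUE
})

#' BScanImage: a grayscale B-scan-like intensity grid
#'
#' A rectangular grayscale image (rows x columns) holding a bright RPE-like
#' band, either rendered synthetically or read from a PNG/TIFF file. This
#' is pipeline plumbing: real vendor OCT exports are out of scope.
#'
#' @slot pixels numeric matrix of finite intensities.
#' @slot provenance single character ("synthetic" or a file path).
#' @export
setClass("BScanImage",
  representation(pixels = "matrix", provenance = "character"))

setValidity("BScanImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels) || any(!is.finite(object@pixels)))
    msg <- c(msg, "pixels must be a finite numeric matrix")
  if (nrow(object@pixels) < 2L || ncol(object@pixels) < 2L)
    msg <- c(msg, "image must have at least 2 rows and 2 columns")
  if (length(msg)) msg else TRUE
})

#' SineFit: least-squares fit of y = a * sin(b*x - c)
#'
#' The result of fitting the three-parameter sine model to a centred RPE
#' trace. The amplitude `a` (pixels) is the optic disc tilt metric; `b`
#' (radians/pixel) is the angular frequency, near one period per scan
#' circumference; `c` (radians) is the phase. After normalisation `a >= 0`
#' and `c` lies in `[0, 2*pi)`. `qualityPass` records the fit-quality gate
#' R^2 > 0.90.
#'
#' @slot a,b,c fitted constants.
#' @slot rSquared coefficient of determination, 1 - RSS/TSS.
#' @slot rss residual sum of squares (pixels^2).
#' @slot nPoints number of points used.
#' @slot converged logical, FALSE when the iteration limit was hit.
#' @slot qualityPass logical, R^2 strictly above 0.90.
#' @slot eyeId single character identifier.
#' @export
setClass("SineFit",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 rSquared = "numeric", rss = "numeric", nPoints = "integer",
                 converged = "logical", qualityPass = "logical",
                 eyeId = "character"))

setValidity("SineFit", function(object) {
  msg <- character()
  if (object@a < 0) msg <- c(msg, "a must be non-negative after normalisation")
  if (object@c < 0 || object@c >= 2 * pi)
    msg <- c(msg, "c must lie in [0, 2*pi)")
  if (object@rss < 0) msg <- c(msg, "rss must be non-negative")
  if (object@rSquared > 1 + 1e-12) msg <- c(msg, "rSquared must be <= 1")
  if (length(msg)) msg else TRUE
})

#' DiscOutline: optic disc margin points on a fundus photograph
#'
#' An ordered polygon of at least 8 margin points in fundus-photo pixel
#' coordinates (y down, x right, right eye). Used to compute the maximum
#' and minimum disc diameters and the ovality ratio.
#'
#' @slot points numeric matrix, n x 2, columns x and y, ordered around the
#'   margin.
#' @slot eyeId single character identifier.
#' @export
setClass("DiscOutline",
  representation(points = "matrix", eyeId = "character"))

setValidity("DiscOutline", function(object) {
  msg <- character()
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L)
    msg <- c(msg, "points must be a numeric n x 2 matrix")
  else {
    if (nrow(p) < 8L) msg <- c(msg, "outline needs at least 8 points")
    if (any(!is.finite(p))) msg <- c(msg, "points must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' RatingMatrix: repeated amplitude measurements for reliability analysis
#'
#' An n-subjects by k-raters matrix of measurements with no missing cells
#' (listwise deletion is applied upstream). Input to the intraclass
#' correlation.
#'
#' @slot values numeric matrix, subjects in rows, raters in columns.
#' @slot subjectIds character vector of row identifiers.
#' @slot raterIds character vector of column identifiers.
#' @export
setClass("RatingMatrix",
  representation(values = "matrix", subjectIds = "character",
                 raterIds = "character"))

setValidity("RatingMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (nrow(v) < 2L || ncol(v) < 2L)
    msg <- c(msg, "need at least 2 subjects and 2 raters")
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "values must be complete and finite")
  if (length(object@subjectIds) != nrow(v))
    msg <- c(msg, "subjectIds must match rows")
  if (length(object@raterIds) != ncol(v))
    msg <- c(msg, "raterIds must match columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RPETrace", function(object) {
  cat(sprintf("RPETrace '%s': %d points, scanWidth = %g px, y in [%g, %g]\n",
              object@eyeId, length(object@x), object@scanWidth,
              min(object@y), max(object@y)))
})

setMethod("show", "CenteredTrace", function(object) {
  cat(sprintf(
    "CenteredTrace '%s': %d points, u in [%g, %g], max |v| = %g px\n",
    object@eyeId, length(object@u), min(object@u), max(object@u),
    max(abs(object@v))))
})

setMethod("show", "BScanImage", function(object) {
  cat(sprintf("BScanImage (%s): %d rows x %d columns, intensity [%g, %g]\n",
              object@provenance, nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "SineFit", function(object) {
  cat(sprintf("SineFit '%s': y = %.3f * sin(%.6g * x - %.4f)\n",
              object@eyeId, object@a, object@b, object@c))
  cat(sprintf("  R^2 = %.4f (%s), RSS = %.4g, n = %d, converged = %s\n",
              object@rSquared,
              if (object@qualityPass) "quality pass" else "below 0.90 gate",
              object@rss, object@nPoints, object@converged))
})

setMethod("show", "DiscOutline", function(object) {
  cat(sprintf("DiscOutline '%s': %d margin points\n",
              object@eyeId, nrow(object@points)))
})

setMethod("show", "RatingMatrix", function(object) {
  cat(sprintf("RatingMatrix: %d subjects x %d raters\n",
              nrow(object@values), ncol(object@values)))
})
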