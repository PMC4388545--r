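#' Construct a disc outline from margin points
#'
#' @param x,y numeric margin coordinates in fundus-photo pixels (y down,
#'   x right, right eye), ordered around the margin; alternatively pass a
#'   two-column matrix as `x`.
#' @param eyeId identifier.
#' @return a [DiscOutline-class] object.
#' @export
discOutline <- function(x, y = NULL, eyeId = "eye") {
  pts <- if (is.null(y)) as.matrix(x) else cbind(x, y)
  colnames(pts) <- c("x", "y")
  new("DiscOutline", points = pts, eyeId = as.character(eyeId))
}

#' Read a disc outline from a two-column CSV of margin points
#'
#' @param path CSV path, columns x,y, optional header.
#' @param eyeId identifier; defaults to the file name.
#' @return a [DiscOutline-class] object.
#' @export
loadOutline <- function(path, eyeId = sub("\\.[^.]*$", "", basename(path))) {
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.]", first)
  df <- utils::read.csv(path, header = has_header)
  discOutline(df[[1]], df[[2]], eyeId = eyeId)
}

#' Maximum and minimum disc diameters and the long-axis angle
#'
#' `dMax` is the largest point-pair distance over the outline (the
#' caliper diameter). `dMin` is, by default, the minimum width: the
#' smallest distance between parallel supporting lines over all
#' directions. `minMode = "perpendicular"` instead measures the extent of
#' the outline along the direction perpendicular to the `dMax` chord,
#' for compatibility with caliper-on-photograph protocols that measure
#' the short diameter at right angles to the long one.
#'
#' `axisAngle` is the acute angle between the `dMax` chord and the
#' vertical axis, in degrees in `[0, 90]`. In displayed fundus-photo
#' coordinates of a right eye (y down) this matches a clockwise reading
#' from vertical.
#'
#' @param outline a [DiscOutline-class] object.
#' @param minMode `"width"` (parallel supporting lines, default) or
#'   `"perpendicular"`.
#' @param nDirections angular resolution for the width scan.
#' @return list with `dMax`, `dMin`, `axisAngle` (degrees).
#' @export
principalDiameters <- function(outline, minMode = c("width", "perpendicular"),
                               nDirections = 720L) {
  stopifnot(is(outline, "DiscOutline"))
  minMode <- match.arg(minMode)
  p <- outline@points
  # collinearity check via the second singular value
  ctr <- scale(p, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate outline: points are collinear")
  d2 <- as.matrix(stats::dist(p))
  idx <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  dMax <- d2[idx[1], idx[2]]
  chord <- p[idx[2], ] - p[idx[1], ]
  axisAngle <- atan2(abs(chord[1]), abs(chord[2])) * 180 / pi
  if (minMode == "width") {
    theta <- seq(0, pi, length.out = nDirections + 1L)[-(nDirections + 1L)]
    proj <- p %*% rbind(cos(theta), sin(theta))
    widths <- apply(proj, 2, function(z) diff(range(z)))
    dMin <- min(widths)
  } else {
    perp <- c(-chord[2], chord[1]) / sqrt(sum(chord^2))
    proj <- as.numeric(p %*% perp)
    dMin <- diff(range(proj))
  }
  list(dMax = unname(dMax), dMin = unname(dMin),
       axisAngle = unname(axisAngle))
}

#' Classify the disc long axis as vertical or horizontal
#'
#' A disc is vertically long when the axis of its longest diameter lies
#' less than 45 degrees (clockwise) from vertical, horizontally long when
#' more than 45 degrees. Exactly 45 degrees is classified vertical, which
#' keeps the original shortest/longest ratio as the default behaviour.
#'
#' @param pair list from [principalDiameters()] (or anything with an
#'   `axisAngle` element in degrees).
#' @return `"vertical"` or `"horizontal"`.
#' @export
classifyAxis <- function(pair) {
  ang <- pair$axisAngle
  stopifnot(is.finite(ang), ang >= 0, ang <= 90)
  if (ang <= 45) "vertical" else "horizontal"
}

#' Modified ovality ratio of the optic disc
#'
#' For a vertically long disc the ratio is minimum/maximum diameter (the
#' classical definition, always <= 1); for a horizontally long disc it is
#' maximum/minimum (>= 1). The modification keeps horizontally elongated
#' discs — where axial elongation acts along the horizontal — from being
#' folded into the same side of 1.0 as vertical ones.
#'
#' @param pair list from [principalDiameters()].
#' @return list with `ratio` and `axisClass`.
#' @export
ovalityRatio <- function(pair) {
  stopifnot(pair$dMax >= pair$dMin)
  if (pair$dMin <= 0) stop("minimum diameter must be positive")
  cls <- classifyAxis(pair)
  ratio <- if (cls == "vertical") pair$dMin / pair$dMax
           else pair$dMax / pair$dMin
  list(ratio = ratio, axisClass = cls)
}

#' Full ovality analysis of one outline
#'
#' @param outline a [DiscOutline-class] object.
#' @param ... passed to [principalDiameters()].
#' @return one-row data frame: eye_id, d_max, d_min, axis_angle,
#'   axis_class, ratio.
#' @export
analyzeOutline <- function(outline, ...) {
  pair <- principalDiameters(outline, ...)
  ov <- ovalityRatio(pair)
  data.frame(eye_id = outline@eyeId, d_max = pair$dMax, d_min = pair$dMin,
             axis_angle = pair$axisAngle, axis_class = ov$axisClass,
             ratio = ov$ratio, stringsAsFactors = FALSE)
}
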