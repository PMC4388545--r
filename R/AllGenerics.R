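#' Amplitude of a fitted sine wave
#'
#' Returns the fitted constant `a`, the amplitude of the sine curve in
#' pixels. The amplitude reflects the degree of optic disc tilt against
#' the optical axis: flatter RPE courses give smaller amplitudes.
#'
#' @param fit a [SineFit-class] object.
#' @return single numeric amplitude in pixels (>= 0).
#' @export
setGeneric("amplitude", function(fit) standardGeneric("amplitude"))

#' Phase direction of the RPE wave minimum
#'
#' Maps the fitted phase to the scan angle of the lowest point of the RPE
#' wave, with angle 0 at the scan start (nasal) and increasing along the
#' scan. The sine minimum sits where `b*u - c = 3*pi/2`, so the minimising
#' position is `u = (c + 3*pi/2)/b`, converted to an angle via
#' `2*pi/scanWidth` and reduced mod `2*pi`.
#'
#' @param fit a [SineFit-class] object with `a > 0`.
#' @param scanWidth scan width in pixels used for the angle conversion.
#' @return angle in radians in `[0, 2*pi)`.
#' @export
setGeneric("tiltDirection",
           function(fit, scanWidth) standardGeneric("tiltDirection"))

#' Goodness of fit and the R^2 > 0.90 quality gate
#'
#' @param fit a [SineFit-class] object.
#' @return list with elements `rSquared` and `qualityPass`
#'   (`rSquared > 0.90`, strict).
#' @export
setGeneric("goodness", function(fit) standardGeneric("goodness"))

#' Centre trace coordinates at the wave origin
#'
#' Converts raw pixel coordinates to the centred system used for sine
#' fitting: `u = x - (min(x)+max(x))/2`, `v = y - mean(y)`.
#'
#' @param trace an [RPETrace-class] object.
#' @return a [CenteredTrace-class] object.
#' @export
setGeneric("centerCoordinates",
           function(trace) standardGeneric("centerCoordinates"))
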