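#' Options controlling the sine fit
#'
#' The model is \eqn{v = a \sin(b u - c)}. With `bMode = "fixed_period"`
#' the angular frequency is held at \eqn{b_0 = 2\pi/\mathrm{scanWidth}}
#' (exactly one period per scan circumference, the anatomical expectation:
#' both scan ends are nasal, the centre temporal) and the model is linear
#' in `(a, c)`. With `bMode = "free"` (the default) `b` is refined jointly
#' with `(a, c)` by damped least squares inside multiplicative bounds
#' around \eqn{b_0}; the bounds keep the fit from locking onto noise
#' harmonics on sparse traces.
#'
#' @param bMode `"free"` or `"fixed_period"`.
#' @param bBounds length-2 multiplicative bounds on `b` around
#'   `2*pi/scanWidth`.
#' @param maxIterations iteration cap for the damped refinement.
#' @param convergenceTolerance relative parameter-change threshold.
#' @param initialPhaseGridSize number of phase grid points available to
#'   grid-based helpers (>= 4); the default initialisation is the exact
#'   linear solve at \eqn{b_0}, which needs no grid.
#' @return a list of validated options.
#' @export
fitOptions <- function(bMode = c("free", "fixed_period"),
                       bBounds = c(0.5, 2),
                       maxIterations = 200L,
                       convergenceTolerance = 1e-10,
                       initialPhaseGridSize = 16L) {
  bMode <- match.arg(bMode)
  stopifnot(length(bBounds) == 2L, all(bBounds > 0),
            bBounds[1] <= bBounds[2], initialPhaseGridSize >= 4L)
  list(bMode = bMode, bBounds = as.numeric(bBounds),
       maxIterations = as.integer(maxIterations),
       convergenceTolerance = convergenceTolerance,
       initialPhaseGridSize = as.integer(initialPhaseGridSize))
}

# Exact conditional least squares for fixed b: v = A sin(bu) + B cos(bu),
# a = sqrt(A^2+B^2), c = atan2(-B, A).
.sineLinearSolve <- function(u, v, b) {
  S <- sin(b * u); C <- cos(b * u)
  X <- cbind(S, C)
  coef <- tryCatch(solve(crossprod(X), crossprod(X, v)),
                   error = function(e) qr.coef(qr(X), v))
  A <- coef[1]; B <- coef[2]
  list(a = sqrt(A^2 + B^2), c = atan2(-B, A), A = A, B = B)
}

.normalizeAC <- function(a, cc) {
  if (a < 0) { a <- -a; cc <- cc + pi }
  cc <- cc %% (2 * pi)
  list(a = a, c = cc)
}

#' Fit the sine model to a centred RPE trace
#'
#' Minimises \eqn{\sum_i (v_i - a \sin(b u_i - c))^2}. Initialisation is
#' deterministic: `(a, c)` come from the exact linear solve of
#' \eqn{v = A\sin(b_0 u) + B\cos(b_0 u)} at \eqn{b_0 = 2\pi/\mathrm{scanWidth}};
#' when `bMode = "free"` all three parameters are then refined by a
#' Levenberg-Marquardt style damped Gauss-Newton iteration with `b`
#' clamped to its bounds. The fitted sign/phase are normalised so that
#' `a >= 0` and `c` lies in `[0, 2*pi)`.
#'
#' A trace with zero total sum of squares (all `v` identical) is flat:
#' the fit short-circuits to `a = 0` with `rSquared` defined as 1 and the
#' quality flag set, without iterating. Such rectilinear RPE courses
#' correspond to untilted discs, for which a near-zero amplitude is the
#' correct report.
#'
#' @param trace a [CenteredTrace-class] with at least 8 points.
#' @param options a list from [fitOptions()].
#' @return a [SineFit-class] object. If the damped refinement does not
#'   converge within the iteration cap, the best parameters so far are
#'   returned with `converged = FALSE`.
#' @examples
#' u <- (0:1023) - 511.5
#' v <- 20 * sin(2 * pi * u / 1024 - 1)
#' ct <- new("CenteredTrace", u = u, v = v - mean(v), scanWidth = 1024,
#'           eyeId = "demo")
#' fitSine(ct)
#' @export
fitSine <- function(trace, options = fitOptions()) {
  stopifnot(is(trace, "CenteredTrace"))
  u <- trace@u; v <- trace@v
  n <- length(u)
  if (n < 8L) stop("sine fit needs at least 8 points, got ", n)
  tss <- sum((v - mean(v))^2)
  b0 <- 2 * pi / trace@scanWidth
  if (tss == 0) {
    return(new("SineFit", a = 0, b = b0, c = 0, rSquared = 1, rss = 0,
               nPoints = n, converged = TRUE, qualityPass = TRUE,
               eyeId = trace@eyeId))
  }
  lin <- .sineLinearSolve(u, v, b0)
  a <- lin$a; b <- b0; cc <- lin$c
  converged <- TRUE
  if (options$bMode == "free") {
    lo <- options$bBounds[1] * b0; hi <- options$bBounds[2] * b0
    lambda <- 1e-3
    rss <- sum((v - a * sin(b * u - cc))^2)
    converged <- FALSE
    for (it in seq_len(options$maxIterations)) {
      phase <- b * u - cc
      s <- sin(phase); co <- cos(phase)
      r <- v - a * s
      # Jacobian of the residuals
      J <- cbind(-s, -a * u * co, a * co)
      g <- crossprod(J, r)
      H <- crossprod(J)
      step <- tryCatch(
        solve(H + lambda * diag(diag(H), 3), -g),
        error = function(e) rep(0, 3))
      cand <- c(a, b, cc) + as.numeric(step)
      cand[2] <- min(max(cand[2], lo), hi)
      newRss <- sum((v - cand[1] * sin(cand[2] * u - cand[3]))^2)
      if (newRss <= rss) {
        relChange <- max(abs(c(a, b, cc) - cand) /
                           pmax(abs(c(a, b, cc)), 1e-12))
        a <- cand[1]; b <- cand[2]; cc <- cand[3]
        rss <- newRss
        lambda <- max(lambda / 10, 1e-12)
        if (relChange < options$convergenceTolerance) {
          converged <- TRUE
          break
        }
      } else {
        lambda <- lambda * 10
        if (lambda > 1e12) { converged <- TRUE; break }  # stationary
      }
    }
    # exact conditional (a, c) at the final b
    lin <- .sineLinearSolve(u, v, b)
    a <- lin$a; cc <- lin$c
  }
  norm <- .normalizeAC(a, cc)
  rss <- sum((v - norm$a * sin(b * u - norm$c))^2)
  r2 <- 1 - rss / tss
  new("SineFit", a = norm$a, b = b, c = norm$c, rSquared = r2, rss = rss,
      nPoints = n, converged = converged, qualityPass = r2 > 0.90,
      eyeId = trace@eyeId)
}

#' @rdname amplitude
#' @export
setMethod("amplitude", "SineFit", function(fit) fit@a)

#' @rdname tiltDirection
#' @export
setMethod("tiltDirection", "SineFit", function(fit, scanWidth) {
  if (missing(scanWidth)) scanWidth <- 2 * pi / fit@b
  if (fit@a <= 0)
    stop("tilt direction is undefined for a flat fit (a = 0)")
  uMin <- (fit@c + 3 * pi / 2) / fit@b
  (uMin * 2 * pi / scanWidth) %% (2 * pi)
})

#' @rdname goodness
#' @export
setMethod("goodness", "SineFit", function(fit) {
  list(rSquared = fit@rSquared, qualityPass = fit@rSquared > 0.90)
})

#' Serialise a sine fit to a one-row data frame
#'
#' @param fit a [SineFit-class] object.
#' @return data frame with columns eye_id, a, b, c, r_squared,
#'   quality_pass, converged, n_points.
#' @export
fitAsRow <- function(fit) {
  data.frame(eye_id = fit@eyeId, a = fit@a, b = fit@b, c = fit@c,
             r_squared = fit@rSquared, quality_pass = fit@qualityPass,
             converged = fit@converged, n_points = fit@nPoints,
             stringsAsFactors = FALSE)
}
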