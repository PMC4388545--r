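#' Simulate an RPE trace
#'
#' Draws `y = y0 + aTrue*sin(bTrue*x - cTrue) + drift + noise` on an
#' integer x grid (or a sparse subsample of it, mirroring manual
#' plotting). The drift term is an optional centred quadratic modelling
#' non-sinusoidal departures seen in nearly flat RPE courses; default 0.
#' Deterministic given `seed`; no global random state is touched.
#'
#' @param aTrue amplitude in pixels.
#' @param bTrue angular frequency; default one period per scan width.
#' @param cTrue phase in radians.
#' @param noiseSd Gaussian plotting noise SD in pixels.
#' @param driftAmplitude peak height of the quadratic drift in pixels.
#' @param nPoints points per trace (>= 8); spread evenly over the scan.
#' @param scanWidth scan width in pixels (1024 A-scans per circle by
#'   default, the circle-scan protocol sampling).
#' @param y0 baseline row; defaults high enough to keep y non-negative.
#' @param seed integer seed.
#' @param eyeId identifier.
#' @return an [RPETrace-class] object.
#' @export
simulateTrace <- function(aTrue = 37, bTrue = 2 * pi / scanWidth,
                          cTrue = 1, noiseSd = 0, driftAmplitude = 0,
                          nPoints = 64L, scanWidth = 1024L,
                          y0 = NULL, seed = 1L, eyeId = "sim") {
  stopifnot(noiseSd >= 0, nPoints >= 8L)
  # uniform grid covering exactly one scan circumference, so the sine
  # term has zero mean and mean-centering leaves it untouched
  x <- (0:(nPoints - 1)) * (scanWidth / nPoints)
  if (is.null(y0)) y0 <- abs(aTrue) + driftAmplitude + 6 * noiseSd + 100
  xm <- (min(x) + max(x)) / 2
  drift <- if (driftAmplitude != 0)
    driftAmplitude * (((x - xm) / (scanWidth / 2))^2 - 1 / 3) else 0
  noise <- if (noiseSd > 0) {
    rng <- .localRNG(seed)
    rng$rnorm(length(x), 0, noiseSd)
  } else 0
  y <- y0 + aTrue * sin(bTrue * x - cTrue) + drift + noise
  rpeTrace(x, pmax(y, 0), scanWidth = scanWidth, eyeId = eyeId)
}

# Seeded RNG confined to a private environment: generators are pure
# functions of (spec, seed) and leave the caller's RNG state untouched.
.localRNG <- function(seed) {
  env <- new.env()
  old0 <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old0)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old0, globalenv())
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    fn(...)
  }
  list(
    rnorm = function(...) draw(stats::rnorm, ...),
    mvrnorm = function(...) draw(MASS::mvrnorm, ...)
  )
}

#' Render a synthetic B-scan image around a trace
#'
#' Draws a Gaussian-profile bright band centred on the trace in each
#' column, plus optional background noise. The image uses the same
#' 0-based row coordinates as [extractRPE()], so render-then-extract
#' round-trips.
#'
#' @param trace an [RPETrace-class]; its y values must fit within
#'   `nRows`.
#' @param nRows image height in pixels.
#' @param bandSigma Gaussian band width (rows).
#' @param peak band peak intensity.
#' @param noiseSd background noise SD (intensity units).
#' @param seed integer seed for the noise field.
#' @return a [BScanImage-class] of size `nRows` x `scanWidth`; between
#'   trace points the band centre is linearly interpolated (constant
#'   beyond the ends), so every column carries the band.
#' @export
renderBScan <- function(trace, nRows = NULL, bandSigma = 3, peak = 1,
                        noiseSd = 0, seed = 1L) {
  stopifnot(is(trace, "RPETrace"), bandSigma > 0)
  if (is.null(nRows)) nRows <- ceiling(max(trace@y) + 6 * bandSigma + 1)
  if (any(trace@y < 0) || any(trace@y > nRows - 1))
    stop("trace lies outside the image rows")
  nc <- as.integer(trace@scanWidth)
  px <- matrix(0, nrow = nRows, ncol = nc)
  rows0 <- seq_len(nRows) - 1
  # a continuous band: interpolate the trace across every column
  yBand <- stats::approx(trace@x, trace@y, xout = 0:(nc - 1), rule = 2)$y
  for (j in seq_len(nc)) {
    px[, j] <- peak * exp(-(rows0 - yBand[j])^2 / (2 * bandSigma^2))
  }
  if (noiseSd > 0) {
    rng <- .localRNG(seed)
    px <- px + matrix(rng$rnorm(length(px), 0, noiseSd), nrow = nRows)
    px <- pmax(px, 0)
  }
  bScanImage(px, provenance = "synthetic")
}

#' Simulate a cohort with target Spearman correlation structure
#'
#' Draws latent Gaussian vectors whose Pearson correlations are the
#' copula conversion \eqn{2\sin(\pi\rho_s/6)} of the requested Spearman
#' correlations, then maps them linearly to the stated marginal means and
#' SDs (a monotone map, so the rank correlations are preserved). The
#' ovality ratio is truncated to be positive, and the disc axis class is
#' derived from it (ratio > 1 = horizontally long). Two rater columns are
#' emitted as the latent amplitude plus independent Gaussian measurement
#' error, plus a repeat by rater 1 for intra-rater reliability.
#'
#' Default marginals and correlation targets mirror a myopic adult
#' normal-eye cohort: amplitude 37.0 +/- 17.5 px, ovality 0.89 +/- 0.11,
#' spherical equivalent -4.71 +/- 3.41 D, axial length 25.4 +/- 1.5 mm,
#' height 167.6 +/- 8.4 cm; Spearman targets to amplitude -0.59
#' (ovality), -0.29 (spherical equivalent), 0.11 (axial length), -0.39
#' (height), and -0.82 between spherical equivalent and axial length.
#' Remaining covariate pairs follow a single-factor product rule. Rater
#' error SDs (intra 1.11 px, rater 2 5.0 px) are calibrated so the
#' expected intra- and inter-rater ICCs are 0.996 and 0.959 at subject
#' SD 17.5.
#'
#' @param nEyes cohort size.
#' @param amplitudeMean,amplitudeSd amplitude marginal (pixels).
#' @param ovalityMean,ovalitySd ovality-ratio marginal.
#' @param seMean,seSd spherical-equivalent marginal (diopters).
#' @param alMean,alSd axial-length marginal (mm).
#' @param heightMean,heightSd body-height marginal (cm).
#' @param rhoAmpOvality,rhoAmpSe,rhoAmpAl,rhoAmpHeight target Spearman
#'   correlations of each covariate with amplitude.
#' @param rhoSeAl target Spearman correlation between spherical
#'   equivalent and axial length.
#' @param intraErrorSd,rater2ErrorSd measurement error SDs (pixels).
#' @param empirical when `TRUE` the latent draw is rescaled so its sample
#'   covariance equals the target exactly (`MASS::mvrnorm(empirical =)`);
#'   use this to build a stand-in for a fixed reference dataset whose
#'   statistics are known, rather than a random cohort from the
#'   population.
#' @param seed integer seed.
#' @return data frame with columns eye_id, amplitude, amplitude_rater1,
#'   amplitude_rater1_repeat, amplitude_rater2, amplitude_mean,
#'   ovality_ratio, axis_class, spherical_equivalent, axial_length,
#'   body_height.
#' @export
simulateCohort <- function(nEyes = 126L,
                           amplitudeMean = 37.0, amplitudeSd = 17.5,
                           ovalityMean = 0.89, ovalitySd = 0.11,
                           seMean = -4.71, seSd = 3.41,
                           alMean = 25.4, alSd = 1.5,
                           heightMean = 167.6, heightSd = 8.4,
                           rhoAmpOvality = -0.59, rhoAmpSe = -0.29,
                           rhoAmpAl = 0.11, rhoAmpHeight = -0.39,
                           rhoSeAl = -0.82,
                           intraErrorSd = 1.11, rater2ErrorSd = 5.0,
                           empirical = FALSE, seed = 1L) {
  rhos <- c(amp = 1, ovality = rhoAmpOvality, se = rhoAmpSe,
            al = rhoAmpAl, height = rhoAmpHeight)
  stopifnot(all(abs(rhos[-1]) < 1), abs(rhoSeAl) < 1,
            amplitudeSd > 0, ovalitySd > 0, seSd > 0, alSd > 0,
            heightSd > 0, nEyes >= 3)
  # Spearman targets: amplitude row from the arguments, covariate pairs
  # by the single-factor product rule, except the stated se-al pair.
  vars <- names(rhos)
  rs <- outer(rhos, rhos)
  diag(rs) <- 1
  rs["se", "al"] <- rs["al", "se"] <- rhoSeAl
  rp <- 2 * sin(pi * rs / 6)   # copula conversion to latent Pearson
  diag(rp) <- 1
  ev <- eigen(rp, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    bad <- which(abs(rp) == max(abs(rp[upper.tri(rp)])), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "target correlation matrix is not positive semidefinite (check pair %s-%s)",
      vars[bad[1]], vars[bad[2]]))
  }
  rng <- .localRNG(seed)
  z <- rng$mvrnorm(n = nEyes, mu = rep(0, 5), Sigma = rp,
                   empirical = empirical)
  colnames(z) <- vars
  amp <- amplitudeMean + amplitudeSd * z[, "amp"]
  ovality <- pmax(ovalityMean + ovalitySd * z[, "ovality"], 1e-6)
  se <- seMean + seSd * z[, "se"]
  al <- alMean + alSd * z[, "al"]
  height <- heightMean + heightSd * z[, "height"]
  r1 <- amp + rng$rnorm(nEyes, 0, intraErrorSd)
  r1b <- amp + rng$rnorm(nEyes, 0, intraErrorSd)
  r2 <- amp + rng$rnorm(nEyes, 0, rater2ErrorSd)
  data.frame(
    eye_id = sprintf("eye%03d", seq_len(nEyes)),
    amplitude = amp,
    amplitude_rater1 = r1,
    amplitude_rater1_repeat = r1b,
    amplitude_rater2 = r2,
    amplitude_mean = (r1 + r2) / 2,
    ovality_ratio = ovality,
    axis_class = ifelse(ovality > 1, "horizontal", "vertical"),
    spherical_equivalent = se,
    axial_length = al,
    body_height = height,
    stringsAsFactors = FALSE)
}

#' Write a complete toy fixture dataset
#'
#' Emits `traces/*.csv`, `images/*.png` and `cohort.csv` under `dir`:
#' per-eye sine traces whose amplitudes are the cohort's latent
#' amplitudes, rendered band images for the first `nImages` eyes, and the
#' cohort table. Used by tests and documentation; everything is
#' regenerated from code, nothing is shipped.
#'
#' @param dir output directory (created if needed).
#' @param nEyes cohort size.
#' @param nImages how many eyes also get a rendered PNG.
#' @param nPoints points per trace.
#' @param noiseSd trace plotting noise SD (pixels).
#' @param scanWidth scan width (pixels).
#' @param seed integer seed.
#' @return invisibly, the cohort data frame (with a `c_true` column of
#'   generating phases).
#' @export
writeFixtures <- function(dir, nEyes = 10L, nImages = 2L, nPoints = 64L,
                          noiseSd = 1, scanWidth = 256L, seed = 1L) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  cohort <- simulateCohort(nEyes = nEyes, seed = seed)
  cohort$amplitude <- pmax(abs(cohort$amplitude), 1)  # renderable traces
  for (i in seq_len(nEyes)) {
    tr <- simulateTrace(aTrue = cohort$amplitude[i], cTrue = 1,
                        noiseSd = noiseSd, nPoints = nPoints,
                        scanWidth = scanWidth, seed = seed + i,
                        eyeId = cohort$eye_id[i])
    saveTrace(tr, file.path(dir, "traces", paste0(cohort$eye_id[i], ".csv")))
    if (i <= nImages) {
      img <- renderBScan(tr, bandSigma = 3, peak = 1, noiseSd = 0.02,
                         seed = seed + 1000L + i)
      writeBScan(img, file.path(dir, "images",
                                paste0(cohort$eye_id[i], ".png")))
    }
  }
  utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(cohort)
}
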