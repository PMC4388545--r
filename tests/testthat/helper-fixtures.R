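# Shared fixture builders. Everything is generated in code; no files ship.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A centred trace sampled on a uniform full-width grid, with the sine
# defined directly in centred coordinates: v = a*sin(2*pi*u/W - cc).
makeCenteredSine <- function(a, cc, n = 1024, W = 1024, noiseSd = 0,
                             seed = NULL) {
  u <- (0:(n - 1)) * (W / n) - W / 2  # uniform, exactly one period
  v <- a * sin(2 * pi * u / W - cc)
  if (noiseSd > 0) {
    stopifnot(!is.null(seed))
    v <- v + withr::with_seed(seed, rnorm(n, 0, noiseSd))
  }
  new("CenteredTrace", u = u, v = v - mean(v), scanWidth = W, eyeId = "fx")
}

# Discretised ellipse outline, semi-axes (ax horizontal, ay vertical),
# optionally rotated clockwise (y-down screen coordinates) by deg degrees.
makeEllipseOutline <- function(ax, ay, deg = 0, nVertices = 360,
                               cx = 300, cy = 300) {
  th <- seq(0, 2 * pi, length.out = nVertices + 1)[-(nVertices + 1)]
  x0 <- ax * cos(th); y0 <- ay * sin(th)
  phi <- deg * pi / 180  # clockwise in y-down coords = usual CCW math angle
  x <- cx + x0 * cos(phi) - y0 * sin(phi)
  y <- cy + x0 * sin(phi) + y0 * cos(phi)
  discOutline(x, y)
}

# By-definition two-way ANOVA ICC(A,1) oracle: explicit loops over the
# sums of squares, no shared code with the implementation.
iccOracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - g)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - g)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - g)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Brute-force Spearman: explicit mid-rank assignment then the Pearson
# product-moment formula written out.
spearmanOracle <- function(x, y) {
  midrank <- function(z) {
    r <- numeric(length(z))
    for (i in seq_along(z)) {
      r[i] <- sum(z < z[i]) + (sum(z == z[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
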