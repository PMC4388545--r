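test_that("noiseless sine traces are recovered exactly", {
  for (a in c(5, 40)) {
    for (cc in c(0.3, 1.0, 4.2)) {
      f <- fitSine(makeCenteredSine(a, cc))
      expect_equal(f@a, a, tolerance = 1e-9)
      expect_equal(f@b, 2 * pi / 1024, tolerance = 1e-9)
      expect_equal(f@c, cc, tolerance = 1e-7)
      expect_equal(f@rSquared, 1, tolerance = 1e-12)
      expect_true(f@qualityPass)
    }
  }
})

test_that("flat and near-flat traces follow the degenerate-fit rule", {
  ct <- new("CenteredTrace", u = seq(-50, 50, length.out = 101),
            v = rep(0, 101), scanWidth = 101, eyeId = "flat")
  f <- fitSine(ct)
  expect_equal(f@a, 0)
  expect_equal(f@rSquared, 1)
  expect_true(f@qualityPass)
  expect_true(f@converged)
  expect_equal(amplitude(f), 0)
  expect_error(tiltDirection(f), "undefined")
})

test_that("fixed-b fit equals the closed-form linear solution", {
  W <- 512
  b0 <- 2 * pi / W
  set.seed(301)
  for (rep in 1:10) {
    u <- sort(runif(64, -W / 2, W / 2))
    v <- runif(1, 2, 40) * sin(b0 * u - runif(1, 0, 2 * pi)) + rnorm(64, 0, 3)
    v <- v - mean(v)
    ct <- new("CenteredTrace", u = u, v = v, scanWidth = W, eyeId = "r")
    f <- fitSine(ct, fitOptions(bMode = "fixed_period"))
    # independent closed form: regress v on sin(b0 u), cos(b0 u)
    co <- coef(lm(v ~ 0 + sin(b0 * u) + cos(b0 * u)))
    aLin <- sqrt(sum(co^2))
    cLin <- atan2(-co[2], co[1]) %% (2 * pi)
    expect_equal(f@a, aLin, tolerance = 1e-10)
    expect_equal(f@b, b0)
    expect_equal(f@c, unname(cLin), tolerance = 1e-10)
  }
})

test_that("free-b fit agrees with an independent nonlinear optimiser", {
  skip_if_not_installed("minpack.lm")
  set.seed(77)
  for (rep in 1:5) {
    a0 <- runif(1, 10, 50); c0 <- runif(1, 0.2, 6)
    bTrue <- 2 * pi / 1024 * runif(1, 0.8, 1.25)
    ct <- makeCenteredSine(1, 0, n = 400)  # placeholder grid
    u <- ct@u
    v <- a0 * sin(bTrue * u - c0) + rnorm(400, 0, 2)
    v <- v - mean(v)
    ct <- new("CenteredTrace", u = u, v = v, scanWidth = 1024, eyeId = "x")
    f <- fitSine(ct)
    ref <- minpack.lm::nlsLM(
      v ~ a * sin(b * u - cc),
      start = list(a = f@a, b = 2 * pi / 1024, cc = f@c %% (2 * pi)),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    expect_equal(f@rss, sum(residuals(ref)^2), tolerance = 1e-6)
    expect_equal(f@a, abs(coef(ref)[["a"]]), tolerance = 1e-4)
  }
})

test_that("fit is scale equivariant and reflection invariant", {
  ct <- makeCenteredSine(25, 2.2, n = 256, noiseSd = 2, seed = 9L)
  f <- fitSine(ct)
  for (k in c(0.5, 3)) {
    fk <- fitSine(new("CenteredTrace", u = ct@u, v = k * ct@v,
                      scanWidth = ct@scanWidth, eyeId = "k"))
    expect_equal(fk@a, k * f@a, tolerance = 1e-6)
    expect_equal(fk@b, f@b, tolerance = 1e-8)
    expect_equal(fk@c, f@c, tolerance = 1e-6)
    expect_equal(fk@rSquared, f@rSquared, tolerance = 1e-10)
  }
  fneg <- fitSine(new("CenteredTrace", u = ct@u, v = -ct@v,
                      scanWidth = ct@scanWidth, eyeId = "neg"))
  expect_equal(fneg@a, f@a, tolerance = 1e-6)
  expect_equal(fneg@rSquared, f@rSquared, tolerance = 1e-10)
  expect_equal((fneg@c - f@c) %% (2 * pi), pi, tolerance = 1e-5)
})

test_that("sign normalisation maps negative amplitude to a phase shift", {
  # data generated with a = -15 must come back as a = 15, c shifted by pi
  ct0 <- makeCenteredSine(15, 0.5 + pi, n = 256)
  vNeg <- -15 * sin(2 * pi * ct0@u / 1024 - 0.5)
  ctNeg <- new("CenteredTrace", u = ct0@u, v = vNeg - mean(vNeg),
               scanWidth = 1024, eyeId = "n")
  f <- fitSine(ctNeg)
  expect_gte(f@a, 0)
  expect_equal(f@a, 15, tolerance = 1e-8)
  expect_equal(f@c, 0.5 + pi, tolerance = 1e-6)
  expect_true(f@c >= 0 && f@c < 2 * pi)
})

test_that("amplitude recovery holds across amplitude and noise grids", {
  n <- 1024
  for (a in c(5, 20, 40, 80)) {
    for (sg in c(0, 2, 5)) {
      errs <- vapply(1:25, function(s) {
        ct <- makeCenteredSine(a, 1.0, n = n, noiseSd = sg, seed = 1000L * a + s)
        abs(fitSine(ct)@a - a)
      }, numeric(1))
      expect_lt(median(errs), max(0.01, 0.5 * sg * sqrt(2 / n) * 3))
    }
  }
})

test_that("fit quality degrades monotonically with noise on matched seeds", {
  for (s in 1:5) {
    r2 <- vapply(c(0, 2, 5, 10), function(sg) {
      ct <- makeCenteredSine(20, 1.0, n = 512,
                             noiseSd = max(sg, 1e-9), seed = s)
      fitSine(ct)@rSquared
    }, numeric(1))
    expect_true(all(diff(r2) <= 1e-9))
  }
})

test_that("goodness applies the strict R^2 > 0.90 gate", {
  f <- fitSine(makeCenteredSine(30, 1))
  expect_equal(goodness(f)$rSquared, 1)
  expect_true(goodness(f)$qualityPass)

  # gross outlier: R^2 < 1 and equals 1 - rss/tss recomputed independently
  ct <- makeCenteredSine(30, 1, n = 128)
  v <- ct@v; v[40] <- v[40] + 100; v <- v - mean(v)
  ct2 <- new("CenteredTrace", u = ct@u, v = v, scanWidth = 1024, eyeId = "o")
  f2 <- fitSine(ct2)
  expect_lt(f2@rSquared, 1)
  pred <- f2@a * sin(f2@b * ct2@u - f2@c)
  expect_equal(f2@rSquared,
               1 - sum((ct2@v - pred)^2) / sum((ct2@v - mean(ct2@v))^2),
               tolerance = 1e-12)

  # the boundary is strict: exactly 0.90 fails
  fakeFit <- new("SineFit", a = 10, b = 0.01, c = 0, rSquared = 0.90,
                 rss = 1, nPoints = 100L, converged = TRUE,
                 qualityPass = FALSE, eyeId = "b")
  expect_false(goodness(fakeFit)$qualityPass)
})

test_that("tilt direction locates the wave minimum", {
  f <- new("SineFit", a = 20, b = 2 * pi / 1024, c = 0, rSquared = 1,
           rss = 0, nPoints = 100L, converged = TRUE, qualityPass = TRUE,
           eyeId = "d")
  expect_equal(tiltDirection(f, scanWidth = 1024), 3 * pi / 2)
  # shifting c by 2*pi leaves the direction unchanged (mod reduction)
  f2 <- new("SineFit", a = 20, b = 2 * pi / 1024, c = 0.8, rSquared = 1,
            rss = 0, nPoints = 100L, converged = TRUE, qualityPass = TRUE,
            eyeId = "d")
  th1 <- tiltDirection(f2, 1024)
  uMin <- (f2@c + 2 * pi + 3 * pi / 2) / f2@b
  th2 <- (uMin * 2 * pi / 1024) %% (2 * pi)
  expect_equal(th1, th2, tolerance = 1e-9)
})
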