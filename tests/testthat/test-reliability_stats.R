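test_that("ICC(A,1) matches the hand-computed ANOVA value", {
  # mean squares computed by hand for this 4x2 matrix:
  # MSR = 38.375/3, MSC = 1.125, MSE = 0.375/3
  # ICC(A,1) = 12.666667 / 13.416667
  m <- matrix(c(8, 9, 4, 5, 6, 6, 2, 3), ncol = 2, byrow = TRUE)
  res <- iccAbsoluteAgreement(m)
  expect_equal(res$msRows, 38.375 / 3, tolerance = 1e-12)
  expect_equal(res$msCols, 1.125, tolerance = 1e-12)
  expect_equal(res$msError, 0.125, tolerance = 1e-12)
  expect_equal(res$icc, (38.375 / 3 - 0.125) /
                 (38.375 / 3 + 0.125 + 0.5 * (1.125 - 0.125)),
               tolerance = 1e-12)
  expect_true(res$ciLower <= res$icc && res$icc <= res$ciUpper)
})

test_that("ICC equals the by-definition oracle on random matrices", {
  set.seed(501)
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    k <- sample(2:3, 1)
    m <- matrix(rnorm(n * k, 20, 5), n, k)
    expect_equal(iccAbsoluteAgreement(m)$icc, iccOracle(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC mean squares agree with aov()", {
  set.seed(502)
  n <- 8; k <- 3
  m <- matrix(rnorm(n * k, 10, 2), n, k)
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(aov(y ~ subj + rater, data = d))[[1]]
  res <- iccAbsoluteAgreement(m)
  expect_equal(res$msRows, tab["subj", "Mean Sq"], tolerance = 1e-10)
  expect_equal(res$msCols, tab["rater", "Mean Sq"], tolerance = 1e-10)
  expect_equal(res$msError, tab["Residuals", "Mean Sq"], tolerance = 1e-10)
})

test_that("perfect agreement gives ICC 1; offsets are penalised", {
  m <- matrix(c(5, 5, 9, 9, 2, 2, 7, 7), ncol = 2, byrow = TRUE)
  res <- iccAbsoluteAgreement(m)
  expect_equal(res$icc, 1)
  expect_equal(res$ciUpper, 1)

  base <- rnorm(10, 30, 8)
  withr::with_seed(77, base <- rnorm(10, 30, 8))
  mOff <- cbind(base, base + 10)
  resOff <- iccAbsoluteAgreement(mOff)
  expect_lt(resOff$icc, 1)
  # the consistency form ignores the offset entirely
  consistency <- with(resOff, (msRows - msError) /
                        (msRows + (k - 1) * msError))
  expect_equal(consistency, 1, tolerance = 1e-9)
  expect_lt(resOff$icc, consistency)

  expect_error(iccAbsoluteAgreement(matrix(3, 4, 2)), "zero total variance")
})

test_that("ICC is invariant to subject and rater permutations", {
  withr::with_seed(503, m <- matrix(rnorm(18, 40, 10), 6, 3))
  r0 <- iccAbsoluteAgreement(m)$icc
  expect_equal(iccAbsoluteAgreement(m[sample(6), ])$icc, r0,
               tolerance = 1e-12)
  expect_equal(iccAbsoluteAgreement(m[, c(3, 1, 2)])$icc, r0,
               tolerance = 1e-12)
})

test_that("simulated reliability is recovered at the study scale", {
  # subject SD 17.5, error SD set for a true ICC of 0.96
  sigmaS <- 17.5
  sigmaE <- sigmaS * sqrt(1 / 0.96 - 1)
  est <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      truth <- rnorm(126, 37, sigmaS)
      m <- cbind(truth + rnorm(126, 0, sigmaE),
                 truth + rnorm(126, 0, sigmaE))
    })
    iccAbsoluteAgreement(m)$icc
  }, numeric(1))
  expect_lt(abs(median(est) - 0.96), 0.01)
})

test_that("Spearman matches brute-force mid-ranks on ties and monotone cases", {
  expect_equal(spearmanCorr(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearmanCorr(1:5, c(10, 8, 6, 4, 2))$rho, -1)
  # hand oracle: ranks (1, 2.5, 2.5, 4) vs (3, 1, 4, 2) -> -1.5/sqrt(22.5)
  res <- spearmanCorr(c(1, 2, 2, 4), c(3, 1, 4, 2))
  expect_equal(res$rho, -1.5 / sqrt(22.5), tolerance = 1e-12)
  expect_equal(res$rho, spearmanOracle(c(1, 2, 2, 4), c(3, 1, 4, 2)),
               tolerance = 1e-12)

  set.seed(601)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:10, n, replace = TRUE)  # ties likely
    y <- rnorm(n)
    expect_equal(spearmanCorr(x, y)$rho, spearmanOracle(x, y),
                 tolerance = 1e-12)
    expect_equal(spearmanCorr(x, y)$rho,
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  expect_error(spearmanCorr(rep(1, 5), 1:5), "constant")
  expect_error(spearmanCorr(1:2, 1:2), "at least 3")
})

test_that("Spearman p-values follow the t approximation and exact mode", {
  withr::with_seed(602, { x <- rnorm(20); y <- x + rnorm(20, 0, 2) })
  res <- spearmanCorr(x, y)
  tStat <- res$rho * sqrt((20 - 2) / (1 - res$rho^2))
  expect_equal(res$pValue, 2 * pt(abs(tStat), 18, lower.tail = FALSE),
               tolerance = 1e-12)

  # exact permutation p for a small untied sample matches cor.test
  withr::with_seed(603, { x <- rnorm(6); y <- rnorm(6) })
  ex <- spearmanCorr(x, y, pMode = "exact")
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(ex$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ex$pValue, ref$p.value, tolerance = 1e-9)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(604)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    r0 <- spearmanCorr(x, y)$rho
    expect_equal(spearmanCorr(exp(x), y)$rho, r0, tolerance = 1e-12)
    expect_equal(spearmanCorr(x, y^3 + 5 * y)$rho, r0, tolerance = 1e-12)
  }
})

test_that("summary statistics use the sample SD and full range", {
  s <- summaryStats(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(c(s$min, s$max), c(1, 3))
  expect_equal(summaryStats(c(4, 4, 4))$sd, 0)
  expect_error(summaryStats(numeric(0)), "at least 2")

  withr::with_seed(605, z <- rnorm(1000, 37, 17.5))
  expect_lt(abs(summaryStats(z)$mean - 37), 17.5 * 3 / sqrt(1000))
})
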