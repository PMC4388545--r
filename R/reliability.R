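#' Construct a rating matrix
#'
#' @param values numeric matrix, n subjects (rows) x k raters (columns).
#' @param subjectIds,raterIds optional identifiers; defaults are derived
#'   from dimnames or generated.
#' @return a [RatingMatrix-class] object.
#' @export
ratingMatrix <- function(values, subjectIds = NULL, raterIds = NULL) {
  values <- as.matrix(values)
  if (is.null(subjectIds))
    subjectIds <- rownames(values) %||% paste0("s", seq_len(nrow(values)))
  if (is.null(raterIds))
    raterIds <- colnames(values) %||% paste0("r", seq_len(ncol(values)))
  new("RatingMatrix", values = values,
      subjectIds = as.character(subjectIds),
      raterIds = as.character(raterIds))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-way absolute-agreement intraclass correlation
#'
#' Computes ICC(A,1), the single-measures intraclass correlation under a
#' two-way model for absolute agreement (McGraw & Wong convention):
#' \deqn{\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the subject, rater and
#' residual mean squares of the two-way ANOVA decomposition. Absolute
#' agreement charges systematic rater offsets against the coefficient,
#' unlike the consistency form. The 95% confidence interval uses the
#' F-based procedure with Satterthwaite degrees of freedom; the p-value
#' tests subject variance via \eqn{F = MS_R/MS_E}.
#'
#' The average-measures coefficient ICC(A,k) is also returned, since
#' reliability software reports either depending on configuration.
#'
#' @param ratings a [RatingMatrix-class] object (or a plain matrix).
#' @param conf confidence level for the interval, default 0.95.
#' @return list with `icc`, `ciLower`, `ciUpper`, `pValue`, `msRows`,
#'   `msCols`, `msError`, `iccAverage`, `n`, `k`.
#' @examples
#' m <- matrix(c(8, 9, 4, 5, 6, 6, 2, 3), ncol = 2, byrow = TRUE)
#' iccAbsoluteAgreement(m)
#' @export
iccAbsoluteAgreement <- function(ratings, conf = 0.95) {
  v <- if (is(ratings, "RatingMatrix")) ratings@values else as.matrix(ratings)
  n <- nrow(v); k <- ncol(v)
  stopifnot(n >= 2L, k >= 2L, !anyNA(v))
  grand <- mean(v)
  rowM <- rowMeans(v); colM <- colMeans(v)
  ssTotal <- sum((v - grand)^2)
  if (ssTotal == 0) stop("zero total variance: ICC undefined")
  ssRows <- k * sum((rowM - grand)^2)
  ssCols <- n * sum((colM - grand)^2)
  ssErr <- ssTotal - ssRows - ssCols
  msR <- ssRows / (n - 1)
  msC <- ssCols / (k - 1)
  msE <- ssErr / ((n - 1) * (k - 1))
  icc <- (msR - msE) / (msR + (k - 1) * msE + (k / n) * (msC - msE))
  iccK <- (msR - msE) / (msR + (msC - msE) / n)
  alpha <- 1 - conf
  if (1 - icc < 1e-15) {
    # exact agreement: rater and error mean squares vanish, CI collapses
    lower <- upper <- 1
  } else {
    # F-based CI for ICC(A,1), Satterthwaite df for the rater+error mixture
    aa <- (k * icc) / (n * (1 - icc))
    bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    vDen <- (aa * msC + bb * msE)^2 /
      ((aa * msC)^2 / (k - 1) + (bb * msE)^2 / ((n - 1) * (k - 1)))
    fU <- stats::qf(1 - alpha / 2, n - 1, vDen)
    fL <- stats::qf(1 - alpha / 2, vDen, n - 1)
    lower <- n * (msR - fU * msE) /
      (fU * (k * msC + (k * n - k - n) * msE) + n * msR)
    upper <- n * (fL * msR - msE) /
      (k * msC + (k * n - k - n) * msE + n * fL * msR)
  }
  fStat <- msR / msE
  p <- stats::pf(fStat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, ciLower = min(lower, icc), ciUpper = max(upper, icc),
       pValue = p, msRows = msR, msCols = msC, msError = msE,
       iccAverage = iccK, n = n, k = k)
}

#' Spearman rank correlation with the t approximation
#'
#' Rho is the Pearson correlation of mid-ranks (average ranks for ties).
#' The two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} degrees of freedom,
#' the large-sample default of mainstream statistical software. For small
#' samples an exact permutation p-value is available
#' (`pMode = "exact"`, n <= 10).
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @param pMode `"t"` (default) or `"exact"`.
#' @return list with `rho`, `pValue`, `n`.
#' @export
spearmanCorr <- function(x, y, pMode = c("t", "exact")) {
  pMode <- match.arg(pMode)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: ranks are degenerate")
  rho <- stats::cor(rank(x), rank(y))
  if (pMode == "exact") {
    if (n > 10L) stop("exact permutation p-value limited to n <= 10")
    perms <- .permutations(n)
    ry <- rank(y)
    rhoPerm <- apply(perms, 1, function(pp) stats::cor(rank(x), ry[pp]))
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tStat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(tStat), n - 2, lower.tail = FALSE)
    }
  }
  list(rho = rho, pValue = p, n = n)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Mean, SD and range of a measurement column
#'
#' Sample SD uses the n-1 denominator, matching demographic summary
#' tables of the form "mean +/- SD (range)".
#'
#' @param values numeric vector, n >= 2 after dropping non-finite values.
#' @return list with `mean`, `sd`, `min`, `max`, `n`.
#' @export
summaryStats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 finite values")
  list(mean = mean(values), sd = stats::sd(values),
       min = min(values), max = max(values), n = length(values))
}
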