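# Agreement-statistics battery: ICC(2,1), Bland-Altman, Cohen's kappa,
# paired Wilcoxon signed-rank, median [IQR], interpretation bands.

.asPairs <- function(a, b) {
  if (is(a, "PairedMeasurements")) return(a)
  pairedMeasurements(a, b)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement ICC from
#' the two-way ANOVA mean squares:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)}
#' with MSR/MSC/MSE the between-subject, between-rater and residual
#' mean squares. The p-value is the one-sided F test of MSR/MSE on
#' (n-1, (n-1)(k-1)) degrees of freedom (the conventional test of
#' ICC > 0).
#'
#' @param a numeric values of the first rater/method, or a
#'   [PairedMeasurements-class].
#' @param b numeric values of the second rater/method (ignored when
#'   \code{a} is a \code{PairedMeasurements}).
#' @return list with \code{icc}, \code{p}, \code{msr}, \code{msc},
#'   \code{mse}, \code{df1}, \code{df2}.
#' @examples
#' iccTwoWayRandom(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
#' @export
iccTwoWayRandom <- function(a, b = NULL) {
  p <- .asPairs(a, b)
  x <- cbind(p@valuesA, p@valuesB)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) stop("ICC requires at least 2 subjects")
  gm <- mean(x)
  if (sum((x - gm)^2) < 1e-24)
    stop("ICC undefined: zero total variance")
  rowM <- rowMeans(x); colM <- colMeans(x)
  ssr <- k * sum((rowM - gm)^2)
  ssc <- n * sum((colM - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  fstat <- msr / mse
  pval <- stats::pf(fstat, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  list(icc = icc, p = pval, msr = msr, msc = msc, mse = mse,
       df1 = n - 1, df2 = (n - 1) * (k - 1))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are taken as (first argument minus second); the bias is
#' their mean and the limits of agreement are
#' \code{bias +/- 1.96 * SD} with the sample standard deviation.
#' Swapping the arguments negates the bias and mirrors the limits.
#'
#' @inheritParams iccTwoWayRandom
#' @return list with \code{bias}, \code{loaLow}, \code{loaHigh},
#'   \code{sd}, \code{direction = "a-b"}.
#' @examples
#' blandAltman(c(2, 4, 6), c(1, 2, 3))
#' @export
blandAltman <- function(a, b = NULL) {
  p <- .asPairs(a, b)
  d <- p@valuesA - p@valuesB
  if (length(d) < 2L) stop("Bland-Altman requires at least 2 pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
       sd = s, direction = "a-b")
}

#' Cohen's kappa for categorical agreement
#'
#' Unweighted kappa \code{(p_o - p_e) / (1 - p_e)} from the full
#' cross-tabulation over a fixed ordered category set (empty rows and
#' columns retained). The p-value tests kappa = 0 by the large-sample
#' normal approximation with the Fleiss standard error under the null.
#'
#' @param labelsA,labelsB equal-length label vectors.
#' @param categories fixed category set; defaults to the MR severity
#'   grades.
#' @return list with \code{kappa}, \code{p}, \code{pObserved},
#'   \code{pExpected}, \code{table}.
#' @examples
#' cohensKappa(rep(c("none", "mild"), c(3, 3)),
#'             rep(c("none", "mild"), c(4, 2)))
#' @export
cohensKappa <- function(labelsA, labelsB, categories = severityLevels()) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length")
  fa <- factor(as.character(labelsA), levels = categories)
  fb <- factor(as.character(labelsB), levels = categories)
  if (anyNA(fa) || anyNA(fb))
    stop("labels outside the declared category set")
  tab <- table(fa, fb)
  n <- sum(tab)
  prop <- tab / n
  po <- sum(diag(prop))
  rowP <- rowSums(prop); colP <- colSums(prop)
  pe <- sum(rowP * colP)
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: expected agreement is 1 (all mass in one cell)")
  kappa <- (po - pe) / (1 - pe)
  # Fleiss large-sample SE of kappa under H0: kappa = 0
  se0 <- sqrt((pe + pe^2 - sum(rowP * colP * (rowP + colP))) / (n * (1 - pe)^2))
  z <- kappa / se0
  pval <- 2 * stats::pnorm(-abs(z))
  list(kappa = kappa, p = pval, pObserved = po, pExpected = pe, table = tab)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences (zeros dropped). With at most
#' 25 nonzero differences the p-value is exact, computed from the full
#' distribution of the positive-rank sum over all sign assignments
#' (a convolution over the observed ranks, which handles ties);
#' otherwise the normal approximation with tie correction and
#' continuity correction is used. All differences zero yields p = 1 by
#' convention.
#'
#' @inheritParams iccTwoWayRandom
#' @param exactLimit largest number of nonzero differences for the
#'   exact path.
#' @return list with \code{p}, \code{statistic} (positive-rank sum W+),
#'   \code{n} (nonzero differences), \code{exact}.
#' @examples
#' wilcoxonSignedRank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p  # 0.0625
#' @export
wilcoxonSignedRank <- function(a, b = NULL, exactLimit = 25L) {
  p <- .asPairs(a, if (is.null(b) && !is(a, "PairedMeasurements"))
    rep(0, length(a)) else b)
  d <- p@valuesA - p@valuesB
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = 1, statistic = NA_real_, n = 0L, exact = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactLimit) {
    # distribution of W+ over all 2^n sign assignments, via polynomial
    # convolution over doubled ranks (integers even with midranks)
    r2 <- as.integer(round(2 * r))
    f <- rep(0, sum(r2) + 1L)
    f[1L] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1L):length(f)] <- g[(ri + 1L):length(f)] + f[1L:(length(f) - ri)]
      f <- g
    }
    f <- f / sum(f)
    W2 <- as.integer(round(2 * W))
    pLow <- sum(f[1L:(W2 + 1L)])
    pHigh <- sum(f[(W2 + 1L):length(f)])
    pval <- min(1, 2 * min(pLow, pHigh))
    list(p = pval, statistic = W, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    list(p = 2 * stats::pnorm(-abs(z)), statistic = W, n = n, exact = FALSE)
  }
}

#' Median and interquartile range
#'
#' Median with 25th/75th percentiles under the linear-interpolation
#' quantile convention (R type 7).
#'
#' @param values numeric, nonempty.
#' @return named numeric: \code{median}, \code{q25}, \code{q75}.
#' @examples
#' summarizeMedianIQR(c(1, 2, 3, 4))
#' @export
summarizeMedianIQR <- function(values) {
  if (!length(values)) stop("empty input")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2L], q25 = q[1L], q75 = q[3L])
}

#' Interpretation bands for ICC and kappa
#'
#' ICC: moderate (0.50-0.70), good (0.71-0.85), strong (0.86-0.95),
#' excellent (0.96-1.00). Kappa: poor (<= 0), slight (0.01-0.20), fair
#' (0.21-0.40), moderate (0.41-0.60), substantial (0.61-0.80),
#' excellent (0.81-1.00). Band membership is decided on the value
#' rounded to two decimals (the bands' printed precision); values below
#' the lowest band map to \code{"below scale"} (ICC) or \code{"poor"}
#' (kappa).
#'
#' @param metric \code{"icc"} or \code{"kappa"}.
#' @param value numeric in [-1, 1].
#' @return character label.
#' @examples
#' interpretAgreement("icc", 0.80)    # "good"
#' interpretAgreement("kappa", 0.27)  # "fair"
#' @export
interpretAgreement <- function(metric = c("icc", "kappa"), value) {
  metric <- match.arg(metric)
  if (!is.finite(value) || value < -1 || value > 1)
    stop("value must lie in [-1, 1]")
  v <- round(value, 2)
  if (metric == "icc") {
    if (v < 0.50) "below scale"
    else if (v <= 0.70) "moderate"
    else if (v <= 0.85) "good"
    else if (v <= 0.95) "strong"
    else "excellent"
  } else {
    if (v <= 0) "poor"
    else if (v <= 0.20) "slight"
    else if (v <= 0.40) "fair"
    else if (v <= 0.60) "moderate"
    else if (v <= 0.80) "substantial"
    else "excellent"
  }
}

#' Run the full agreement battery on paired measurements
#'
#' Computes ICC(2,1), Bland-Altman bias and limits of agreement, the
#' paired Wilcoxon signed-rank p-value and - when both label vectors
#' are present - Cohen's kappa on the severity grades, with
#' interpretation labels.
#'
#' @param pairs a [PairedMeasurements-class].
#' @return an [AgreementResult-class].
#' @examples
#' pm <- pairedMeasurements(c(10, 20, 35, 5), c(12, 18, 40, 6),
#'                          labelsA = c("mild", "mild", "moderate", "none"),
#'                          labelsB = c("mild", "mild", "moderate", "none"))
#' agreementBattery(pm)
#' @export
agreementBattery <- function(pairs) {
  stopifnot(is(pairs, "PairedMeasurements"))
  icc <- iccTwoWayRandom(pairs)
  ba <- blandAltman(pairs)
  wx <- wilcoxonSignedRank(pairs)
  kp <- if (length(pairs@labelsA) && length(pairs@labelsB))
    cohensKappa(pairs@labelsA, pairs@labelsB) else NULL
  new("AgreementResult",
      icc = icc$icc, iccP = icc$p,
      bias = ba$bias, loaLow = ba$loaLow, loaHigh = ba$loaHigh,
      kappa = if (is.null(kp)) NA_real_ else kp$kappa,
      kappaP = if (is.null(kp)) NA_real_ else kp$p,
      pObserved = if (is.null(kp)) NA_real_ else kp$pObserved,
      pExpected = if (is.null(kp)) NA_real_ else kp$pExpected,
      wilcoxonP = wx$p,
      iccLabel = interpretAgreement("icc", max(-1, min(1, icc$icc))),
      kappaLabel = if (is.null(kp)) NA_character_ else
        interpretAgreement("kappa", max(-1, min(1, kp$kappa))),
      direction = "a-b", n = length(pairs@valuesA))
}
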