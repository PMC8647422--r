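# Independent ICC(2,1) oracle via stats::aov mean squares (a different
# computational route than the package's closed-form sums of squares).
iccOracleAov <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

test_that("ICC(2,1) matches an independent ANOVA oracle on small fixtures", {
  set.seed(7)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    a <- rnorm(n, 20, 8)
    b <- a + rnorm(n, 1, 3)
    res <- iccTwoWayRandom(a, b)
    expect_equal(res$icc, iccOracleAov(a, b), tolerance = 1e-10)
  }
  a <- c(9, 6, 8, 7, 10, 6)
  expect_equal(iccTwoWayRandom(a, a)$icc, 1)
  expect_lt(iccTwoWayRandom(a, a + 3)$icc, 1)  # absolute agreement penalizes offsets
  expect_error(iccTwoWayRandom(rep(5, 4), rep(5, 4)), "variance")
  expect_error(iccTwoWayRandom(1, 2), "2 subjects")
})

test_that("Bland-Altman limits are mean +/- 1.96 sample SD", {
  ba <- blandAltman(c(2, 4, 6), c(1, 2, 3))  # d = {1, 2, 3}
  expect_equal(ba$bias, 2)
  expect_equal(ba$loaLow, 0.04)
  expect_equal(ba$loaHigh, 3.96)
  same <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$bias, same$loaLow, same$loaHigh), c(0, 0, 0))
  swapped <- blandAltman(c(1, 2, 3), c(2, 4, 6))
  expect_equal(swapped$bias, -ba$bias)
  expect_equal(swapped$loaLow, -ba$loaHigh)
  expect_equal(swapped$loaHigh, -ba$loaLow)
})

test_that("Cohen's kappa reproduces the hand-computed confusion table", {
  # 2x2 table [[20, 5], [10, 15]]: p_o = 0.70, p_e = 0.50, kappa = 0.40
  la <- rep(c("none", "none", "mild", "mild"), c(20, 5, 10, 15))
  lb <- rep(c("none", "mild", "none", "mild"), c(20, 5, 10, 15))
  k <- cohensKappa(la, lb, categories = c("none", "mild"))
  expect_equal(k$pObserved, 0.70)
  expect_equal(k$pExpected, 0.50)
  expect_equal(k$kappa, 0.40)
  # perfect agreement
  lv <- c("none", "mild", "moderate", "mild", "severe")
  expect_equal(cohensKappa(lv, lv)$kappa, 1)
  # degenerate: all mass in one cell for both raters
  expect_error(cohensKappa(rep("mild", 5), rep("mild", 5)), "undefined")
  # invariant under category relabelling that preserves the table
  k2 <- cohensKappa(chartr("nm", "ab", la), chartr("nm", "ab", lb),
                    categories = c("aoae", "bild"))
  expect_equal(k2$kappa, k$kappa)
})

test_that("independent raters give kappa near zero (Monte-Carlo null)", {
  set.seed(11)
  n <- 1e4
  cats <- severityLevels()
  la <- sample(cats, n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1))
  lb <- sample(cats, n, replace = TRUE, prob = c(0.25, 0.35, 0.25, 0.15))
  expect_lt(abs(cohensKappa(la, lb)$kappa), 0.05)
})

test_that("Wilcoxon signed-rank exact path agrees with full enumeration", {
  # all-positive n = 5: p = 2/32
  expect_equal(wilcoxonSignedRank(c(1, 2, 3, 4, 5))$p, 0.0625)
  # perfectly symmetric differences
  expect_equal(wilcoxonSignedRank(c(1, -1, 2, -2))$p, 1)
  # all-zero differences -> p = 1 by convention
  expect_equal(wilcoxonSignedRank(c(0, 0, 0))$p, 1)
  # literal 2^n enumeration oracle on random data (with ties)
  set.seed(21)
  for (rep in 1:4) {
    d <- round(rnorm(8, 0.5, 2), 1)
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    allW <- as.vector(signs %*% r)
    pOracle <- min(1, 2 * min(mean(allW <= W), mean(allW >= W)))
    expect_equal(wilcoxonSignedRank(d)$p, pOracle)
    # and agreement with the stats implementation where it is exact
    if (!any(duplicated(abs(d))))
      expect_equal(wilcoxonSignedRank(d)$p,
                   stats::wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("normal approximation tracks the exact Wilcoxon p at moderate n", {
  set.seed(33)
  for (rep in 1:5) {
    d <- rnorm(15, 0.2)
    pExact <- wilcoxonSignedRank(d)$p
    pApprox <- wilcoxonSignedRank(d, exactLimit = 0L)$p
    expect_lt(abs(pExact - pApprox), 0.015)
  }
})

test_that("median [IQR] uses the linear-interpolation convention", {
  expect_equal(unname(summarizeMedianIQR(1:5)), c(3, 2, 4))
  expect_equal(unname(summarizeMedianIQR(7)), c(7, 7, 7))
  expect_equal(unname(summarizeMedianIQR(c(1, 2, 3, 4))), c(2.5, 1.75, 3.25))
  expect_error(summarizeMedianIQR(numeric()), "empty")
})

test_that("interpretation bands reproduce the published labels", {
  expect_equal(interpretAgreement("icc", 0.80), "good")
  expect_equal(interpretAgreement("icc", 0.97), "excellent")
  expect_equal(interpretAgreement("icc", 0.69), "moderate")
  expect_equal(interpretAgreement("icc", 0.30), "below scale")
  expect_equal(interpretAgreement("kappa", 0.27), "fair")
  expect_equal(interpretAgreement("kappa", 0.84), "excellent")
  expect_equal(interpretAgreement("kappa", 0.38), "fair")
  expect_equal(interpretAgreement("kappa", -0.2), "poor")
  expect_error(interpretAgreement("icc", 1.5), "lie in")
  expect_error(interpretAgreement("auc", 0.5))
})

test_that("the battery assembles a valid AgreementResult", {
  set.seed(5)
  va <- runif(12, 0, 70)
  vb <- va + rnorm(12, 2, 6)
  pm <- pairedMeasurements(va, vb,
                           labelsA = as.character(classifyMRSeverity(va)),
                           labelsB = as.character(classifyMRSeverity(pmax(vb, 0))))
  res <- agreementBattery(pm)
  expect_s4_class(res, "AgreementResult")
  expect_true(validObject(res))
  expect_true(res@loaLow <= res@bias && res@bias <= res@loaHigh)
  expect_true(abs(res@kappa) <= 1 && abs(res@icc) <= 1)
  expect_equal(res@direction, "a-b")
})
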