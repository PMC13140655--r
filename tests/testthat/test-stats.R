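# Cohort statistics: RM-ANOVA with sphericity handling, chi-square and
# McNemar symptom tests, logistic regressions, correlations, SF ratio.

test_that("RM-ANOVA matches the brute-force sums-of-squares oracle", {
  set.seed(18)
  for (i in 1:25) {
    n <- sample(4:8, 1); k <- sample(3:5, 1)
    Y <- matrix(rnorm(n * k, sd = runif(1, 0.5, 2)), n, k) +
      matrix(rep(rnorm(k), each = n), n, k)
    res <- rmAnovaGG(Y)
    orc <- rmAnovaOracle(Y)
    expect_equal(res$F, orc$F, tolerance = 1e-10)
    expect_equal(res$eta2p, orc$eta2p, tolerance = 1e-10)
    expect_equal(res$ssEffect, orc$ssEffect, tolerance = 1e-10)
    expect_equal(res$ssError, orc$ssError, tolerance = 1e-10)
  }
})

test_that("Mauchly W and Greenhouse-Geisser epsilon match the mlm machinery", {
  set.seed(19)
  for (i in 1:5) {
    Y <- matrix(rnorm(48), 12, 4)
    Y[, 2] <- Y[, 2] * (1 + i / 3)  # break sphericity progressively
    res <- rmAnovaGG(Y)
    fit <- lm(Y ~ 1)
    idata <- data.frame(cond = factor(seq_len(ncol(Y))))
    mt <- stats::mauchly.test(fit, X = ~1, idata = idata)
    expect_equal(res$mauchlyW, unname(mt$statistic), tolerance = 1e-8)
    expect_equal(res$mauchlyP, mt$p.value, tolerance = 0.02)
    av <- stats::anova(fit, X = ~1, idata = idata, test = "Spherical")
    # uncorrected F agrees with the mlm intra-subject test
    expect_equal(res$F, av["(Intercept)", "F"], tolerance = 1e-8)
  }
})

test_that("RM-ANOVA degenerate and guarded cases behave as specified", {
  Yc <- matrix(0.4, 6, 3)  # all cells equal
  resC <- rmAnovaGG(Yc)
  expect_true(resC$eta2p == 0 || is.nan(resC$F))
  # two levels: sphericity trivially satisfied
  res2 <- rmAnovaGG(matrix(rnorm(20), 10, 2))
  expect_identical(res2$ggEpsilon, 1)
  expect_true(is.na(res2$mauchlyW))
  expect_false(res2$corrected)
  expect_error(rmAnovaGG(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "complete")
  expect_error(rmAnovaGG(matrix(rnorm(4), 2, 2)), "3 participants")
})

test_that("chi-square against control reproduces hand-computed values", {
  r <- chiSquareVsControl(4, 8, 12)
  expect_equal(r$chi2, 6)
  expect_identical(r$df, 1L)
  expect_equal(r$p, pchisq(6, 1, lower.tail = FALSE))
  expect_equal(chiSquareVsControl(6, 9, 12)$chi2, 3)
  expect_equal(chiSquareVsControl(6, 6, 12)$chi2, 0)
  expect_error(chiSquareVsControl(0, 5, 12), "expected cell")
  expect_error(chiSquareVsControl(4, 13, 12), "counts")
})

test_that("McNemar statistic and exact tail follow the discordant counts", {
  a <- c(rep(TRUE, 6), rep(FALSE, 6))
  b <- rep(FALSE, 12)
  r <- mcnemarTest(a, b)  # b = 6, c = 0
  expect_equal(r$chi2, 6)
  expect_equal(r$pExact, 2 * 0.5^6)
  sym <- mcnemarTest(c(rep(TRUE, 3), rep(FALSE, 3)),
                     c(rep(FALSE, 3), rep(TRUE, 3)))  # b = c = 3
  expect_equal(sym$chi2, 0)
  same <- mcnemarTest(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_match(same$note, "no discordance")
  # agrees with the uncorrected base-R test when defined
  base <- stats::mcnemar.test(table(factor(a, c(FALSE, TRUE)),
                                    factor(b, c(FALSE, TRUE))),
                              correct = FALSE)
  expect_equal(r$chi2, unname(base$statistic))
})

test_that("logistic regression handles the null model and recovers truth", {
  set.seed(23)
  y <- rep(c(0, 1), 10)
  rConst <- logisticSymptomRegression(rep(2.5, 20), y)
  expect_equal(rConst$R2McF, 0, tolerance = 1e-8)
  expect_equal(rConst$AUC, 0.5)
  # coverage: true beta = 1, n = 500, estimate within its 95% CI ~95% of runs
  cover <- vapply(1:200, function(s) {
    set.seed(s)
    x <- rnorm(500)
    yy <- rbinom(500, 1, plogis(-0.3 + 1.0 * x))
    f <- logisticSymptomRegression(x, yy)
    se <- sqrt(diag(stats::vcov(f$fit)))[2]
    abs(f$coefficients[1] - 1) < 1.96 * se
  }, logical(1))
  expect_gt(mean(cover), 0.9)
  expect_lt(mean(cover), 0.99)
  expect_error(logisticSymptomRegression(rnorm(20), rep(1, 20)), "single class")
  expect_error(logisticSymptomRegression(rnorm(5), c(0, 1, 0, 1, 0)), "10")
})

test_that("null symptom cohorts reject at close to the nominal 5% rate", {
  pvals <- vapply(1:400, function(s) {
    set.seed(s + 9000)
    x <- rnorm(12)
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) return(NA_real_)
    logisticSymptomRegression(x, y)$pModel
  }, numeric(1))
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_lt(rate, 0.1)
})

test_that("VIF, odds ratios and separation flag behave sensibly", {
  set.seed(29)
  x1 <- rnorm(40)
  x2 <- 0.8 * x1 + 0.6 * rnorm(40)
  y <- rbinom(40, 1, plogis(x1))
  f <- logisticSymptomRegression(cbind(rest = x1, exercise = x2), y)
  expect_equal(unname(f$VIF["rest"]), 1 / (1 - cor(x1, x2)^2), tolerance = 1e-8)
  expect_equal(unname(f$oddsRatios), unname(exp(f$coefficients)))
  xs <- c(rnorm(10, -3), rnorm(10, 3))
  ys <- rep(c(0, 1), each = 10)
  fs <- logisticSymptomRegression(xs, ys)
  expect_true(fs$separated)
})

test_that("correlation matrix reports Pearson r and tie-corrected Kendall tau-B", {
  # x = (1,2,3,4) vs y = (1,3,2,4): 5 concordant, 1 discordant pair -> 2/3
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  cm <- correlationMatrix(X)
  expect_equal(cm$tauB["b", "a"], 2 / 3, tolerance = 1e-10)
  expect_equal(cm$r["a", "a"], 1)
  rev <- cbind(u = 1:6, v = 6:1)
  cmr <- correlationMatrix(rev)
  expect_equal(cmr$tauB["v", "u"], -1)
  expect_lt(cmr$r["v", "u"], 0)
  expect_error(correlationMatrix(cbind(a = rep(1, 5), b = rnorm(5))),
               "zero-variance")
  expect_error(correlationMatrix(X[1:2, ]), "3 participants")
})

test_that("SF ratio and the SpO2~FiO2 regression follow their definitions", {
  expect_equal(sfRatio(100, 1), 100)
  expect_equal(sfRatio(98, 0.209), 468.9, tolerance = 1e-3)
  expect_equal(sfRatio(90, 0.135), 666.7, tolerance = 1e-3)
  expect_error(sfRatio(95, 0), "positive")
  fio2 <- c(13.5, 15.1, 20.9, 17, 14.2)
  spo2 <- 1.4 * fio2 + 70
  f <- spo2Fio2Regression(fio2, spo2)
  expect_equal(f$slope, 1.4, tolerance = 1e-10)
  expect_equal(f$intercept, 70, tolerance = 1e-8)
  expect_equal(f$r, 1)
  expect_equal(f$syx, 0, tolerance = 1e-10)
  two <- spo2Fio2Regression(c(14, 20), c(88, 97))
  expect_equal(two$syx, 0)
  expect_error(spo2Fio2Regression(rep(15, 4), rnorm(4)), "constant")
  # recovery under noise comparable to the instrument spread
  hit <- vapply(1:200, function(s) {
    set.seed(s)
    x <- runif(54, 13, 21)
    y <- 1.416 * x + 68.83 + rnorm(54, sd = 1.7)
    abs(spo2Fio2Regression(x, y)$slope - 1.416) < 0.3
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})
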