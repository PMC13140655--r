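## Cohort-level statistics: one-way repeated-measures ANOVA with Mauchly's
## sphericity test and Greenhouse-Geisser correction, chi-square and McNemar
## symptom comparisons, logistic symptom regressions, correlation matrices,
## and SpO2/FiO2 summaries.

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Decomposes a complete participants x levels matrix into subject, effect
#' and error sums of squares; `F = MS_effect / MS_error` and the effect size
#' is partial eta squared `SS_effect / (SS_effect + SS_error)`. With three or
#' more levels, Mauchly's W tests sphericity on the orthonormal-contrast
#' covariance; when its p-value falls below `ggThreshold` both degrees of
#' freedom are multiplied by the Greenhouse-Geisser epsilon before the F
#' p-value is computed. With two levels sphericity holds trivially
#' (epsilon = 1, Mauchly skipped).
#'
#' @param values numeric matrix, participants in rows, within-subject levels
#'   in columns; complete cases required (no imputation)
#' @param ggThreshold Mauchly p-value below which the correction is applied
#'   (default 0.05)
#' @return a list of class `"AnovaResult"`: `F`, `dfEffect`, `dfError`, `p`,
#'   `eta2p`, `mauchlyW`, `mauchlyP`, `ggEpsilon`, `corrected`, and the sums
#'   of squares `ssEffect`, `ssError`, `ssSubjects`
#' @export
#' @examples
#' y <- matrix(rnorm(36), 12, 3)
#' rmAnovaGG(y)$eta2p
rmAnovaGG <- function(values, ggThreshold = 0.05) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("missing or non-finite cells: repeated-measures ANOVA needs complete cases")
  n <- nrow(values)
  k <- ncol(values)
  if (k < 2L) stop("need at least 2 within-subject levels")
  if (n < 3L) stop("need at least 3 participants")

  grand <- mean(values)
  rowM <- rowMeans(values)
  colM <- colMeans(values)
  ssSubjects <- k * sum((rowM - grand)^2)
  ssEffect <- n * sum((colM - grand)^2)
  ssTotal <- sum((values - grand)^2)
  ssError <- ssTotal - ssSubjects - ssEffect
  dfE <- k - 1
  dfErr <- (n - 1) * (k - 1)
  Fval <- (ssEffect / dfE) / (ssError / dfErr)
  eta2p <- if (ssEffect + ssError > 0) ssEffect / (ssEffect + ssError) else 0

  mauchlyW <- NA_real_
  mauchlyP <- NA_real_
  eps <- 1
  corrected <- FALSE
  if (k >= 3L) {
    S <- stats::cov(values)
    C <- contrOrthonormal(k)
    Tm <- C %*% S %*% t(C)
    lam <- sum(diag(Tm)) / (k - 1)
    detT <- det(Tm)
    mauchlyW <- if (lam > 0) detT / lam^(k - 1) else NA_real_
    eps <- sum(diag(Tm))^2 / ((k - 1) * sum(Tm * Tm))
    eps <- min(1, eps)
    if (is.finite(mauchlyW) && mauchlyW > 0) {
      d <- k - 1
      f <- 1 - (2 * d^2 + d + 2) / (6 * d * (n - 1))
      chi2 <- -(n - 1) * f * log(mauchlyW)
      dfW <- d * (d + 1) / 2 - 1
      mauchlyP <- pchisq(chi2, dfW, lower.tail = FALSE)
      if (!is.na(mauchlyP) && mauchlyP < ggThreshold) corrected <- TRUE
    }
  }
  dfEffUse <- dfE * (if (corrected) eps else 1)
  dfErrUse <- dfErr * (if (corrected) eps else 1)
  p <- pf(Fval, dfEffUse, dfErrUse, lower.tail = FALSE)
  structure(list(F = Fval, dfEffect = dfEffUse, dfError = dfErrUse, p = p,
                 eta2p = eta2p, mauchlyW = mauchlyW, mauchlyP = mauchlyP,
                 ggEpsilon = eps, corrected = corrected,
                 ssEffect = ssEffect, ssError = ssError,
                 ssSubjects = ssSubjects),
            class = "AnovaResult")
}

## (k-1) x k orthonormal contrasts, rows orthogonal to the unit vector
contrOrthonormal <- function(k) {
  C <- stats::contr.helmert(k)      # k x (k-1)
  C <- t(C)
  C / sqrt(rowSums(C^2))
}

#' @export
print.AnovaResult <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g, partial eta^2 = %.3f%s\n",
              x$dfEffect, x$dfError, x$F, x$p, x$eta2p,
              if (x$corrected)
                sprintf(" (Greenhouse-Geisser corrected, eps = %.3f)", x$ggEpsilon)
              else ""))
  invisible(x)
}

#' Chi-square test of symptom occurrence against the control rate
#'
#' Goodness-of-fit of a test condition's (yes, no) counts against the
#' proportions observed under control: `chi2 = sum (O - E)^2 / E` with
#' `E = (n * p0, n * (1 - p0))`, `p0 = controlYes / n`, on 1 degree of
#' freedom.
#'
#' @param controlYes number of participants with the symptom under control
#' @param testYes number with the symptom under the test condition
#' @param n participants per condition
#' @return list of class `"ChiSquareResult"`: `chi2`, `df`, `p`
#' @export
#' @examples
#' chiSquareVsControl(4, 8, 12)  # chi2 = 6, df = 1
chiSquareVsControl <- function(controlYes, testYes, n) {
  if (controlYes < 0 || testYes < 0 || controlYes > n || testYes > n)
    stop("counts must lie in [0, n]")
  if (controlYes == 0 || controlYes == n)
    stop("control rate of 0 or 1 gives a zero expected cell; use an exact test")
  p0 <- controlYes / n
  E <- c(n * p0, n * (1 - p0))
  O <- c(testYes, n - testYes)
  chi2 <- sum((O - E)^2 / E)
  structure(list(chi2 = chi2, df = 1L,
                 p = pchisq(chi2, 1, lower.tail = FALSE)),
            class = "ChiSquareResult")
}

#' McNemar's test for paired symptom flags
#'
#' With discordant counts `b` (yes under A only) and `c` (yes under B only):
#' `chi2 = (b - c)^2 / (b + c)` on 1 df (no continuity correction). When
#' `b + c < 25` an exact two-sided binomial p-value is also reported. With no
#' discordant pairs the result is defined as `chi2 = 0`, `p = 1` and flagged.
#'
#' @param flagsA,flagsB logical vectors of per-participant flags under the
#'   two conditions
#' @return list of class `"ChiSquareResult"` with `chi2`, `df`, `p`, `b`,
#'   `c`, optional `pExact`, and `note`
#' @export
mcnemarTest <- function(flagsA, flagsB) {
  stopifnot(length(flagsA) == length(flagsB))
  b <- sum(flagsA & !flagsB)
  cc <- sum(!flagsA & flagsB)
  if (b + cc == 0L) {
    return(structure(list(chi2 = 0, df = 1L, p = 1, b = b, c = cc,
                          note = "no discordance"),
                     class = "ChiSquareResult"))
  }
  chi2 <- (b - cc)^2 / (b + cc)
  out <- list(chi2 = chi2, df = 1L,
              p = pchisq(chi2, 1, lower.tail = FALSE), b = b, c = cc)
  if (b + cc < 25L)
    out$pExact <- min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
  structure(out, class = "ChiSquareResult")
}

#' @export
print.ChiSquareResult <- function(x, ...) {
  cat(sprintf("chi2(%d df) = %.3f, p = %.4g\n", x$df, x$chi2, x$p))
  if (!is.null(x$pExact)) cat(sprintf("  exact binomial p = %.4g\n", x$pExact))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

## Mann-Whitney AUC of fitted probabilities against a binary outcome
aucFromScores <- function(scores, outcome) {
  pos <- scores[outcome == 1]
  neg <- scores[outcome == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Logistic regression of symptom occurrence
#'
#' Maximum-likelihood binomial (logit) regression of a binary outcome on one
#' or more predictors (e.g. total TE at rest and during exercise), with the
#' assumption-check and fit statistics usually reported alongside it: Wald
#' p-values and odds ratios per predictor, a likelihood-ratio p-value for the
#' whole model, McFadden's R-squared, AIC, BIC, AUC of the fitted
#' probabilities, and variance inflation factors (diagonal of the inverse
#' predictor correlation matrix) for multi-predictor models. Perfect
#' separation is detected and flagged rather than silently diverging.
#'
#' @param predictors numeric vector, matrix or data.frame of predictors
#' @param outcome binary outcome (logical or 0/1), both classes present
#' @param standardize if `TRUE`, predictors are centred and scaled before the
#'   fit (default `FALSE`: raw units, so odds ratios are per unit)
#' @return list of class `"RegressionResult"`: `coefficients`, `oddsRatios`,
#'   `p` (per predictor), `pModel`, `R2McF`, `AIC`, `BIC`, `AUC`, `VIF`,
#'   `separated`, `fit` (the underlying `glm`)
#' @export
logisticSymptomRegression <- function(predictors, outcome,
                                      standardize = FALSE) {
  X <- as.data.frame(predictors)
  if (ncol(X) == 1L && is.null(colnames(predictors)))
    names(X) <- "predictor"
  y <- as.integer(outcome)
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations")
  if (nrow(X) != n) stop("predictors and outcome lengths differ")
  if (length(unique(y)) < 2L)
    stop("outcome has a single class: regression undefined")
  if (standardize) X[] <- lapply(X, function(v) as.numeric(scale(v)))

  dat <- cbind(X, .y = y)
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  nullFit <- glm(.y ~ 1, data = dat, family = binomial())
  ll <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(nullFit))
  cf <- coef(fit)[-1L]
  se <- sqrt(diag(stats::vcov(fit)))[-1L]
  z <- cf / se
  pWald <- 2 * stats::pnorm(-abs(z))
  dev <- nullFit$deviance - fit$deviance
  dfModel <- sum(!is.na(cf))
  pModel <- if (dfModel > 0) pchisq(dev, dfModel, lower.tail = FALSE) else 1
  vif <- rep(NA_real_, ncol(X))
  names(vif) <- names(X)
  keep <- vapply(X, function(v) sd(v) > 0, logical(1))
  if (sum(keep) >= 2L) {
    vif[keep] <- diag(solve(cor(X[keep])))
  } else if (sum(keep) == 1L) vif[keep] <- 1
  separated <- sepWarn || any(abs(cf[!is.na(cf)]) > 15)
  structure(list(coefficients = cf, oddsRatios = exp(cf), p = pWald,
                 pModel = pModel,
                 R2McF = if (ll0 != 0) 1 - ll / ll0 else 0,
                 AIC = AIC(fit), BIC = BIC(fit),
                 AUC = aucFromScores(stats::fitted(fit), y),
                 VIF = vif, separated = separated, fit = fit),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("Logistic regression: model p = %.3f, AUC = %.3f, McFadden R2 = %.3f, AIC = %.2f, BIC = %.2f\n",
              x$pModel, x$AUC, x$R2McF, x$AIC, x$BIC))
  tab <- cbind(OR = x$oddsRatios, p = x$p)
  print(round(tab, 3))
  if (x$separated) cat("  warning: possible perfect separation\n")
  invisible(x)
}

#' Pairwise Pearson and Kendall correlation matrix
#'
#' Pearson's r and tie-corrected Kendall's tau-B (with two-sided p-values)
#' for every pair of columns, laid out as lower-triangular matrices.
#'
#' @param values numeric matrix or data.frame (participants x conditions);
#'   at least 3 complete rows, no zero-variance column
#' @return list of class `"CorrelationMatrix"` with matrices `r`, `tauB`,
#'   `pR`, `pTau`
#' @export
correlationMatrix <- function(values) {
  X <- as.matrix(values)
  if (nrow(X) < 3L) stop("need at least 3 participants")
  if (any(!is.finite(X))) stop("complete cases required")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "),
         " (correlation undefined)")
  k <- ncol(X)
  nm <- colnames(X)
  r <- tau <- pR <- pTau <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      if (i == j) { r[i, j] <- tau[i, j] <- 1; next }
      ctP <- suppressWarnings(cor.test(X[, i], X[, j], method = "pearson"))
      ctK <- suppressWarnings(cor.test(X[, i], X[, j], method = "kendall"))
      r[i, j] <- unname(ctP$estimate); pR[i, j] <- ctP$p.value
      tau[i, j] <- unname(ctK$estimate); pTau[i, j] <- ctK$p.value
    }
  }
  structure(list(r = r, tauB = tau, pR = pR, pTau = pTau),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat("Pearson r (lower triangle):\n"); print(round(x$r, 3))
  cat("Kendall tau-B (lower triangle):\n"); print(round(x$tauB, 3))
  invisible(x)
}

#' SpO2 to FiO2 ratio
#'
#' The spot oxygen-saturation percentage divided by the fractional inspired
#' oxygen: desaturation normalized to the hypoxic stimulus (e.g. 98% at
#' FiO2 0.209 gives ~469).
#'
#' @param spo2 SpO2 in percent (0, 100\]
#' @param fio2 FiO2 as a fraction in (0, 1\]
#' @return SF ratio, `spo2 / fio2`
#' @export
sfRatio <- function(spo2, fio2) {
  if (any(fio2 <= 0)) stop("FiO2 must be positive")
  if (any(spo2 <= 0 | spo2 > 100)) stop("SpO2 must lie in (0, 100]")
  spo2 / fio2
}

#' Linear regression of SpO2 on FiO2
#'
#' Ordinary least squares of SpO2 (%) on FiO2 (%), with Pearson's r and the
#' residual standard deviation Sy.x (denominator n - 2; defined as 0 for an
#' exact two-point fit).
#'
#' @param fio2,spo2 paired measurements in percent; at least 2 points and
#'   non-constant FiO2
#' @return list with `slope`, `intercept`, `r`, `syx`, `n`
#' @export
spo2Fio2Regression <- function(fio2, spo2) {
  stopifnot(length(fio2) == length(spo2))
  n <- length(fio2)
  if (n < 2L) stop("need at least 2 points")
  if (sd(fio2) == 0) stop("FiO2 is constant: regression undefined")
  fit <- lm(spo2 ~ fio2)
  res <- residuals(fit)
  syx <- if (n > 2L) sqrt(sum(res^2) / (n - 2)) else 0
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r = cor(fio2, spo2), syx = syx, n = n)
}
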