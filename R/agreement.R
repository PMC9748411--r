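#' Bland-Altman agreement analysis
#'
#' Bias and limits of agreement (LOA) for paired method-comparison data,
#' with t-based confidence intervals for the bias and each limit
#' (Bland & Altman 1999: SE(limit) = sd * sqrt(1/n + multiplier^2/(2(n-1)))),
#' and a proportional-bias regression of the differences on the pairwise
#' means. Differences are `test - reference`, so a positive bias means the
#' test method reads high.
#'
#' @param reference reference-method values (e.g. CT-derived adipose mass)
#' @param test test-method values (e.g. BIS-predicted adipose mass)
#' @param multiplier LOA multiplier (default 1.96, the 95% convention)
#' @param alpha confidence level for the CIs (default 0.05)
#' @return an object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `bias_ci`, `loa_lower_ci`, `loa_upper_ci`,
#'   `prop_bias` (slope, intercept, slope_ci), `multiplier`, `alpha`
#' @examples
#' ba <- bland_altman(c(1, 2, 3, 4), c(1.1, 2.0, 3.2, 3.9))
#' ba$bias
#' @export
bland_altman <- function(reference, test, multiplier = 1.96, alpha = 0.05) {
  if (length(reference) != length(test))
    stopf("`reference` and `test` must have equal length")
  n <- length(reference)
  if (n < 3) stopf("need at least 3 pairs, got %d", n)
  d <- test - reference
  m <- (test + reference) / 2
  bias <- mean(d)
  sd_diff <- sd(d)
  prop <- if (sd(m) > 0) {
    fit <- lm(d ~ m)
    # identical methods give a zero-residual fit; the warning is expected
    sm <- suppressWarnings(summary(fit))
    se <- sm$coefficients["m", "Std. Error"]
    tq <- qt(1 - alpha / 2, n - 2)
    list(slope = unname(coef(fit)["m"]),
         intercept = unname(coef(fit)[1]),
         slope_ci = unname(coef(fit)["m"]) + c(-1, 1) * tq * se)
  } else {
    list(slope = NA_real_, intercept = NA_real_, slope_ci = c(NA_real_, NA_real_))
  }
  out <- ba_from_summary(n, bias, sd_diff, multiplier, alpha)
  out$prop_bias <- prop
  out
}

#' @rdname bland_altman
#' @param n number of pairs (summary-input mode)
#' @param bias mean difference (summary-input mode)
#' @param sd_diff SD of the differences (summary-input mode)
#' @export
ba_from_summary <- function(n, bias, sd_diff, multiplier = 1.96, alpha = 0.05) {
  assert_scalar_num(n, "n", 3)
  assert_scalar_num(sd_diff, "sd_diff", 0)
  loa_lower <- bias - multiplier * sd_diff
  loa_upper <- bias + multiplier * sd_diff
  tq <- qt(1 - alpha / 2, n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(1 / n + multiplier^2 / (2 * (n - 1)))
  structure(list(
    n = n, bias = bias, sd_diff = sd_diff,
    loa_lower = loa_lower, loa_upper = loa_upper,
    bias_ci = bias + c(-1, 1) * tq * se_bias,
    loa_lower_ci = loa_lower + c(-1, 1) * tq * se_loa,
    loa_upper_ci = loa_upper + c(-1, 1) * tq * se_loa,
    prop_bias = NULL, multiplier = multiplier, alpha = alpha
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias = %.3f [%.3f, %.3f]\n",
              x$n, x$bias, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  LOA: %.3f [%.3f, %.3f] to %.3f [%.3f, %.3f] (bias +/- %.2f SD, SD = %.3f)\n",
              x$loa_lower, x$loa_lower_ci[1], x$loa_lower_ci[2],
              x$loa_upper, x$loa_upper_ci[1], x$loa_upper_ci[2],
              x$multiplier, x$sd_diff))
  if (!is.null(x$prop_bias) && is.finite(x$prop_bias$slope))
    cat(sprintf("  proportional bias slope = %.4f [%.4f, %.4f]\n",
                x$prop_bias$slope, x$prop_bias$slope_ci[1], x$prop_bias$slope_ci[2]))
  invisible(x)
}

#' Power of the Bland-Altman agreement test
#'
#' Probability, under true bias `bias` and SD `sd_diff`, that both estimated
#' limits of agreement fall inside +/- `delta` at significance `alpha`
#' (per-limit two-sided critical value), using the noncentral-t formulation
#' of Lu et al. (2016): with se = sd * sqrt(1/n + z^2/(2(n-1))) and
#' tau_(1,2) = (delta -/+ bias - z*sd)/se, power = P1 + P2 - 1 where
#' P_i = P(T'_{n-1}(tau_i) > t_{1-alpha/2, n-1}).
#'
#' @param delta agreement margin (same units as the differences)
#' @param n number of pairs
#' @param bias,sd_diff assumed mean and SD of the differences
#' @param power unused here; see [max_allowed_difference()]
#' @param alpha significance level (default 0.05)
#' @param multiplier LOA multiplier (default 1.96)
#' @return attained power (can be <= 0 when delta is too small)
#' @export
agreement_power <- function(delta, n, bias, sd_diff, alpha = 0.05,
                            multiplier = 1.96) {
  df <- n - 1
  se <- sd_diff * sqrt(1 / n + multiplier^2 / (2 * (n - 1)))
  if (se == 0) return(as.numeric(delta > abs(bias)))
  tau1 <- (delta - bias - multiplier * sd_diff) / se
  tau2 <- (delta + bias - multiplier * sd_diff) / se
  tc <- qt(1 - alpha / 2, df)
  p1 <- 1 - pt(tc, df, ncp = tau1)
  p2 <- 1 - pt(tc, df, ncp = tau2)
  p1 + p2 - 1
}

#' Maximum allowed difference for method agreement
#'
#' The smallest margin Delta such that the Bland-Altman agreement test (both
#' 95% limits of agreement inside +/- Delta) attains the stated power at the
#' stated alpha for a study of `n` pairs, solved by bisection on the
#' Lu et al. (2016) power formula ([agreement_power()]). Differences smaller
#' than this margin cannot be distinguished from agreement at the design
#' power; published alongside the LOA it states what the sample size can
#' resolve.
#'
#' @param n number of pairs (>= 3)
#' @param bias assumed mean difference
#' @param sd_diff assumed SD of differences (>= 0)
#' @param power target power (default 0.80)
#' @param alpha significance level (default 0.05)
#' @param multiplier LOA multiplier (default 1.96)
#' @param tol bisection tolerance on Delta (default 1e-6)
#' @return Delta, same units as the differences
#' @examples
#' max_allowed_difference(49, 0.06, 0.25) # ~0.73 kg
#' @export
max_allowed_difference <- function(n, bias, sd_diff, power = 0.80,
                                   alpha = 0.05, multiplier = 1.96,
                                   tol = 1e-6) {
  assert_scalar_num(n, "n", 3)
  assert_scalar_num(sd_diff, "sd_diff", 0)
  assert_scalar_num(power, "power", 0, 1, strict_lower = TRUE)
  if (power >= 1) stopf("`power` must be < 1")
  assert_scalar_num(alpha, "alpha", 0, 1, strict_lower = TRUE)
  if (alpha >= 1) stopf("`alpha` must be < 1")
  if (sd_diff == 0) return(abs(bias)) # degenerate limit: LOA collapse onto bias
  lo <- abs(bias)
  hi <- abs(bias) + 100 * sd_diff
  f <- function(d) agreement_power(d, n, bias, sd_diff, alpha, multiplier) - power
  if (f(hi) < 0)
    stopf("convergence error: no Delta below %.3g attains power %.2f", hi, power)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) hi <- mid else lo <- mid
  }
  hi # upper bracket: attains the target power
}

#' Passing-Bablok regression
#'
#' Rank-based structural regression for method comparison (Passing & Bablok
#' 1983). The slope is the shifted median of all pairwise slopes
#' (y_j - y_i)/(x_j - x_i): slopes of exactly -1 are excluded, and the median
#' is offset by K, the number of slopes below -1, making the estimator
#' scale-invariant under swapping axes. The intercept is median(y - slope*x).
#' CIs are the rank-based intervals of the original method.
#'
#' @param x,y paired measurements (n >= 3, x not all identical)
#' @param alpha CI level (default 0.05)
#' @return an object of class `pb_regression`: `slope`, `intercept`,
#'   `slope_ci`, `intercept_ci`, `n_pairs`
#' @examples
#' pb <- passing_bablok(1:10, 2 * (1:10) + 1)
#' pb$slope # 2
#' @export
passing_bablok <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stopf("need at least 3 pairs")
  if (length(unique(x)) == 1L) stopf("all x identical; slope undefined")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- x[ij[, 2]] - x[ij[, 1]]
  dy <- y[ij[, 2]] - y[ij[, 1]]
  keep <- !(dx == 0 & dy == 0)          # identical points: slope undefined 0/0
  dx <- dx[keep]; dy <- dy[keep]
  s <- ifelse(dx == 0, ifelse(dy > 0, Inf, -Inf), dy / dx)
  s <- s[s != -1]                        # slopes of exactly -1 excluded
  if (length(s) == 0) stopf("all pairwise slopes undefined")
  s <- sort(s)
  nS <- length(s)
  K <- sum(s < -1)
  # shifted median with the offset K
  pick <- function(pos) {
    pos <- pmin(pmax(pos, 1), nS)
    s[pos]
  }
  b <- if (nS %% 2 == 1) {
    pick((nS + 1) / 2 + K)
  } else {
    mean(pick(c(nS / 2 + K, nS / 2 + 1 + K)))
  }
  w <- qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- round((nS - w) / 2)
  m2 <- nS - m1 + 1
  slope_ci <- c(pick(m1 + K), pick(m2 + K))
  intercept <- median(y - b * x)
  intercept_ci <- c(median(y - slope_ci[2] * x), median(y - slope_ci[1] * x))
  structure(list(slope = b, intercept = intercept, slope_ci = slope_ci,
                 intercept_ci = intercept_ci, n_pairs = n, alpha = alpha),
            class = "pb_regression")
}

#' @export
print.pb_regression <- function(x, ...) {
  cat(sprintf("Passing-Bablok (n = %d): slope = %.4f [%.4f, %.4f], intercept = %.4f [%.4f, %.4f]\n",
              x$n_pairs, x$slope, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2) with sample
#' (n-1) moments. Penalizes both dispersion and location shifts from the
#' identity line; |ccc| <= |pearson r|.
#'
#' @param x,y paired measurements (n >= 2)
#' @return concordance coefficient in \[-1, 1\]
#' @examples
#' lin_ccc(1:4, 2:5) # 0.7692...
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  if (length(x) < 2) stopf("need at least 2 pairs")
  vx <- var(x); vy <- var(y)
  dmu <- mean(x) - mean(y)
  if (vx == 0 && vy == 0 && dmu == 0)
    stopf("concordance undefined: zero variance in both variables with equal means")
  2 * cov(x, y) / (vx + vy + dmu^2)
}

#' Absolute percentage error summary
#'
#' APE_i = 100 |pred_i - ref_i| / |ref_i|, summarized by the median (default,
#' matching the tabulated "MAPE (median)") or the mean.
#'
#' @param reference reference values (all nonzero)
#' @param predicted predicted values
#' @param center `"median"` (default) or `"mean"`
#' @return summary APE, percent
#' @export
mape <- function(reference, predicted, center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(reference) != length(predicted))
    stopf("`reference` and `predicted` must have equal length")
  zero <- which(reference == 0)
  if (length(zero))
    stopf("zero reference value at index %d: APE undefined", zero[1])
  ape <- 100 * abs(predicted - reference) / abs(reference)
  if (center == "median") median(ape) else mean(ape)
}

#' Full method-agreement report
#'
#' Assembles the complete agreement battery for a pair of methods:
#' Bland-Altman bias and LOA with CIs and proportional-bias slope, the
#' maximum allowed difference at the stated power, Passing-Bablok regression,
#' Lin's concordance, Pearson's r, and the median absolute percentage error.
#'
#' @param reference,test paired measurements (reference method first)
#' @param multiplier LOA multiplier (default 1.96)
#' @param alpha significance level (default 0.05)
#' @param power target power for the maximum allowed difference (default 0.80)
#' @return an object of class `agreement_report`
#' @export
agreement_report <- function(reference, test, multiplier = 1.96, alpha = 0.05,
                             power = 0.80) {
  ba <- bland_altman(reference, test, multiplier, alpha)
  structure(list(
    ba = ba,
    max_allowed_diff = max_allowed_difference(ba$n, ba$bias, ba$sd_diff,
                                              power, alpha, multiplier),
    pb = passing_bablok(reference, test, alpha),
    ccc = lin_ccc(reference, test),
    pearson_r = cor(reference, test),
    mape_median = mape(reference, test, "median"),
    mape_mean = mape(reference, test, "mean"),
    power = power, alpha = alpha, multiplier = multiplier
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$ba)
  cat(sprintf("  max allowed difference = %.3f (power %.2f, alpha %.2f)\n",
              x$max_allowed_diff, x$power, x$alpha))
  cat(sprintf("  CCC = %.4f, Pearson r = %.4f, MAPE(median) = %.2f%%\n",
              x$ccc, x$pearson_r, x$mape_median))
  print(x$pb)
  invisible(x)
}
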