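test_that("Bland-Altman identity and constant-offset cases", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  ba2 <- bland_altman(x, x + 2)
  expect_equal(ba2$bias, 2)
  expect_equal(ba2$sd_diff, 0)
  expect_equal(ba2$prop_bias$slope, 0)
  expect_error(bland_altman(1:4, 1:5), "equal length")
  expect_error(bland_altman(1:2, 2:3), "at least 3")
})

test_that("LOA arithmetic identity and t-based CIs", {
  set.seed(3)
  ref <- rnorm(40, 10, 2)
  tst <- ref + rnorm(40, 0.3, 0.5)
  ba <- bland_altman(ref, tst)
  expect_equal(ba$loa_lower, ba$bias - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_upper, ba$bias + 1.96 * ba$sd_diff)
  d <- tst - ref
  expect_equal(ba$bias_ci,
               mean(d) + c(-1, 1) * qt(0.975, 39) * sd(d) / sqrt(40))
  se_loa <- sd(d) * sqrt(1 / 40 + 1.96^2 / (2 * 39))
  expect_equal(ba$loa_upper_ci,
               ba$loa_upper + c(-1, 1) * qt(0.975, 39) * se_loa)
  # CIs shrink as n grows on a fixed distribution
  widths <- vapply(c(10, 100, 1000), function(n) {
    set.seed(n)
    r <- rnorm(n, 10, 2); t2 <- r + rnorm(n, 0.3, 0.5)
    b <- bland_altman(r, t2)
    diff(b$loa_upper_ci)
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("swapping methods negates bias and mirrors the limits", {
  set.seed(9)
  a <- as.numeric(1:30); b <- a + rnorm(30, 0.2, 0.1) # all pairwise slopes > 0
  f <- bland_altman(a, b); r <- bland_altman(b, a)
  expect_equal(r$bias, -f$bias)
  expect_equal(r$loa_lower, -f$loa_upper)
  expect_equal(r$loa_upper, -f$loa_lower)
  expect_equal(lin_ccc(a, b), lin_ccc(b, a))          # ccc symmetric
  pb_f <- passing_bablok(a, b); pb_r <- passing_bablok(b, a)
  expect_equal(pb_r$slope, 1 / pb_f$slope, tolerance = 1e-10)
})

test_that("maximum allowed difference: degenerate limit and monotonicity", {
  expect_equal(max_allowed_difference(49, 0.5, 0), 0.5)
  deltas <- vapply(seq(0.1, 0.5, by = 0.1), function(s)
    max_allowed_difference(49, 0.06, s), 0)
  expect_true(all(diff(deltas) > 0))
  # more pairs resolve a smaller difference
  expect_lt(max_allowed_difference(200, 0.06, 0.25),
            max_allowed_difference(20, 0.06, 0.25))
  # the returned Delta attains the target power and is minimal
  d <- max_allowed_difference(49, 0.06, 0.25, 0.8, 0.05)
  expect_gte(agreement_power(d + 1e-9, 49, 0.06, 0.25), 0.8)
  expect_lt(agreement_power(d - 1e-3, 49, 0.06, 0.25), 0.8)
})

test_that("Passing-Bablok recovers exact linear relations", {
  x <- 1:10
  pb1 <- passing_bablok(x, x)
  expect_equal(pb1$slope, 1)
  expect_equal(pb1$intercept, 0)
  pb2 <- passing_bablok(x, 2 * x + 1)
  expect_equal(pb2$slope, 2)
  expect_equal(pb2$intercept, 1)
  expect_true(pb2$slope_ci[1] <= 2 && 2 <= pb2$slope_ci[2])
  expect_error(passing_bablok(rep(1, 5), 1:5), "identical")
})

test_that("Passing-Bablok equals the brute-force pairwise-slope oracle", {
  set.seed(14)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    x <- round(runif(n, 0, 10), 1) # rounding creates ties
    y <- round(0.5 + 1.3 * x + rnorm(n, 0, 0.8), 1)
    if (length(unique(x)) == 1) next
    expect_equal(passing_bablok(x, y)$slope, pb_slope_bruteforce(x, y))
  }
  # including negatively correlated data (offset K in action)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    x <- runif(n, 0, 10)
    y <- 5 - 2 * x + rnorm(n, 0, 0.5)
    expect_equal(passing_bablok(x, y)$slope, pb_slope_bruteforce(x, y))
  }
})

test_that("concordance correlation closed form and bound by Pearson", {
  expect_equal(lin_ccc(1:10, 1:10), 1)
  v <- var(1:4)
  expect_equal(lin_ccc(1:4, 2:5), 2 * v / (2 * v + 1)) # 0.769230...
  expect_equal(lin_ccc(1:4, 2:5), 10 / 13)
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(15); y <- rnorm(15, x, runif(1, 0.1, 2))
    expect_lte(abs(lin_ccc(x, y)), abs(cor(x, y)) + 1e-12)
  }
  expect_error(lin_ccc(rep(1, 4), rep(1, 4)), "undefined")
})

test_that("absolute percentage error summaries", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(10, 11), 10)
  expect_equal(mape(c(10, 10, 10), c(11, 12, 13)), 20)        # median of 10,20,30
  expect_equal(mape(c(10, 10, 10), c(11, 12, 13), "mean"), 20)
  expect_error(mape(c(1, 0, 2), c(1, 1, 2)), "index 2")
})

test_that("full agreement report is internally consistent", {
  set.seed(33)
  ref <- rnorm(49, 6.5, 2)
  tst <- ref + rnorm(49, 0.05, 0.25)
  rep <- agreement_report(ref, tst)
  expect_equal(rep$ba$loa_upper - rep$ba$loa_lower, 2 * 1.96 * rep$ba$sd_diff)
  expect_lte(abs(rep$ccc), abs(rep$pearson_r))
  expect_gt(rep$max_allowed_diff, rep$ba$loa_upper) # methods agree here
  expect_gte(rep$mape_mean, 0)
})

test_that("population-level bias of the full generative loop is near zero", {
  p <- cohort_params(noise_sd = 0.19, replicate_cv = 0)
  co <- generate_cohort(1000, p, seed = 31)
  m <- fit_calibration(co, "SCL2/R50")
  pred <- predict_adipose_mass(co$body_mass,
                               impedance_index(co$scl, co$r50),
                               co$time_after_capture, m)
  ref_pct <- 100 * (co$body_mass - co$nonat_ct) / co$body_mass
  pred_pct <- 100 * as.numeric(pred) / co$body_mass
  ba <- bland_altman(ref_pct, pred_pct)
  mc_se <- ba$sd_diff / sqrt(ba$n)
  expect_lt(abs(ba$bias), 2 * mc_se + 1e-6)
})
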