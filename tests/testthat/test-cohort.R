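test_that("empty and invalid cohort requests", {
  co <- generate_cohort(0, seed = 1)
  expect_s3_class(co, "bis_cohort")
  expect_identical(nrow(co), 0L)
  expect_error(generate_cohort(-1), "nonnegative")
})

test_that("seeded determinism: same seed, byte-identical cohorts", {
  a <- generate_cohort(25, seed = 42)
  b <- generate_cohort(25, seed = 42)
  expect_identical(a, b)
  c <- generate_cohort(25, seed = 43)
  expect_false(identical(a, c))
})

test_that("default cohort matches the stated world", {
  co <- generate_cohort(2000, seed = 1)
  # adipose fraction centred on 6.5% of body mass
  expect_lt(abs(mean(co$true_at_fraction) - 0.065), 0.003)
  expect_true(all(co$true_at_fraction >= 0.005 & co$true_at_fraction < 0.25))
  # morphometric invariants
  expect_true(all(co$scl > 0))
  expect_true(all(co$ccl >= co$scl))
  expect_true(all(co$body_mass > 0))
  expect_true(all(co$time_after_capture >= 0))
  # Cole ordering holds for every generated animal
  expect_true(all(co$r0 > co$r50 & co$r50 > co$rinf & co$rinf > 0))
  expect_true(all(co$xc50 >= 0 & co$ri > 0))
})

test_that("impedance inversion makes the generating model recoverable", {
  p <- cohort_params(noise_sd = 0, replicate_cv = 0)
  co <- generate_cohort(60, p, seed = 9)
  idx <- impedance_index(co$scl, co$r50)
  lhs <- p$coefficients[["intercept"]] + p$coefficients[["index"]] * idx +
    p$coefficients[["body_mass"]] * co$body_mass +
    p$coefficients[["time"]] * co$time_after_capture
  expect_equal(lhs, co$nonat_true, tolerance = 1e-10)
})

test_that("infeasible generation parameters fail naming the record", {
  # mean handling time of 40 h forces a nonpositive index for every draw
  bad <- cohort_params(time_mean = 40, time_sd = 0.1, time_range = c(39, 41))
  expect_error(generate_cohort(5, bad, seed = 1), "record.*nonpositive")
})

test_that("cohort CSV round trip preserves values", {
  co <- generate_cohort(8, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  co2 <- read_cohort(f)
  expect_equal(as.data.frame(co2), as.data.frame(co), tolerance = 1e-12)
})

test_that("regenerate_impedance encodes the supplied fraction", {
  p <- cohort_params(noise_sd = 0, replicate_cv = 0)
  co <- generate_cohort(12, p, seed = 4)
  f_new <- pmin(pmax(co$true_at_fraction + 0.01, 0.005), 0.25)
  co2 <- regenerate_impedance(co, f_new, p, seed = 5)
  expect_equal(co2$true_at_fraction, f_new)
  expect_equal(co2$nonat_ct, co2$body_mass * (1 - f_new))
  m <- fit_calibration(co2, "SCL2/R50")
  expect_equal(unname(m$coefficients), unname(p$coefficients),
               tolerance = 1e-8)
})
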