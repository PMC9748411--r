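test_that("condition factor and impedance index match hand arithmetic", {
  expect_equal(fulton_k(10, 50), 0.8)
  expect_equal(fulton_k(0, 40), 0)
  expect_equal(fulton_k(100, 100), 1.0)
  expect_error(fulton_k(10, 0), "scl")
  expect_equal(impedance_index(45, 600), 3.375)
  expect_equal(impedance_index(50, 500), 5.0)
  expect_error(impedance_index(50, 0), "resistance")
})

test_that("index specs parse from several spellings", {
  expect_identical(parse_index_spec("scl2_r50")$label, "SCL2/R50")
  expect_identical(parse_index_spec("CCL2/Rinf")$resistance_col, "rinf")
  expect_error(parse_index_spec("SCL2/R42"), "parse")
  expect_length(index_candidates(), 10)
})

test_that("noise-free cohorts refit the generating coefficients exactly", {
  gen <- c(intercept = -0.03, index = -0.29, body_mass = 1.07, time = -0.11)
  p <- cohort_params(coefficients = gen, noise_sd = 0, replicate_cv = 0)
  co <- generate_cohort(50, p, seed = 11)
  m <- fit_calibration(co, "SCL2/R50")
  expect_lt(max(abs(m$coefficients - gen) / abs(gen)), 1e-8)
  expect_equal(m$r2, 1)
})

test_that("AICc equals the hand formula on a small fixture", {
  set.seed(8)
  co <- generate_cohort(10, seed = 8)
  m <- fit_calibration(co, "SCL2/R50")
  d <- data.frame(y = co$nonat_ct,
                  index = impedance_index(co$scl, co$r50),
                  body_mass = co$body_mass, time = co$time_after_capture)
  fit <- lm(y ~ index + body_mass + time, data = d)
  expect_equal(m$aicc, aicc_hand(fit), tolerance = 1e-10)
})

test_that("rank-deficient designs error naming the collinear column", {
  co <- generate_cohort(20, seed = 2)
  co$time_after_capture <- 2 # constant: collinear with the intercept
  expect_error(fit_calibration(co, "SCL2/R50"), "collinear")
})

test_that("model selection ranks the generating index first", {
  p <- cohort_params(noise_sd = 0.19, replicate_cv = 0)
  wins <- 0L
  set.seed(77)
  for (s in 1:20) {
    co <- generate_cohort(49, p, seed = 100 + s)
    # pure-noise competitor: shuffled resistance breaks the index signal
    co$xc50 <- sample(co$xc50)
    rk <- select_model(co, c("SCL2/R50", "SCL2/Xc50"))
    if (rk$models[[1]]$index_spec == "SCL2/R50") wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("selection is invariant to candidate order and handles one candidate", {
  co <- generate_cohort(40, seed = 5)
  a <- select_model(co, c("SCL2/R50", "CCL2/R0", "SCL2/Rinf"))
  b <- select_model(co, c("SCL2/Rinf", "SCL2/R50", "CCL2/R0"))
  expect_identical(a$table$index_spec, b$table$index_spec)
  single <- select_model(co, "CCL2/R50")
  expect_identical(single$table$index_spec, "CCL2/R50")
  expect_identical(single$table$rank, 1L)
})

test_that("split validation partitions 2/3-1/3 deterministically", {
  co <- generate_cohort(49, seed = 6)
  sv <- split_validate(co, "SCL2/R50", seed = 1)
  expect_length(sv$fit_ids, 33)
  expect_length(sv$test_ids, 16)
  expect_length(intersect(sv$fit_ids, sv$test_ids), 0)
  expect_setequal(c(sv$fit_ids, sv$test_ids), co$id)
  sv2 <- split_validate(co, "SCL2/R50", seed = 1)
  expect_identical(sv$fit_ids, sv2$fit_ids)
  expect_error(split_validate(co[1:5, ], "SCL2/R50", seed = 1), "n >= 9")
})

test_that("printed equations evaluate as published", {
  m2a <- printed_equation("final_scl_r50")
  # mass 10 kg, index 3.375, 1 h after capture
  at <- predict_adipose_mass(10, 3.375, 1, m2a)
  expect_equal(as.numeric(at), 10 - (-0.03 - 0.29 * 3.375 + 1.07 * 10 - 0.11))
  expect_equal(as.numeric(at), 0.41875)
  m1a <- printed_equation("prediction_scl_r50")
  expect_equal(as.numeric(predict_adipose_mass(10, 3.375, 1, m1a)), 0.38)
  expect_error(printed_equation("nope"), "unknown")
  expect_setequal(printed_equation(),
                  c("prediction_scl_r50", "prediction_ccl_r50",
                    "final_scl_r50", "final_ccl_r50"))
})

test_that("adipose + nonadipose prediction conserves body mass; clipping flags", {
  m <- printed_equation("final_scl_r50")
  mass <- c(8, 12, 20); idx <- c(3, 5, 8); tm <- c(0.5, 1, 3)
  at <- predict_adipose_mass(mass, idx, tm, m)
  co <- m$coefficients
  nonat <- co[["intercept"]] + co[["index"]] * idx + co[["body_mass"]] * mass +
    co[["time"]] * tm
  expect_equal(as.numeric(at) + nonat, mass) # before any clipping
  expect_false(any(attr(at, "clipped")))
  # identity model predicts zero fat everywhere
  ident <- m; ident$coefficients <- c(intercept = 0, index = 0,
                                      body_mass = 1, time = 0)
  expect_equal(as.numeric(predict_adipose_mass(c(5, 15), c(2, 4), c(0, 2),
                                               ident)), c(0, 0))
  # negative prediction clips to zero and is flagged
  heavy <- m; heavy$coefficients <- c(intercept = 0, index = 0,
                                      body_mass = 1.2, time = 0)
  atc <- predict_adipose_mass(10, 3, 1, heavy)
  expect_equal(as.numeric(atc), 0)
  expect_true(attr(atc, "clipped"))
})

test_that("Monte-Carlo refits with response noise are unbiased", {
  # scaled-down version of the full acceptance study (see test-acceptance)
  gen <- c(intercept = -0.03, index = -0.29, body_mass = 1.07, time = -0.11)
  p <- cohort_params(coefficients = gen, noise_sd = 0.19, replicate_cv = 0)
  est <- t(vapply(1:40, function(s) {
    co <- generate_cohort(250, p, seed = 5000 + s)
    fit_calibration(co, "SCL2/R50")$coefficients
  }, numeric(4)))
  bias <- colMeans(est) - gen
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) <= 2.5 * mc_se))
})
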