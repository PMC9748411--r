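#' Fulton's condition factor
#'
#' The standard sea-turtle body condition index,
#' K = body mass / SCL^3 * 10,000 with mass in kg and straight carapace
#' length in cm.
#'
#' @param body_mass body mass, kg (>= 0)
#' @param scl straight carapace length, cm (> 0)
#' @return condition factor (dimensionless), vectorized
#' @examples
#' fulton_k(10, 50) # 0.8
#' @export
fulton_k <- function(body_mass, scl) {
  if (any(!is.finite(scl)) || any(scl <= 0)) stopf("`scl` must be > 0")
  if (any(!is.finite(body_mass)) || any(body_mass < 0))
    stopf("`body_mass` must be >= 0")
  body_mass / scl^3 * 1e4
}

#' Impedance index
#'
#' The conductor-geometry predictor of conductive (nonadipose) tissue mass:
#' length squared over resistance, cm^2/ohm.
#'
#' @param length body length (SCL or CCL), cm (> 0)
#' @param resistance resistance, ohm (> 0)
#' @return index value, cm^2/ohm, vectorized
#' @examples
#' impedance_index(45, 600) # 3.375
#' @export
impedance_index <- function(length, resistance) {
  if (any(!is.finite(length)) || any(length <= 0)) stopf("`length` must be > 0")
  if (any(!is.finite(resistance)) || any(resistance <= 0))
    stopf("`resistance` must be > 0 (bad sweep extraction?)")
  length^2 / resistance
}

# Index values for a cohort under a given spec.
cohort_index <- function(cohort, spec) {
  spec <- parse_index_spec(spec)
  impedance_index(cohort[[spec$length_col]], cohort[[spec$resistance_col]])
}

# Gaussian AICc with k counting intercept + slopes + residual variance.
aicc_gaussian <- function(rss, n, n_coef) {
  k <- n_coef + 1
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  aic <- -2 * ll + 2 * k
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the nonadipose-mass calibration model
#'
#' Ordinary least squares of the CT-derived nonadipose tissue mass (kg) on an
#' impedance index, body mass and time after capture (with intercept):
#' `nonat = b0 + b_index * index + b_mass * mass + b_time * time`.
#' Reports R^2, residual-SE RMSE, the overall F statistic and small-sample
#' corrected AIC (AICc, Gaussian likelihood, k counting intercept, slopes and
#' the residual variance).
#'
#' @param cohort a cohort data.frame with impedance columns and the response
#' @param index_spec impedance index, e.g. `"SCL2/R50"`
#' @param response name of the response column (default `"nonat_ct"`, the
#'   CT-derived nonadipose mass)
#' @param include_time include the time-after-capture term (default TRUE)
#' @return an object of class `calibration_model` with elements
#'   `coefficients` (intercept, index, body_mass, time), `r2`, `rmse`,
#'   `f_stat` (+ `f_df`), `aicc`, `n_fit`, `index_spec`
#' @export
fit_calibration <- function(cohort, index_spec, response = "nonat_ct",
                            include_time = TRUE) {
  spec <- parse_index_spec(index_spec)
  if (!response %in% names(cohort)) stopf("response column '%s' missing", response)
  d <- data.frame(y = cohort[[response]],
                  index = cohort_index(cohort, spec),
                  body_mass = cohort$body_mass)
  if (include_time) d$time <- cohort$time_after_capture
  d <- d[complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  p <- ncol(d) # coefficients incl. intercept (y replaced by intercept)
  if (n < 6 || n <= p) stopf("need at least %d complete rows to fit, got %d",
                             max(6, p + 1), n)
  X <- cbind(1, as.matrix(d[-1]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(drop_cols, collapse = ", "))
  }
  fit <- lm(y ~ ., data = d)
  # noise-free cohorts interpolate exactly; the perfect-fit warning is expected
  sm <- suppressWarnings(summary(fit))
  rss <- sum(fit$residuals^2)
  beta <- coef(fit)
  co <- c(intercept = unname(beta[1]),
          index = unname(beta["index"]),
          body_mass = unname(beta["body_mass"]),
          time = if (include_time) unname(beta["time"]) else NA_real_)
  structure(list(
    coefficients = co,
    r2 = unname(sm$r.squared),
    rmse = unname(sm$sigma),
    f_stat = unname(sm$fstatistic[1]),
    f_df = unname(sm$fstatistic[2:3]),
    aicc = aicc_gaussian(rss, n, length(beta)),
    n_fit = n,
    include_time = include_time,
    index_spec = spec$label,
    response = response
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Nonadipose mass calibration [%s], n = %d\n", x$index_spec, x$n_fit))
  co <- x$coefficients
  cat(sprintf("  nonat = %.4g %+.4g*index %+.4g*mass%s\n",
              co[["intercept"]], co[["index"]], co[["body_mass"]],
              if (!is.na(co[["time"]])) sprintf(" %+.4g*time", co[["time"]]) else ""))
  cat(sprintf("  R2 = %.4f, RMSE = %.3f kg, F = %.4g (%d, %d), AICc = %.2f\n",
              x$r2, x$rmse, x$f_stat, x$f_df[1], x$f_df[2], x$aicc))
  invisible(x)
}

#' Rank candidate impedance indices by AICc
#'
#' Fits the calibration for every candidate index (exhaustive search over the
#' small candidate space rather than path-dependent stepwise selection) and
#' ranks ascending by AICc; ties are broken by fewer parameters, then by
#' index label.
#'
#' @param cohort a cohort data.frame
#' @param candidates character vector of index specs
#'   (default [index_candidates()])
#' @param response,include_time passed to [fit_calibration()]
#' @return a list of class `model_ranking`: `models` (ranked list of
#'   `calibration_model`) and `table` (data.frame with index_spec, aicc,
#'   delta_aicc, r2, rmse)
#' @export
select_model <- function(cohort, candidates = index_candidates(),
                         response = "nonat_ct", include_time = TRUE) {
  if (length(candidates) < 1) stopf("need at least one candidate")
  labels <- vapply(candidates, function(s) parse_index_spec(s)$label, "")
  fits <- lapply(labels, function(s) {
    tryCatch(fit_calibration(cohort, s, response, include_time),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  if (!any(ok)) stopf("selection error: all candidate fits failed")
  fits <- fits[ok]; labels <- labels[ok]
  aicc <- vapply(fits, `[[`, 0, "aicc")
  npar <- vapply(fits, function(f) sum(!is.na(f$coefficients)), 0)
  ord <- order(aicc, npar, labels)
  fits <- fits[ord]
  tab <- data.frame(
    rank = seq_along(fits),
    index_spec = vapply(fits, `[[`, "", "index_spec"),
    aicc = vapply(fits, `[[`, 0, "aicc"),
    r2 = vapply(fits, `[[`, 0, "r2"),
    rmse = vapply(fits, `[[`, 0, "rmse"))
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  structure(list(models = fits, table = tab), class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Split-sample validation of a calibration
#'
#' Seeded random partition of the cohort into a fit set of round(2n/3)
#' animals and a test set of the remainder (49 animals split 33/16); the
#' calibration is fit on the fit set and adipose mass predicted for the test
#' set.
#'
#' @param cohort a cohort data.frame (n >= 9)
#' @param index_spec impedance index spec
#' @param seed integer seed controlling the partition
#' @param response,include_time passed to [fit_calibration()]
#' @return an object of class `split_result`: `fit_ids`, `test_ids`, `model`,
#'   and `test_predictions` (data.frame with id, reference and predicted
#'   adipose mass, kg)
#' @export
split_validate <- function(cohort, index_spec, seed = NULL,
                           response = "nonat_ct", include_time = TRUE) {
  n <- nrow(cohort)
  if (n < 9) stopf("need n >= 9 for a 2/3-1/3 split, got %d", n)
  n_fit <- round(2 * n / 3)
  fit_idx <- with_seed(seed, sort(sample.int(n, n_fit)))
  test_idx <- setdiff(seq_len(n), fit_idx)
  model <- fit_calibration(cohort[fit_idx, , drop = FALSE], index_spec,
                           response, include_time)
  test <- cohort[test_idx, , drop = FALSE]
  pred <- predict_adipose_mass(test$body_mass,
                               cohort_index(test, index_spec),
                               test$time_after_capture, model)
  structure(list(
    fit_ids = cohort$id[fit_idx],
    test_ids = cohort$id[test_idx],
    model = model,
    test_predictions = data.frame(
      id = test$id,
      body_mass = test$body_mass,
      at_mass_ref = test$body_mass - test[[response]],
      at_mass_pred = as.numeric(pred),
      clipped = attr(pred, "clipped"))
  ), class = "split_result")
}

#' Predict adipose tissue mass from a calibration model
#'
#' Evaluates the nonadipose-mass equation and returns adipose mass by
#' difference with body mass:
#' `at = mass - (b0 + b_index*index + b_mass*mass + b_time*time)`.
#' Predictions are clipped to `[0, body_mass]`; the logical attribute
#' `"clipped"` flags affected animals.
#'
#' @param body_mass body mass, kg (> 0)
#' @param index impedance index value, cm^2/ohm
#' @param time time after capture, h (>= 0); ignored if the model has no
#'   time term
#' @param model a `calibration_model` (fitted or from [printed_equation()])
#' @return numeric vector of adipose mass, kg, with attribute `clipped`
#' @examples
#' m <- printed_equation("final_scl_r50")
#' predict_adipose_mass(10, 3.375, 1, m) # 0.41875
#' @export
predict_adipose_mass <- function(body_mass, index, time, model) {
  if (!inherits(model, "calibration_model")) stopf("`model` must be a calibration_model")
  if (any(body_mass <= 0)) stopf("`body_mass` must be > 0")
  if (any(time < 0)) stopf("`time` must be >= 0")
  co <- model$coefficients
  nonat <- co[["intercept"]] + co[["index"]] * index +
    co[["body_mass"]] * body_mass +
    (if (is.na(co[["time"]])) 0 else co[["time"]] * time)
  at <- body_mass - nonat
  clipped <- at < 0 | at > body_mass
  at <- pmin(pmax(at, 0), body_mass)
  attr(at, "clipped") <- clipped
  at
}

# ---- printed coefficient fixtures -----------------------------------------

printed_equations_path <- function() {
  system.file("extdata", "printed_equations.csv", package = "turtleBIS",
              mustWork = TRUE)
}

#' Published calibration equations
#'
#' Loads one of the published coefficient sets for the nonadipose-mass
#' equation as a `calibration_model` usable with [predict_adipose_mass()].
#' Available names: `prediction_scl_r50` / `prediction_ccl_r50` (fit on the
#' 2/3 prediction group) and `final_scl_r50` / `final_ccl_r50` (refit on the
#' whole sample; the equations recommended for field use).
#'
#' @param name equation name (see Details); `printed_equation()` with no
#'   arguments lists the available names
#' @return a `calibration_model` with coefficients only (fit statistics NA)
#' @export
printed_equation <- function(name) {
  tab <- read.csv(printed_equations_path(), stringsAsFactors = FALSE)
  if (missing(name)) return(tab$name)
  row <- tab[tab$name == name, ]
  if (nrow(row) != 1L) stopf("unknown equation '%s'; available: %s", name,
                             paste(tab$name, collapse = ", "))
  structure(list(
    coefficients = c(intercept = row$intercept, index = row$index,
                     body_mass = row$body_mass, time = row$time),
    r2 = NA_real_, rmse = NA_real_, f_stat = NA_real_, f_df = c(NA, NA),
    aicc = NA_real_, n_fit = row$n_fit, include_time = TRUE,
    index_spec = row$index_spec, response = "nonat_ct"
  ), class = "calibration_model")
}

#' Published agreement summary table
#'
#' The published per-index agreement summaries (calibration coefficients,
#' fit statistics, Bland-Altman bias/SD/limits in kg and %, maximum allowed
#' difference, concordance and Pearson correlations, median APE) shipped as a
#' plain-text fixture. The %-scale SD/LOA columns are reproduced as printed
#' but are not arithmetically consistent with bias +/- 1.96 SD and are kept
#' for reference only.
#'
#' @return data.frame, one row per index candidate plus the body-mass-only row
#' @export
table1_summaries <- function() {
  read.csv(system.file("extdata", "table1_agreement.csv", package = "turtleBIS",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}
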