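#' Generative settings for a synthetic turtle cohort
#'
#' Defaults describe the calibration cohort the package emulates: juvenile
#' green turtles small enough for a clinical CT gantry, with adipose tissue
#' averaging 6.5% of body mass (SD 3.7%) and impedance measured on average
#' 1.5 h (SD 2.0 h) after capture. Morphometrics are drawn as straight
#' carapace length (SCL, cm), a Fulton condition factor K linking mass to
#' SCL^3, and a curved/straight length ratio; impedance is obtained by
#' inverting the linear nonadipose-mass calibration model (so the generating
#' coefficients are recoverable by refitting) and realizing a Cole model
#' consistent with the implied resistance.
#'
#' @param scl_mean,scl_sd,scl_range straight carapace length distribution, cm;
#'   truncated to `scl_range` (gantry-limited animals)
#' @param condition_mean,condition_sd,condition_range Fulton condition factor
#'   K = mass/SCL^3 * 1e4 used to derive body mass
#' @param ccl_factor_range uniform range of the CCL/SCL ratio
#' @param at_mean,at_sd,at_range adipose tissue fraction of body mass;
#'   a truncated normal whose location is solved so the *truncated* mean
#'   equals `at_mean`
#' @param time_mean,time_sd,time_range time after capture, h
#' @param temp_mean,temp_sd cloacal body temperature, degrees C
#' @param prop_wild proportion of wild (vs captive) animals
#' @param coefficients generating calibration coefficients
#'   (intercept, index, body_mass, time) for nonadipose mass, kg
#' @param index_spec impedance index the coefficients refer to,
#'   e.g. `"SCL2/R50"`
#' @param noise_sd SD (kg) of the noise added to the CT-derived nonadipose
#'   mass response (`nonat_ct`); the scale of the calibration RMSE
#' @param n_replicates,replicate_cv replicate sweeps per animal and their
#'   within-animal coefficient of variation
#' @param fc_range,alpha_range,ri_re_ratio_range uniform ranges for the Cole
#'   model characteristic frequency (kHz), dispersion exponent, and
#'   intracellular/extracellular resistance ratio
#' @return a list of class `cohort_params`
#' @export
cohort_params <- function(scl_mean = 45, scl_sd = 7, scl_range = c(34, 57),
                          condition_mean = 1.40, condition_sd = 0.15,
                          condition_range = c(1.0, 1.8),
                          ccl_factor_range = c(1.04, 1.10),
                          at_mean = 0.065, at_sd = 0.037,
                          at_range = c(0.005, 0.25),
                          time_mean = 1.5, time_sd = 2.0, time_range = c(0, 5),
                          temp_mean = 26, temp_sd = 2,
                          prop_wild = 25 / 49,
                          coefficients = c(intercept = -0.03, index = -0.29,
                                           body_mass = 1.07, time = -0.11),
                          index_spec = "SCL2/R50",
                          noise_sd = 0.19,
                          n_replicates = 10L, replicate_cv = 0.005,
                          fc_range = c(20, 80), alpha_range = c(0.6, 0.75),
                          ri_re_ratio_range = c(1.5, 3)) {
  p <- as.list(environment())
  if (any(c(p$scl_sd, p$condition_sd, p$at_sd, p$time_sd, p$temp_sd,
            p$noise_sd, p$replicate_cv) < 0))
    stopf("distribution SDs must be >= 0")
  if (length(p$coefficients) != 4L) stopf("`coefficients` must have 4 elements")
  names(p$coefficients) <- c("intercept", "index", "body_mass", "time")
  if (p$coefficients[["index"]] == 0) stopf("index coefficient must be nonzero")
  p$index_spec <- parse_index_spec(index_spec)$label
  class(p) <- "cohort_params"
  p
}

# Canonical index spec parsing: "SCL2/R50", "scl2_r50", "CCL2/Rinf", ...
parse_index_spec <- function(spec) {
  if (is.list(spec) && !is.null(spec$label)) return(spec)
  s <- toupper(gsub("[_ ]", "/", as.character(spec)))
  s <- sub("\\^?2", "2", s)
  m <- regmatches(s, regexec("^(SCL|CCL)2/(RINF|R0|R50|RI|XC50)$", s))[[1]]
  if (length(m) != 3L)
    stopf("cannot parse index spec '%s' (expected e.g. 'SCL2/R50')", spec)
  res_map <- c(RINF = "rinf", R0 = "r0", R50 = "r50", RI = "ri", XC50 = "xc50")
  res_lab <- c(RINF = "Rinf", R0 = "R0", R50 = "R50", RI = "Ri", XC50 = "Xc50")
  list(length_basis = m[2], resistance_basis = res_lab[[m[3]]],
       length_col = tolower(m[2]), resistance_col = res_map[[m[3]]],
       label = paste0(m[2], "2/", res_lab[[m[3]]]))
}

#' All candidate impedance index specifications
#'
#' The ten length-squared-over-resistance indices considered for calibration:
#' SCL or CCL as the length basis crossed with Rinf, R0, R50, Ri, Xc50.
#' @return character vector of canonical labels
#' @export
index_candidates <- function() {
  as.vector(outer(c("SCL2/", "CCL2/"), c("Rinf", "R0", "R50", "Ri", "Xc50"),
                  paste0))
}

# Draw morphometric fields for k animals (impedance handled separately).
draw_morphometrics <- function(k, p, at_mu) {
  scl <- rtnorm(k, p$scl_mean, p$scl_sd, p$scl_range[1], p$scl_range[2])
  kf <- rtnorm(k, p$condition_mean, p$condition_sd,
               p$condition_range[1], p$condition_range[2])
  data.frame(
    scl = scl,
    ccl = scl * runif(k, p$ccl_factor_range[1], p$ccl_factor_range[2]),
    body_mass = kf * scl^3 / 1e4,
    time_after_capture = rtnorm(k, p$time_mean, p$time_sd,
                                p$time_range[1], p$time_range[2]),
    body_temp = rnorm(k, p$temp_mean, p$temp_sd),
    source = ifelse(runif(k) < p$prop_wild, "wild", "captive"),
    true_at_fraction = rtnorm(k, at_mu, p$at_sd, p$at_range[1], p$at_range[2])
  )
}

# Impedance index implied by the generating model at nonadipose mass `basis`.
invert_index <- function(basis, body_mass, time, beta) {
  (basis - beta[["intercept"]] - beta[["body_mass"]] * body_mass -
     beta[["time"]] * time) / beta[["index"]]
}

# Realize Cole parameters and replicate-averaged measurements for given
# target resistance values at the configured basis. Vectorized over animals.
realize_impedance <- function(target_r, resistance_col, p) {
  k <- length(target_r)
  fc <- runif(k, p$fc_range[1], p$fc_range[2])
  alpha <- runif(k, p$alpha_range[1], p$alpha_range[2])
  ratio <- runif(k, p$ri_re_ratio_range[1], p$ri_re_ratio_range[2])
  # unit Cole model (re = 1): values of each extractable parameter
  rinf_u <- ratio / (1 + ratio)
  z50 <- rinf_u + (1 - rinf_u) / (1 + (1i * 50 / fc)^alpha)
  unit <- list(r0 = rep(1, k), rinf = rinf_u, r50 = Re(z50), ri = ratio,
               xc50 = -Im(z50))
  scale <- target_r / unit[[resistance_col]]
  if (any(scale <= 0)) stopf("internal: nonpositive Cole scale")
  out <- data.frame(r0 = scale, rinf = scale * rinf_u, r50 = scale * Re(z50),
                    ri = scale * ratio, xc50 = scale * -Im(z50))
  if (p$replicate_cv > 0 && p$n_replicates >= 1L) {
    for (colnm in names(out)) {
      jit <- matrix(rnorm(k * p$n_replicates, 0, p$replicate_cv),
                    nrow = k)
      out[[colnm]] <- out[[colnm]] * rowMeans(1 + jit)
    }
  }
  out$xc50 <- pmax(out$xc50, 0)
  out$pha50 <- atan2(out$xc50, out$r50) * 180 / pi
  out$n_replicates <- as.integer(p$n_replicates)
  out
}

#' Generate a synthetic calibration cohort
#'
#' Draws `n` turtle records (morphometrics, handling time, true adipose
#' fraction) and BIS measurements consistent with them. The impedance index
#' is obtained by inverting the generating calibration model at the animal's
#' true nonadipose mass, and a Cole model is realized around the implied
#' resistance, so that refitting the calibration on the cohort recovers the
#' generating coefficients. Measurement noise of SD `noise_sd` (kg) is added
#' to the CT-side nonadipose response column `nonat_ct`, the regression
#' response used downstream; with `noise_sd = 0` and `replicate_cv = 0` the
#' cohort is exactly collinear with the generating model.
#'
#' Draws whose (mass, fraction, time) combination implies a nonpositive
#' impedance index or resistance are redrawn (up to 100 attempts per record);
#' if the configured parameter ranges make a positive resistance impossible,
#' generation fails naming the record.
#'
#' @param n number of animals (>= 0)
#' @param params a [cohort_params()] object
#' @param seed integer seed; identical seeds give identical cohorts
#' @return a data.frame of class `bis_cohort`, one row per animal, with
#'   morphometrics, `true_at_fraction`, the noisy CT nonadipose response
#'   `nonat_ct`, and impedance columns `r0, rinf, r50, ri, xc50, pha50`.
#' @examples
#' co <- generate_cohort(10, seed = 1)
#' mean(co$true_at_fraction)
#' @export
generate_cohort <- function(n, params = cohort_params(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stopf("`n` must be a nonnegative integer")
  n <- as.integer(n)
  if (!inherits(params, "cohort_params")) stopf("`params` must be cohort_params()")
  spec <- parse_index_spec(params$index_spec)
  at_mu <- tnorm_calibrate_mean(params$at_mean, params$at_sd,
                                params$at_range[1], params$at_range[2])
  cols <- c("id", "source", "scl", "ccl", "body_mass", "time_after_capture",
            "body_temp", "true_at_fraction", "nonat_true", "nonat_ct",
            "r0", "rinf", "r50", "ri", "xc50", "pha50", "n_replicates")
  if (n == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(out) <- cols
    out$id <- character(0); out$source <- character(0)
    class(out) <- c("bis_cohort", "data.frame")
    return(out)
  }
  with_seed(seed, {
    df <- draw_morphometrics(n, params, at_mu)
    nonat <- df$body_mass * (1 - df$true_at_fraction)
    idx <- invert_index(nonat, df$body_mass, df$time_after_capture,
                        params$coefficients)
    bad <- !(idx > 0)
    attempts <- 0L
    while (any(bad) && attempts < 100L) {
      attempts <- attempts + 1L
      redraw <- draw_morphometrics(sum(bad), params, at_mu)
      df[bad, names(redraw)] <- redraw
      nonat <- df$body_mass * (1 - df$true_at_fraction)
      idx <- invert_index(nonat, df$body_mass, df$time_after_capture,
                          params$coefficients)
      bad <- !(idx > 0)
    }
    if (any(bad))
      stopf("generation error: record %d implies nonpositive resistance under the configured parameters",
            which(bad)[1])
    target_r <- df[[spec$length_col]]^2 / idx
    imp <- realize_impedance(target_r, spec$resistance_col, params)
    out <- cbind(
      data.frame(id = sprintf("T%04d", seq_len(n)), source = df$source),
      df[c("scl", "ccl", "body_mass", "time_after_capture", "body_temp",
           "true_at_fraction")],
      data.frame(nonat_true = nonat,
                 nonat_ct = nonat + rnorm(n, 0, params$noise_sd)),
      imp)
    class(out) <- c("bis_cohort", "data.frame")
    out
  })
}

#' Regenerate impedance from a given adipose fraction
#'
#' Replaces a cohort's impedance columns with measurements inverted from
#' `at_fraction` (typically the phantom's voxelized truth, so that the BIS and
#' CT stages of a pipeline describe the same body). Noise of SD
#' `params$noise_sd` is placed on the BIS side: the index is inverted at
#' `body_mass * (1 - at_fraction) + eps`, emulating impedance measurement
#' error against a clean CT reference.
#'
#' @param cohort a `bis_cohort` data.frame
#' @param at_fraction per-animal adipose fraction to encode (defaults to the
#'   cohort's `true_at_fraction`)
#' @param params a [cohort_params()] object (noise, Cole settings, index spec)
#' @param seed integer seed
#' @return the cohort with updated impedance columns, `true_at_fraction`,
#'   and `nonat_true`/`nonat_ct` set to the (clean) nonadipose mass
#' @export
regenerate_impedance <- function(cohort, at_fraction = cohort$true_at_fraction,
                                 params = cohort_params(), seed = NULL) {
  stopifnot(inherits(cohort, "data.frame"))
  if (length(at_fraction) != nrow(cohort))
    stopf("`at_fraction` must have one value per animal")
  spec <- parse_index_spec(params$index_spec)
  with_seed(seed, {
    nonat <- cohort$body_mass * (1 - at_fraction)
    basis <- nonat + rnorm(nrow(cohort), 0, params$noise_sd)
    idx <- invert_index(basis, cohort$body_mass, cohort$time_after_capture,
                        params$coefficients)
    bad <- !(idx > 0)
    attempts <- 0L
    while (any(bad) && attempts < 100L) {
      attempts <- attempts + 1L
      basis[bad] <- nonat[bad] + rnorm(sum(bad), 0, params$noise_sd)
      idx <- invert_index(basis, cohort$body_mass, cohort$time_after_capture,
                          params$coefficients)
      bad <- !(idx > 0)
    }
    if (any(bad))
      stopf("generation error: record %s implies nonpositive resistance",
            cohort$id[which(bad)[1]])
    target_r <- cohort[[spec$length_col]]^2 / idx
    imp <- realize_impedance(target_r, spec$resistance_col, params)
    cohort[names(imp)] <- imp
    cohort$true_at_fraction <- at_fraction
    cohort$nonat_true <- nonat
    cohort$nonat_ct <- nonat
    cohort
  })
}

#' Write / read a cohort as CSV
#'
#' Plain-CSV round trip of a cohort table. Column names are the documented
#' contract: `id, source, scl, ccl, body_mass, time_after_capture, body_temp,
#' true_at_fraction, nonat_true, nonat_ct, r0, rinf, r50, ri, xc50, pha50,
#' n_replicates`.
#'
#' @param cohort a `bis_cohort` data.frame
#' @param path file path
#' @return `read_cohort` returns a `bis_cohort` data.frame
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("bis_cohort", "data.frame")
  out
}
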