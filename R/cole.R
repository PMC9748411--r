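#' Cole model parameters
#'
#' Container for the four parameters of the Cole dispersion model of tissue
#' impedance: extracellular resistance `re` (ohm), intracellular resistance
#' `ri` (ohm), characteristic frequency `fc` (kHz) and the dimensionless
#' dispersion exponent `alpha` in (0, 1]. The model ties together the
#' quantities a multi-frequency impedance device extracts from a sweep:
#' resistance at zero frequency R0 = re, resistance at infinite frequency
#' Rinf = re*ri/(re + ri), and the 50 kHz resistance/reactance in between.
#'
#' @param re extracellular resistance, ohm (> 0)
#' @param ri intracellular resistance, ohm (> 0)
#' @param fc characteristic frequency, kHz (in \[3, 1000\])
#' @param alpha dispersion exponent, in (0, 1]
#' @return an object of class `cole_params`
#' @examples
#' cole_parameters(600, 1200, 40, 0.7)
#' @export
cole_parameters <- function(re, ri, fc = 50, alpha = 0.7) {
  assert_scalar_num(re, "re", 0, strict_lower = TRUE)
  assert_scalar_num(ri, "ri", 0, strict_lower = TRUE)
  assert_scalar_num(fc, "fc", 3, 1000)
  assert_scalar_num(alpha, "alpha", 0, 1, strict_lower = TRUE)
  structure(list(re = re, ri = ri, fc = fc, alpha = alpha),
            class = "cole_params")
}

#' @export
print.cole_params <- function(x, ...) {
  cat(sprintf("Cole model: Re = %.4g ohm, Ri = %.4g ohm, fc = %.4g kHz, alpha = %.3f\n",
              x$re, x$ri, x$fc, x$alpha))
  cat(sprintf("  R0 = %.4g ohm, Rinf = %.4g ohm\n",
              x$re, x$re * x$ri / (x$re + x$ri)))
  invisible(x)
}

#' Resistance and reactance of a Cole model at given frequencies
#'
#' Evaluates Z(f) = Rinf + (R0 - Rinf) / (1 + (i f / fc)^alpha) and returns
#' the resistance (real part) and reactance magnitude (-Im Z, >= 0), together
#' with the limiting resistances. Resistance decreases monotonically with
#' frequency from R0 to Rinf.
#'
#' @param p a [cole_parameters()] object
#' @param freq_khz frequency or vector of frequencies, kHz (> 0)
#' @return list with `resistance`, `reactance` (vectors along `freq_khz`),
#'   and scalars `r0`, `rinf`, `ri`
#' @examples
#' p <- cole_parameters(600, 1200, 40, 0.7)
#' cole_resistances(p, c(3, 50, 1000))
#' @export
cole_resistances <- function(p, freq_khz) {
  if (!inherits(p, "cole_params")) stopf("`p` must be a cole_params object")
  if (!is.numeric(freq_khz) || any(!is.finite(freq_khz)) || any(freq_khz <= 0))
    stopf("`freq_khz` must be positive and finite")
  r0 <- p$re
  rinf <- p$re * p$ri / (p$re + p$ri)
  z <- rinf + (r0 - rinf) / (1 + (1i * freq_khz / p$fc)^p$alpha)
  list(resistance = Re(z), reactance = -Im(z), r0 = r0, rinf = rinf, ri = p$ri)
}

#' Summarize a Cole model as a BIS measurement record
#'
#' Produces the parameter set a bioimpedance spectroscopy device reports from
#' a sweep: R0, Rinf, R50, Ri, Xc50 and the 50 kHz phase angle (degrees).
#' When `n_replicates > 1` the sweep is re-measured with multiplicative
#' replicate noise of coefficient of variation `replicate_cv` and the
#' replicate means are reported, mirroring repeated in-field measurements
#' taken without moving the electrodes.
#'
#' @param p a [cole_parameters()] object
#' @param n_replicates number of replicate sweeps averaged (default 10)
#' @param replicate_cv within-animal replicate coefficient of variation
#'   (default 0: replicates identical)
#' @return one-row data.frame with columns `r0, rinf, r50, ri, xc50, pha50,
#'   n_replicates`
#' @export
impedance_from_cole <- function(p, n_replicates = 10L, replicate_cv = 0) {
  if (n_replicates < 1L) stopf("`n_replicates` must be >= 1")
  base <- cole_resistances(p, 50)
  vals <- c(r0 = base$r0, rinf = base$rinf, r50 = base$resistance,
            ri = base$ri, xc50 = base$reactance)
  if (replicate_cv > 0 && n_replicates >= 1L) {
    reps <- vapply(seq_len(n_replicates), function(i) {
      vals * (1 + rnorm(length(vals), 0, replicate_cv))
    }, numeric(length(vals)))
    vals <- rowMeans(reps)
  }
  if (vals[["xc50"]] < 0) vals[["xc50"]] <- 0
  data.frame(r0 = vals[["r0"]], rinf = vals[["rinf"]], r50 = vals[["r50"]],
             ri = vals[["ri"]], xc50 = vals[["xc50"]],
             pha50 = atan2(vals[["xc50"]], vals[["r50"]]) * 180 / pi,
             n_replicates = as.integer(n_replicates))
}

# Validate the ordering invariants of a measurement block (r0 > rinf > 0,
# r0 >= r50 >= rinf, ri > 0, xc50 >= 0). Returns TRUE or a message.
check_impedance <- function(m) {
  ok <- m$r0 > m$rinf & m$rinf > 0 & m$ri > 0 &
    m$r0 >= m$r50 & m$r50 >= m$rinf & m$xc50 >= 0
  all(ok)
}
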