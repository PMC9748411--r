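#' @useDynLib turtleBIS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats density lm coef qt pt qnorm pnorm rnorm runif median
#'   var cov cor sd uniroot predict setNames complete.cases
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Truncated normal draws by inverse-CDF; exact for the modest truncations used
# here (no rejection loop, so draw counts stay seed-stable).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate truncated normal outside bounds")
    return(rep(mean, n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

tnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean + sd * (dnorm(a) - dnorm(b)) / z
}

#' @importFrom stats dnorm
# Location of a normal such that, truncated to [lower, upper], its mean equals
# `target`. Used so the generated adipose fractions average to the stated value.
tnorm_calibrate_mean <- function(target, sd, lower, upper) {
  if (sd == 0) return(target)
  f <- function(mu) tnorm_mean(mu, sd, lower, upper) - target
  uniroot(f, c(target - 4 * sd, target + 4 * sd), tol = 1e-10)$root
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a finite numeric scalar", name)
  if (strict_lower && x <= lower) stopf("`%s` must be > %s", name, lower)
  if (!strict_lower && x < lower) stopf("`%s` must be >= %s", name, lower)
  if (x > upper) stopf("`%s` must be <= %s", name, upper)
  invisible(x)
}
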