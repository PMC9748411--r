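# Independent oracles used across tests. Kept deliberately naive (scalar
# loops, closed forms) so they share no code with the implementation.

# Passing-Bablok slope by double-loop enumeration with the original
# exclusion/offset rules.
pb_slope_bruteforce <- function(x, y) {
  n <- length(x)
  slopes <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- if (dx == 0) (if (dy > 0) Inf else -Inf) else dy / dx
      if (s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  nS <- length(slopes)
  K <- sum(slopes < -1)
  clamp <- function(p) min(max(p, 1), nS)
  if (nS %% 2 == 1) {
    slopes[clamp((nS + 1) / 2 + K)]
  } else {
    (slopes[clamp(nS / 2 + K)] + slopes[clamp(nS / 2 + 1 + K)]) / 2
  }
}

# AICc by the hand formula AIC + 2k(k+1)/(n-k-1) from an lm fit.
aicc_hand <- function(fit) {
  n <- length(fit$residuals)
  k <- length(coef(fit)) + 1
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

# A tiny deterministic paired dataset generator.
make_pairs <- function(n, seed, slope = 1, intercept = 0, noise = 0.1) {
  set.seed(seed)
  x <- sort(runif(n, 1, 10))
  y <- intercept + slope * x + rnorm(n, 0, noise)
  list(x = x, y = y)
}

small_phantom <- function(seed, target = 0.065,
                          fp = c("A", "B", "C", "D", "table"),
                          grid = c(48L, 40L, 40L)) {
  build_phantom(phantom_spec(grid_shape = grid, target_at_fraction = target,
                             fp_plan = fp, seed = seed))
}

adipose_range <- function() {
  r <- default_hu_model()$adipose$range
  hu_range(r[1], r[2])
}
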