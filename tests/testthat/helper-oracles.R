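# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: direct (non-log-space) Bayesian recursion, and
# density-based Lloyd-Max iteration.

# Direct implementation of the two-state recursion: hazard propagation,
# Gaussian likelihood weighting, posterior mean estimate.
brute_force_observer <- function(x, config) {
  h <- config$hazard
  if (config$mode == "mean") {
    muL <- config$theta_low; muH <- config$theta_high
    sdL <- config$fixed_sigma; sdH <- config$fixed_sigma
  } else {
    muL <- config$fixed_mu; muH <- config$fixed_mu
    sdL <- config$theta_low; sdH <- config$theta_high
  }
  p <- 0.5
  p_trace <- numeric(length(x))
  for (t in seq_along(x)) {
    prior <- p * (1 - h) + (1 - p) * h
    num <- dnorm(x[t], muL, sdL) * prior
    den <- num + dnorm(x[t], muH, sdH) * (1 - prior)
    p <- num / den
    p_trace[t] <- p
  }
  p_trace
}

# Density-based Lloyd-Max for a standard Gaussian: boundaries are level
# midpoints, levels are conditional means of the truncated density.
lloyd_max_gaussian <- function(n_levels, iters = 500) {
  levels <- seq(-1, 1, length.out = n_levels)
  for (i in seq_len(iters)) {
    b <- c(-Inf, (levels[-1] + levels[-n_levels]) / 2, Inf)
    lo <- b[-(n_levels + 1)]; hi <- b[-1]
    levels <- (dnorm(lo) - dnorm(hi)) / (pnorm(hi) - pnorm(lo))
  }
  levels
}

# standard study-condition environments
mean_env <- function(...) env_config("mean", ...)
var_env <- function(...) env_config("variance", ...)
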