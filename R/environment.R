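#' Two-state switching Gaussian environment
#'
#' Defines a nonstationary environment in which a latent state \eqn{\theta_t}
#' switches between two fixed values \eqn{\theta_L} and \eqn{\theta_H} with a
#' constant per-timestep hazard rate \eqn{h}. The state parametrizes either
#' the mean (\code{mode = "mean"}) or the standard deviation
#' (\code{mode = "variance"}) of a Gaussian stimulus distribution
#' \eqn{p(x_t | \theta_t)}.
#'
#' Defaults reproduce the standard study conditions: mean-switching
#' \eqn{(\theta_L, \theta_H, \sigma) = (-1, 1, 1)}; variance-switching
#' \eqn{(\theta_L, \theta_H, \mu) = (1, 2, 0)}; hazard \eqn{h = 0.01}.
#'
#' @param mode "mean" or "variance": which Gaussian parameter switches.
#' @param theta_low,theta_high the two state values; in variance mode both
#'   must be positive (they are standard deviations).
#' @param hazard per-timestep switch probability, in \[0, 1\].
#' @param fixed_sigma fixed stimulus standard deviation (mean mode only).
#' @param fixed_mu fixed stimulus mean (variance mode only).
#' @return An object of class \code{"env_config"}.
#' @examples
#' env_config("mean")
#' env_config("variance", hazard = 0.02)
#' @export
env_config <- function(mode = c("mean", "variance"),
                       theta_low = NULL, theta_high = NULL,
                       hazard = 0.01,
                       fixed_sigma = 1, fixed_mu = 0) {
  mode <- match.arg(mode)
  if (is.null(theta_low))  theta_low  <- if (mode == "mean") -1 else 1
  if (is.null(theta_high)) theta_high <- if (mode == "mean")  1 else 2
  stopifnot(is.numeric(theta_low), is.numeric(theta_high),
            length(theta_low) == 1L, length(theta_high) == 1L,
            is.numeric(hazard), length(hazard) == 1L)
  if (hazard < 0 || hazard > 1)
    stop("'hazard' must lie in [0, 1]", call. = FALSE)
  if (theta_low == theta_high)
    stop("'theta_low' and 'theta_high' must differ", call. = FALSE)
  if (mode == "variance" && (theta_low <= 0 || theta_high <= 0))
    stop("in variance mode both states are standard deviations and must be > 0",
         call. = FALSE)
  if (mode == "mean" && (!is.numeric(fixed_sigma) || fixed_sigma < 0))
    stop("'fixed_sigma' must be a nonnegative number", call. = FALSE)
  structure(
    list(mode = mode, theta_low = theta_low, theta_high = theta_high,
         hazard = hazard,
         fixed_sigma = if (mode == "mean") fixed_sigma else NA_real_,
         fixed_mu = if (mode == "variance") fixed_mu else NA_real_),
    class = "env_config")
}

#' @export
print.env_config <- function(x, ...) {
  cat(sprintf("Two-state %s-switching environment\n", x$mode))
  cat(sprintf("  states: theta_L = %g, theta_H = %g;  hazard h = %g\n",
              x$theta_low, x$theta_high, x$hazard))
  if (x$mode == "mean")
    cat(sprintf("  stimulus: x ~ N(theta, sigma^2), sigma = %g\n", x$fixed_sigma))
  else
    cat(sprintf("  stimulus: x ~ N(mu, theta^2), mu = %g\n", x$fixed_mu))
  invisible(x)
}

# (mu, sigma) of the stimulus distribution for a given state value
state_params <- function(theta, config) {
  if (config$mode == "mean")
    list(mu = theta, sigma = config$fixed_sigma)
  else
    list(mu = config$fixed_mu, sigma = theta)
}

#' Advance the environmental state by one timestep
#'
#' With probability \code{1 - h} the state is retained, otherwise it switches
#' to the other value: \eqn{\theta_t = z_t \theta_{t-1} +
#' (1 - z_t)(\theta_L + \theta_H - \theta_{t-1})} with
#' \eqn{z_t \sim \mathrm{Bernoulli}(1 - h)}.
#'
#' @param theta_prev current state, one of \code{theta_low}/\code{theta_high}.
#' @param config an \code{\link{env_config}}.
#' @param seed optional integer seed (NULL uses the current RNG stream).
#' @return The next state value.
#' @export
step_state <- function(theta_prev, config, seed = NULL) {
  if (!theta_prev %in% c(config$theta_low, config$theta_high))
    stop("'theta_prev' must be one of the two state values", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (stats::runif(1) < config$hazard)
    config$theta_low + config$theta_high - theta_prev
  else
    theta_prev
}

#' Simulate a random state sequence
#'
#' @param n number of timesteps.
#' @param config an \code{\link{env_config}}.
#' @param theta0 initial state (default \code{theta_low}).
#' @inheritParams step_state
#' @return Numeric vector of states of length \code{n}.
#' @export
simulate_states <- function(n, config, theta0 = config$theta_low, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- stats::runif(n) < config$hazard  # switch indicators
  # cumulated parity of switches decides which state we are in
  flip <- cumsum(z) %% 2 == 1
  other <- config$theta_low + config$theta_high - theta0
  ifelse(flip, other, theta0)
}

#' Deterministic probe state sequence
#'
#' The probe environment switches between the two states every \code{1/h}
#' timesteps: each cycle consists of \code{1/h} samples in the low state
#' followed by \code{1/h} samples in the high state (200 samples per cycle at
#' the default h = 0.01). All trial-averaged results use this sequence, which
#' is deterministic and seed-independent. \code{1/h} must be an integer so
#' that cycles align exactly across trials.
#'
#' @param config an \code{\link{env_config}}.
#' @param n_cycles number of low/high cycles.
#' @return Numeric vector of length \code{n_cycles * 2/h} with attribute
#'   \code{"phase_length"} = 1/h.
#' @export
probe_sequence <- function(config, n_cycles) {
  stopifnot(n_cycles >= 0, n_cycles == round(n_cycles))
  if (config$hazard <= 0)
    stop("probe sequence requires hazard > 0", call. = FALSE)
  len <- 1 / config$hazard
  if (abs(len - round(len)) > 1e-9)
    stop("probe sequence requires 1/hazard to be an integer", call. = FALSE)
  len <- as.integer(round(len))
  states <- rep(rep(c(config$theta_low, config$theta_high), each = len),
                times = n_cycles)
  structure(states, phase_length = len)
}

#' Draw stimuli from the state-conditional Gaussian
#'
#' \eqn{x \sim N(\theta, \sigma^2)} in mean mode,
#' \eqn{x \sim N(\mu, \theta^2)} in variance mode. Vectorized over
#' \code{theta}.
#'
#' @param theta state value(s), recycled against \code{n}.
#' @param config an \code{\link{env_config}}.
#' @param n number of draws (default \code{length(theta)}).
#' @param seed optional integer seed.
#' @return Numeric vector of stimuli.
#' @export
sample_stimulus <- function(theta, config, n = length(theta), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (config$mode == "mean")
    stats::rnorm(n, mean = theta, sd = config$fixed_sigma)
  else
    stats::rnorm(n, mean = config$fixed_mu, sd = theta)
}
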