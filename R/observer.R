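#' Propagate the belief through the environment dynamics
#'
#' Applies the hazard-rate transition to the probability of the low state:
#' \eqn{P^L_{t+1} = P^L_t (1 - h) + (1 - P^L_t) h}.
#'
#' @param p_low probability that the environment is in the low state.
#' @param hazard per-timestep switch probability.
#' @return The propagated probability. Vectorized over \code{p_low}.
#' @export
hazard_propagate <- function(p_low, hazard) {
  p_low * (1 - hazard) + (1 - p_low) * hazard
}

# log densities of x under the low/high stimulus distributions
state_loglik <- function(x, config) {
  pl <- state_params(config$theta_low, config)
  ph <- state_params(config$theta_high, config)
  list(low  = stats::dnorm(x, pl$mu, pl$sigma, log = TRUE),
       high = stats::dnorm(x, ph$mu, ph$sigma, log = TRUE))
}

#' Bayesian likelihood update of the belief
#'
#' Combines a hazard-propagated prior \code{p_prior} with the likelihood of a
#' stimulus under the two state-conditional Gaussians, in log space:
#' \eqn{P^L_t \propto N(x; \mu_L, \sigma_L^2)\, p_{prior}}, normalized against
#' the high-state term. If both likelihoods underflow to \code{-Inf} the
#' prior is returned unchanged with a warning.
#'
#' @param p_prior hazard-propagated prior probability of the low state.
#' @param x stimulus value(s); vectorized.
#' @param config an \code{\link{env_config}}.
#' @return Posterior probability of the low state (same length as \code{x}).
#' @examples
#' cfg <- env_config("mean")
#' likelihood_update(0.5, 0, cfg)  # symmetric point: 0.5
#' @export
likelihood_update <- function(p_prior, x, config) {
  ll <- state_loglik(x, config)
  la <- log(p_prior) + ll$low
  lb <- log1p(-p_prior) + ll$high
  bad <- is.infinite(ll$low) & is.infinite(ll$high) & ll$low < 0 & ll$high < 0
  # log-sum-exp normalization
  m <- pmax(la, lb)
  post <- exp(la - (m + log(exp(la - m) + exp(lb - m))))
  # absorbing beliefs: la or lb is -Inf through the prior term alone
  post[p_prior == 0] <- 0
  post[p_prior == 1] <- 1
  if (any(bad)) {
    warning("both state likelihoods underflowed; returning prior unchanged")
    post[bad] <- p_prior
  }
  post
}

#' Posterior point estimate of the environmental state
#'
#' \eqn{\hat\theta_t = P^L_t \theta_L + (1 - P^L_t) \theta_H}: the posterior
#' mean, which minimizes mean squared error. Continuous even though the
#' states are discrete.
#'
#' @param p_low probability of the low state; vectorized.
#' @param config an \code{\link{env_config}}.
#' @return Point estimate(s).
#' @export
point_estimate <- function(p_low, config) {
  p_low * config$theta_low + (1 - p_low) * config$theta_high
}

# inverse of point_estimate: belief implied by an estimate value
belief_from_estimate <- function(theta_hat, config) {
  p <- (config$theta_high - theta_hat) / (config$theta_high - config$theta_low)
  pmin(pmax(p, 0), 1)
}

#' Observer's uncertainty: binary entropy of the belief
#'
#' \eqn{H[P^L_t] = -p \log p - (1-p)\log(1-p)} in nats, with
#' \eqn{0 \log 0 := 0}.
#'
#' @param p_low probability of the low state; vectorized.
#' @return Entropy in nats.
#' @export
belief_uncertainty <- function(p_low) {
  h <- numeric(length(p_low))
  ok <- p_low > 0 & p_low < 1
  p <- p_low[ok]
  h[ok] <- -p * log(p) - (1 - p) * log1p(-p)
  h
}

#' Predicted stimulus distribution parameters
#'
#' Given a belief (or point estimate), returns the (mu, sigma) of the
#' observer's predicted stimulus distribution \eqn{p(x_t | \hat\theta_{t-1})}:
#' in mean mode \eqn{N(\hat\theta, \sigma^2)}, in variance mode
#' \eqn{N(\mu, \hat\theta^2)}.
#'
#' @param p_low probability of the low state.
#' @param config an \code{\link{env_config}}.
#' @return List with elements \code{mu} and \code{sigma}.
#' @export
predicted_params <- function(p_low, config) {
  theta_hat <- point_estimate(p_low, config)
  state_params(theta_hat, config)
}

#' Decoding distribution
#'
#' The conditional distribution of the stimulus given the neural response,
#' used by the observer to marginalize over its uncertainty about the
#' stimulus. Three kinds arise from the encoders: \code{"delta"} (noiseless
#' transmitted value; scale 0), \code{"gaussian"} (temporal-filter inversion;
#' scale > 0), and \code{"prior_marginal"} (null symbol: the observer falls
#' back on its own predicted stimulus distribution).
#'
#' @param kind one of "delta", "gaussian", "prior_marginal".
#' @param location center of the distribution.
#' @param scale standard deviation (0 for delta).
#' @return An object of class \code{"decoding_dist"}.
#' @export
decoding_dist <- function(kind = c("delta", "gaussian", "prior_marginal"),
                          location, scale = 0) {
  kind <- match.arg(kind)
  if (kind == "delta" && scale != 0)
    stop("delta decoding has scale 0", call. = FALSE)
  if (kind != "delta" && scale <= 0)
    stop(sprintf("%s decoding requires scale > 0", kind), call. = FALSE)
  structure(list(kind = kind, location = location, scale = scale),
            class = "decoding_dist")
}

#' Belief update marginalized over the decoding distribution
#'
#' Implements the observer's posterior update when the stimulus is known only
#' through a decoding distribution: draws \code{n_samples} stimulus values,
#' applies the hazard propagation and likelihood update to each, and averages
#' the resulting posteriors across samples (Monte-Carlo marginalization).
#' For \code{kind = "delta"} this reduces exactly to a single
#' \code{\link{likelihood_update}}.
#'
#' @param p_prev belief before propagation (previous posterior).
#' @param decode a \code{\link{decoding_dist}}.
#' @param config an \code{\link{env_config}}.
#' @param n_samples number of Monte-Carlo samples (default 200; results are
#'   robust above roughly 50).
#' @param seed optional integer seed.
#' @return Updated posterior probability of the low state.
#' @export
marginal_update <- function(p_prev, decode, config, n_samples = 200,
                            seed = NULL) {
  stopifnot(inherits(decode, "decoding_dist"))
  if (n_samples < 1) stop("'n_samples' must be >= 1", call. = FALSE)
  p_prior <- hazard_propagate(p_prev, config$hazard)
  if (decode$kind == "delta")
    return(likelihood_update(p_prior, decode$location, config))
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(n_samples, decode$location, decode$scale)
  mean(likelihood_update(p_prior, z, config))
}

# One Bayesian step from a fixed belief, returning the point estimate.
# Vectorized over x. This is the ideal-observer estimate used inside the
# inference distortion d(x, y) = (est(x) - est(y))^2.
one_step_estimate <- function(p_prev, x, config) {
  p_prior <- hazard_propagate(p_prev, config$hazard)
  point_estimate(likelihood_update(p_prior, x, config), config)
}
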