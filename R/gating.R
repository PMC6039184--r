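#' Analytic misalignment between true and predicted stimulus distributions
#'
#' For Gaussian stimulus distributions the misalignment signal (cross-entropy
#' of the predicted distribution under the true one, minus the predicted
#' entropy) has the closed form
#' \deqn{M = \tfrac{1}{2}\log(2\pi e \sigma_t^2) +
#'   \log(\hat\sigma/\sigma_t) +
#'   \frac{\sigma_t^2 + (\mu_t - \hat\mu)^2}{2\hat\sigma^2} - \tfrac{1}{2}
#'   - \tfrac{1}{2}\log(2\pi e \hat\sigma^2),}
#' i.e. true entropy plus KL(true || predicted) minus predicted entropy. It
#' is zero when the prediction matches the truth, depends only on
#' \eqn{(\mu_t - \hat\mu)^2} for mean mismatches, and is asymmetric in the
#' variance ratio (larger magnitude when the true variance is the higher
#' one).
#'
#' @param mu_true,sigma_true parameters of the true stimulus distribution.
#' @param mu_hat,sigma_hat parameters of the predicted distribution.
#' @return Misalignment in nats; vectorized.
#' @examples
#' analytic_misalignment(2, 1, 0, 1)  # (delta mu)^2 / 2 = 2
#' @export
analytic_misalignment <- function(mu_true, sigma_true, mu_hat, sigma_hat) {
  stopifnot(all(sigma_true > 0), all(sigma_hat > 0))
  0.5 * log(2 * pi * exp(1) * sigma_true^2) +
    log(sigma_hat / sigma_true) +
    (sigma_true^2 + (mu_true - mu_hat)^2) / (2 * sigma_hat^2) - 0.5 -
    0.5 * log(2 * pi * exp(1) * sigma_hat^2)
}

#' Maximum analytic misalignment of a two-state environment
#'
#' The maximum of |misalignment| over ordered (true, predicted) state pairs;
#' selection thresholds are expressed as fractions of this value.
#'
#' @param config an \code{\link{env_config}}.
#' @return Positive scalar.
#' @export
max_misalignment <- function(config) {
  pl <- state_params(config$theta_low, config)
  ph <- state_params(config$theta_high, config)
  max(abs(analytic_misalignment(pl$mu, pl$sigma, ph$mu, ph$sigma)),
      abs(analytic_misalignment(ph$mu, ph$sigma, pl$mu, pl$sigma)))
}

#' Running-average misalignment from buffered stimuli
#'
#' Estimates the misalignment directly from the last \eqn{T} stimulus
#' samples: the buffered stimuli are all scored under the observer's current
#' prediction, \eqn{M = \frac{1}{T}\sum_\tau -\log p(x_{t-\tau} |
#' \hat\theta_{t-1}) - H(x | \hat\theta_{t-1})}, with \eqn{H} the Gaussian
#' entropy of the predicted distribution. An empty buffer returns 0 (no
#' evidence of misalignment).
#'
#' @param buffer numeric vector of the most recent stimuli (length <= T).
#' @param mu_hat,sigma_hat predicted stimulus parameters.
#' @return Estimated misalignment in nats.
#' @export
running_misalignment <- function(buffer, mu_hat, sigma_hat) {
  if (length(buffer) == 0) return(0)
  surprise <- -stats::dnorm(buffer, mu_hat, sigma_hat, log = TRUE)
  mean(surprise) - 0.5 * log(2 * pi * exp(1) * sigma_hat^2)
}

#' Surprise-gated encoding of one stimulus
#'
#' Transmits the stimulus verbatim when the magnitude of the running
#' misalignment exceeds \code{threshold_fraction} times the environment's
#' maximum analytic misalignment; otherwise emits an explicit null symbol
#' (never the numeric 0, which is a legitimate stimulus value).
#'
#' @param x stimulus value.
#' @param misalignment current running misalignment.
#' @param threshold_fraction threshold V as a fraction of
#'   \code{\link{max_misalignment}}.
#' @param max_m the environment's maximum analytic misalignment.
#' @return List with \code{value} (x or NA) and \code{null} (logical flag).
#' @export
select_encode <- function(x, misalignment, threshold_fraction, max_m) {
  stopifnot(threshold_fraction >= 0, max_m > 0)
  if (abs(misalignment) > threshold_fraction * max_m)
    list(value = x, null = FALSE)
  else
    list(value = NA_real_, null = TRUE)
}

#' Observer update on a null symbol
#'
#' When no stimulus is transmitted the observer marginalizes over its own
#' predicted stimulus distribution \eqn{p(x | \hat\theta_{t-1})}: a
#' "prior_marginal" decoding distribution. In expectation (exact prediction,
#' h = 0) this carries no information; with h > 0 the belief drifts toward
#' 0.5 through hazard propagation.
#'
#' @param p_prev belief before propagation.
#' @param config an \code{\link{env_config}}.
#' @param n_samples Monte-Carlo samples (default 200).
#' @param seed optional integer seed.
#' @return Updated belief.
#' @export
null_observer_update <- function(p_prev, config, n_samples = 200,
                                 seed = NULL) {
  pr <- predicted_params(p_prev, config)
  marginal_update(p_prev,
                  decoding_dist("prior_marginal", pr$mu, pr$sigma),
                  config, n_samples = n_samples, seed = seed)
}
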