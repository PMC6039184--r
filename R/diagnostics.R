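# cell usage probabilities of a quantizer's boundaries under the true
# stimulus distribution
cell_probs <- function(boundaries, true_theta, config) {
  sp <- state_params(true_theta, config)
  if (config$mode == "mean") {
    cdf <- stats::pnorm(boundaries, sp$mu, sp$sigma)
  } else {
    a <- pmax(boundaries, 0)
    cdf <- 2 * stats::pnorm(a / sp$sigma) - 1
    cdf[boundaries == Inf] <- 1
  }
  diff(cdf)
}

#' Entropy-coded spike rasters from a discretization run
#'
#' Converts a 4-level discretization simulation into binary spike patterns:
#' at each timestep the four response levels are ranked by their usage
#' probability under the true stimulus distribution (partitioned by the
#' current belief bin's boundaries), and the patterns \{[00], [10], [01],
#' [11]\} are assigned so that the fewest-spike pattern goes to the most
#' probable level (entropy coding). The spike count emitted at each timestep
#' is that of the pattern of the level actually used.
#'
#' @param sim a \code{\link{simulate_coding}} result with
#'   \code{encoder = "discretize"} and \code{n_levels = 4}.
#' @return List with \code{spikes} (per-timestep spike count),
#'   \code{raster} (cycles x cycle-length matrix of spike counts), and
#'   \code{rate} (cycle-averaged spikes per timestep).
#' @export
spike_raster <- function(sim) {
  stopifnot(inherits(sim, "coding_sim"))
  cfg <- sim$config
  if (cfg$encoder != "discretize" || cfg$n_levels != 4)
    stop("spike rasters require a discretization run with N = 4 levels",
         call. = FALSE)
  bank <- sim$policy
  env <- cfg$environment
  tr <- sim$trace
  states <- c(env$theta_low, env$theta_high)
  # spike counts per (belief bin, true state, level): computed once
  pattern_spikes <- c(0, 1, 1, 2)
  n_bins <- length(bank$belief_grid)
  spikes_for <- array(NA_real_, c(n_bins, 2, 4))
  for (b in seq_len(n_bins)) {
    for (s in 1:2) {
      pr <- cell_probs(bank$boundaries[[b]], states[s], env)
      # most probable level gets the fewest spikes
      spikes_for[b, s, order(pr, decreasing = TRUE)] <- pattern_spikes
    }
  }
  s_idx <- match(tr$theta, states)
  spikes <- spikes_for[cbind(tr$bin, s_idx, tr$level)]
  L2 <- 2 * sim$phase_length
  raster <- matrix(spikes, ncol = L2, byrow = TRUE)
  list(spikes = spikes, raster = raster, rate = colMeans(raster))
}

#' Metamer probability versus prediction alignment
#'
#' Two stimuli are metamers when they are mapped onto the same response
#' level and are therefore indistinguishable to the observer. With the true
#' state fixed at \eqn{\theta_L} (mean mode), draws \code{n_pairs} stimulus
#' pairs from \eqn{p(x | \theta_L)} for each of \code{n_grid} values of the
#' observer's estimate \eqn{\hat\theta} spanning \[\eqn{\theta_L},
#' \eqn{\theta_H}\] and reports the fraction of pairs encoded to the same
#' level.
#'
#' @param bank a \code{\link{quantizer_bank}} (typically N = 8, mean mode).
#' @param n_grid number of estimate values (default 100).
#' @param n_pairs stimulus pairs per grid value (default 100000).
#' @param seed optional integer seed.
#' @return A data.frame with columns \code{theta_hat} and
#'   \code{p_metamer}.
#' @export
metamer_probability <- function(bank, n_grid = 100, n_pairs = 100000,
                                seed = NULL) {
  stopifnot(inherits(bank, "quantizer_bank"))
  env <- bank$config
  if (env$mode != "mean")
    stop("metamer analysis is defined for the mean-switching environment",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  th <- seq(env$theta_low, env$theta_high, length.out = n_grid)
  sp <- state_params(env$theta_low, env)
  p_met <- vapply(th, function(theta_hat) {
    b <- nearest_bin(belief_from_estimate(theta_hat, env), bank$belief_grid)
    bd <- bank$boundaries[[b]]
    inner <- bd[-c(1, length(bd))]
    x1 <- stats::rnorm(n_pairs, sp$mu, sp$sigma)
    x2 <- stats::rnorm(n_pairs, sp$mu, sp$sigma)
    i1 <- findInterval(x1, inner, left.open = TRUE)
    i2 <- findInterval(x2, inner, left.open = TRUE)
    mean(i1 == i2)
  }, numeric(1))
  data.frame(theta_hat = th, p_metamer = p_met)
}
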