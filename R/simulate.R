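#' Closed-loop adaptive-coding simulation
#'
#' Runs the full encoder-observer feedback loop on the deterministic probe
#' environment: at each timestep a stimulus is drawn from the true
#' state-conditional distribution, encoded under the current policy (adapted
#' to the observer's fed-back estimate), decoded, and used to update the
#' observer's posterior. A parallel ideal observer receives the raw stimuli;
#' the per-step inference error is the squared difference between the two
#' state estimates.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param policy optional precomputed encoder policy (a
#'   \code{\link{quantizer_bank}} or \code{\link{filter_policy}}) to reuse
#'   across runs; fitted from \code{config} when NULL.
#' @return An object of class \code{"coding_sim"}: the per-timestep trace
#'   (data.frame), the configuration, the policy, and the probe phase
#'   length.
#' @examples
#' cfg <- experiment_config(env_config("mean"), encoder = "identity",
#'                          n_cycles = 5, seed = 1)
#' sim <- simulate_coding(cfg)
#' summary(sim)
#' @export
simulate_coding <- function(config, policy = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  env <- config$environment
  h <- env$hazard
  seed <- config$seed
  policy_seed <- if (is.null(seed)) NULL else derive_seed(seed, 1L)
  sim_seed <- if (is.null(seed)) NULL else derive_seed(seed, 2L)

  if (is.null(policy)) {
    policy <- switch(config$encoder,
      identity = NULL,
      discretize = quantizer_bank(env, config$goal, config$n_levels,
                                  n_bins = config$n_bins,
                                  n_train = config$n_train,
                                  seed = policy_seed),
      filter = filter_policy(env, config$goal, config$beta,
                             n_bins = config$n_bins,
                             n_pairs = config$n_train,
                             seed = policy_seed),
      select = NULL)
  }
  max_m <- if (config$encoder == "select") max_misalignment(env) else NA_real_

  theta <- probe_sequence(env, config$n_cycles)
  phase_len <- attr(theta, "phase_length")
  n <- length(theta)
  if (!is.null(sim_seed)) set.seed(sim_seed)
  x <- sample_stimulus(theta, env)

  p <- 0.5
  p_ideal <- 0.5
  x_prev <- if (n > 0) x[1] else NA_real_
  buffer <- numeric(0)

  y <- rep(NA_real_, n); null <- rep(FALSE, n); level <- rep(NA_integer_, n)
  bin <- rep(NA_integer_, n); p_low <- numeric(n); p_id <- numeric(n)
  ent_rate <- rep(NA_real_, n); mis <- rep(NA_real_, n)
  alpha_t <- rep(NA_real_, n); rec_err <- rep(NA_real_, n)
  noise_sd <- sqrt(config$noise_variance)

  for (t in seq_len(n)) {
    pr <- predicted_params(p, env)
    p_prior <- hazard_propagate(p, h)
    if (config$encoder == "identity") {
      y[t] <- x[t]
      p <- likelihood_update(p_prior, x[t], env)
      rec_err[t] <- 0
    } else if (config$encoder == "discretize") {
      b <- nearest_bin(p, policy$belief_grid)
      bin[t] <- b
      xin <- if (env$mode == "variance") abs(x[t] - env$fixed_mu) else x[t]
      bd <- policy$boundaries[[b]]
      i <- findInterval(xin, bd[-c(1, length(bd))], left.open = TRUE) + 1L
      level[t] <- i
      y[t] <- policy$levels[[b]][i]
      y_obs <- if (noise_sd > 0) y[t] + stats::rnorm(1, 0, noise_sd) else y[t]
      p <- likelihood_update(p_prior, y_obs, env)
      ent_rate[t] <- entropy_rate(bd, theta[t], env)
      rec_err[t] <- (xin - y[t])^2
    } else if (config$encoder == "filter") {
      b <- nearest_bin(p, policy$belief_grid)
      bin[t] <- b
      a <- policy$alpha_star[b]
      alpha_t[t] <- a
      y[t] <- filter_response(x[t], x_prev, a)
      dp <- decode_filter_params(y[t], a, pr$mu, pr$sigma)
      if (dp$sd == 0) {
        p <- likelihood_update(p_prior, dp$mean, env)
      } else {
        z <- stats::rnorm(config$mc_samples, dp$mean, dp$sd)
        p <- mean(likelihood_update(p_prior, z, env))
      }
      rec_err[t] <- (x[t] - y[t])^2
    } else {  # select
      buffer <- c(buffer, x[t])
      if (length(buffer) > config$window)
        buffer <- buffer[(length(buffer) - config$window + 1):length(buffer)]
      m <- running_misalignment(buffer, pr$mu, pr$sigma)
      mis[t] <- m
      transmit <- t <= config$window ||  # warm-up: transmit unconditionally
        abs(m) > config$threshold * max_m
      if (transmit) {
        y[t] <- x[t]
        p <- likelihood_update(p_prior, x[t], env)
        rec_err[t] <- 0
      } else {
        null[t] <- TRUE
        z <- stats::rnorm(config$mc_samples, pr$mu, pr$sigma)
        p <- mean(likelihood_update(p_prior, z, env))
      }
    }
    p_ideal <- likelihood_update(hazard_propagate(p_ideal, h), x[t], env)
    p_low[t] <- p
    p_id[t] <- p_ideal
    x_prev <- x[t]
  }

  est <- point_estimate(p_low, env)
  est_ideal <- point_estimate(p_id, env)
  prediction <- point_estimate(hazard_propagate(p_low, h), env)
  trace <- data.frame(
    t = seq_len(n),
    cycle = if (n > 0) rep(seq_len(config$n_cycles), each = 2 * phase_len)
            else integer(0),
    theta = as.numeric(theta), x = x, y = y, null = null,
    transmitted = !null, level = level, bin = bin,
    p_low = p_low, estimate = est, prediction = prediction,
    uncertainty = belief_uncertainty(p_low),
    p_low_ideal = p_id, estimate_ideal = est_ideal,
    inference_error = (est_ideal - est)^2,
    reconstruction_error = rec_err,
    entropy_rate = ent_rate, misalignment = mis, alpha = alpha_t)
  structure(list(trace = trace, config = config, policy = policy,
                 phase_length = phase_len),
            class = "coding_sim")
}

#' @export
print.coding_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Closed-loop coding simulation: %s encoder (%s mode%s)\n",
              cfg$encoder, cfg$environment$mode,
              if (cfg$encoder %in% c("discretize", "filter"))
                paste0(", goal = ", cfg$goal) else ""))
  cat(sprintf("  %d cycles x %d steps (h = %g), seed = %s\n",
              cfg$n_cycles, 2 * x$phase_length, cfg$environment$hazard,
              if (is.null(cfg$seed)) "none" else cfg$seed))
  invisible(x)
}

#' @export
summary.coding_sim <- function(object, ...) {
  tr <- object$trace
  out <- list(
    encoder = object$config$encoder,
    mode = object$config$environment$mode,
    goal = object$config$goal,
    n_steps = nrow(tr),
    mean_inference_error = mean(tr$inference_error),
    mean_reconstruction_error = mean(tr$reconstruction_error, na.rm = TRUE),
    mean_entropy_rate = if (all(is.na(tr$entropy_rate))) NA_real_
                        else mean(tr$entropy_rate, na.rm = TRUE),
    transmitted_fraction = mean(tr$transmitted),
    speed_accuracy = if (object$config$n_cycles > 0)
      speed_accuracy(cycle_average(object)$p_low, object$phase_length)
      else NULL)
  class(out) <- "summary.coding_sim"
  out
}

#' @export
print.summary.coding_sim <- function(x, ...) {
  cat(sprintf("%s encoder, %s mode%s: %d steps\n", x$encoder, x$mode,
              if (x$encoder %in% c("discretize", "filter"))
                paste0(" (goal = ", x$goal, ")") else "", x$n_steps))
  cat(sprintf("  mean inference error:      %.5g\n", x$mean_inference_error))
  cat(sprintf("  mean reconstruction error: %.5g\n",
              x$mean_reconstruction_error))
  if (!is.na(x$mean_entropy_rate))
    cat(sprintf("  mean entropy rate:         %.4g bits\n",
                x$mean_entropy_rate))
  cat(sprintf("  fraction transmitted:      %.3f\n", x$transmitted_fraction))
  if (!is.null(x$speed_accuracy)) {
    sa <- x$speed_accuracy
    cat(sprintf("  accuracy low/high: %.3f / %.3f;  speed down/up: %.3g / %.3g\n",
                sa$accuracy_low, sa$accuracy_high, sa$speed_down, sa$speed_up))
  }
  invisible(x)
}

#' @export
plot.coding_sim <- function(x, ...) {
  avg <- cycle_average(x)
  L <- x$phase_length
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(avg$step, avg$estimate, type = "l", col = "blue",
                 xlab = "time in cycle", ylab = "estimate",
                 main = sprintf("cycle-averaged estimate (%s)",
                                x$config$encoder), ...)
  graphics::lines(avg$step, avg$theta, lty = 2)
  graphics::abline(v = L + 0.5, col = "grey")
  graphics::plot(avg$step, avg$p_low, type = "l",
                 xlab = "time in cycle", ylab = "P(low)", ylim = c(0, 1))
  graphics::abline(v = L + 0.5, col = "grey")
  invisible(x)
}

#' Average a simulation trace across probe cycles
#'
#' @param sim a \code{\link{simulate_coding}} result.
#' @param columns which trace columns to average (default all numeric ones).
#' @param drop_first drop the first cycle (the observer starts from an
#'   uninformed belief, so the first low phase lacks the preceding
#'   high-state history the remaining cycles have)? Default FALSE.
#' @return A data.frame with \code{step} (position within the cycle,
#'   1 .. 2/h) and the cycle-averaged columns; \code{transmitted} averages to
#'   a transmission probability.
#' @export
cycle_average <- function(sim, columns = NULL, drop_first = FALSE) {
  stopifnot(inherits(sim, "coding_sim"))
  tr <- sim$trace
  L2 <- 2 * sim$phase_length
  if (drop_first && sim$config$n_cycles > 1) tr <- tr[tr$cycle > 1, ]
  if (is.null(columns))
    columns <- c("theta", "x", "p_low", "estimate", "uncertainty",
                 "p_low_ideal", "estimate_ideal", "inference_error",
                 "reconstruction_error", "entropy_rate", "misalignment",
                 "alpha", "transmitted")
  out <- data.frame(step = seq_len(L2))
  for (cn in columns) {
    v <- as.numeric(tr[[cn]])
    out[[cn]] <- rowMeans(matrix(v, nrow = L2), na.rm = TRUE)
  }
  out
}

#' Speed and accuracy of inference from a cycle-averaged posterior
#'
#' Accuracy is the time-average of \eqn{P^L_t} (low phase) or
#' \eqn{1 - P^L_t} (high phase) over the final \code{window} timesteps of
#' each phase. Speed is the inverse of the number of timesteps after a
#' switch before the averaged posterior comes within \code{band} of its
#' final-window average (1/phase length if it never does).
#'
#' @param avg_p_low cycle-averaged posterior, length 2 x phase_length
#'   (low phase first).
#' @param phase_length samples per phase (1/h).
#' @param window averaging window at the end of each phase (default 10).
#' @param band convergence band (default 0.05).
#' @return List with \code{accuracy_low}, \code{accuracy_high},
#'   \code{speed_down} (switch into the low state), \code{speed_up} (switch
#'   into the high state).
#' @export
speed_accuracy <- function(avg_p_low, phase_length, window = 10,
                           band = 0.05) {
  L <- phase_length
  stopifnot(length(avg_p_low) == 2 * L, window <= L)
  low <- avg_p_low[1:L]
  high <- avg_p_low[(L + 1):(2 * L)]
  final_low <- mean(low[(L - window + 1):L])
  final_high <- mean(high[(L - window + 1):L])
  t_down <- which(abs(low - final_low) <= band)[1]
  t_up <- which(abs(high - final_high) <= band)[1]
  list(accuracy_low = final_low,
       accuracy_high = 1 - final_high,
       speed_down = 1 / (if (is.na(t_down)) L else t_down),
       speed_up = 1 / (if (is.na(t_up)) L else t_up))
}
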