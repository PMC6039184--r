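#' Two-tap temporal filter response
#'
#' \eqn{y_t = \alpha x_t + (1 - \alpha) x_{t-1}}. With \eqn{\alpha = 1} the
#' current stimulus is transmitted with perfect fidelity; with
#' \eqn{\alpha = 0.5} the encoder transmits the average of the two most
#' recent stimuli (minimal fidelity).
#'
#' @param x_now,x_prev current and previous stimulus values; vectorized.
#' @param alpha filter coefficient in \[0.5, 1\] (the lower end may be
#'   relaxed to 0 via \code{alpha_range} in \code{\link{filter_policy}}).
#' @return Filtered response.
#' @export
filter_response <- function(x_now, x_prev, alpha) {
  if (any(alpha < 0) || any(alpha > 1))
    stop("'alpha' must lie in [0, 1]", call. = FALSE)
  alpha * x_now + (1 - alpha) * x_prev
}

#' Closed-form Gaussian decoding of a filtered response
#'
#' Inverts the two-tap filter by marginalizing the unknown previous stimulus
#' under the observer's prediction \eqn{N(\hat\mu, \hat\sigma^2)}, giving a
#' Gaussian decoding distribution with mean
#' \eqn{[\alpha y - (1-\alpha)(2\alpha - 1)\hat\mu] / (1 - 2\alpha + 2\alpha^2)}
#' and variance
#' \eqn{[(1-\alpha)^2 / (1 - 2\alpha + 2\alpha^2)] \hat\sigma^2}. The
#' denominator is bounded below by 1/2 so the form is always well defined;
#' at \eqn{\alpha = 1} it degenerates to a delta at \eqn{y}.
#'
#' @param y observed response.
#' @param alpha filter coefficient used to produce \code{y}.
#' @param mu_hat,sigma_hat predicted stimulus mean and standard deviation.
#' @return A \code{\link{decoding_dist}} ("gaussian", or "delta" when
#'   \code{alpha = 1}).
#' @export
decode_filter <- function(y, alpha, mu_hat, sigma_hat) {
  den <- 1 - 2 * alpha + 2 * alpha^2
  m <- (alpha * y - (1 - alpha) * (2 * alpha - 1) * mu_hat) / den
  s <- sqrt((1 - alpha)^2 / den) * sigma_hat
  if (s == 0) decoding_dist("delta", m) else decoding_dist("gaussian", m, s)
}

# decoding mean/sd without constructing the object (vectorized over y)
decode_filter_params <- function(y, alpha, mu_hat, sigma_hat) {
  den <- 1 - 2 * alpha + 2 * alpha^2
  list(mean = (alpha * y - (1 - alpha) * (2 * alpha - 1) * mu_hat) / den,
       sd = sqrt((1 - alpha)^2 / den) * sigma_hat)
}

#' Joint entropy of two consecutive filtered responses
#'
#' Analytic entropy penalty used in the filter objective:
#' \deqn{H(y_t, y_{t+1}) = \frac{1}{2}\log\left(4\pi^2 e^2
#'  \left(\alpha^2\hat\sigma^2 +
#'   \frac{(1-\alpha)^4}{1 - 2\alpha + 2\alpha^2}\hat\sigma^2\right)
#'  \left(\alpha^2\hat\sigma^2 + (1-\alpha)^2\hat\sigma^2\right)\right)}
#' in nats. At \eqn{\alpha = 1} this equals twice the marginal entropy of a
#' Gaussian response (two independent responses); averaging
#' (\eqn{\alpha < 1}) lowers it.
#'
#' @param alpha filter coefficient; vectorized.
#' @param sigma_hat predicted stimulus standard deviation.
#' @return Joint entropy in nats.
#' @export
filter_joint_entropy <- function(alpha, sigma_hat) {
  den <- 1 - 2 * alpha + 2 * alpha^2
  v1 <- alpha^2 * sigma_hat^2 + (1 - alpha)^4 / den * sigma_hat^2
  v2 <- alpha^2 * sigma_hat^2 + (1 - alpha)^2 * sigma_hat^2
  0.5 * log(4 * pi^2 * exp(2) * v1 * v2)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention,
# weight exp(-t^2)); used to marginalize Gaussian decoding distributions
# deterministically: E[f(Z)] ~ sum w_i f(m + sqrt(2) s t_i) / sqrt(pi).
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(sqrt(pi) * e$vectors[1, ]^2))
}

# Posterior-mean estimate after marginalizing a Gaussian decoding
# distribution with per-response mean m (vector) and common sd s, by
# Gauss-Hermite quadrature. p_prior is already hazard-propagated.
quadrature_estimate <- function(p_prior, m, s, config, gh) {
  if (s == 0) {
    post <- likelihood_update(p_prior, m, config)
  } else {
    z <- outer(m, gh$nodes, function(mm, t) mm + sqrt(2) * s * t)
    pz <- likelihood_update(p_prior, as.vector(z), config)
    post <- as.vector(matrix(pz, nrow = length(m)) %*% gh$weights) / sqrt(pi)
  }
  point_estimate(post, config)
}

#' Fit the belief-conditional filter-coefficient policy
#'
#' For each belief bin and each candidate coefficient on the alpha grid, the
#' objective \eqn{\langle E(x_t, y_t)\rangle + \beta H(y_t, y_{t+1})} is
#' evaluated by Monte-Carlo over \code{n_pairs} stimulus pairs drawn from the
#' predicted distribution \eqn{p(x | \hat\theta_{bin})}; the optimal
#' coefficient is the grid argmin (ties broken toward the larger alpha, i.e.
#' higher fidelity). For \code{goal = "inference"} the error compares
#' one-step ideal-observer estimates from the raw stimulus versus the
#' decoded response, with the decoding distribution marginalized either by
#' Gauss-Hermite quadrature (\code{marginalize = "quadrature"}, the default;
#' deterministic) or by plugging in the decoding mean
#' (\code{marginalize = "mean"}, fast approximation).
#'
#' @param config an \code{\link{env_config}}.
#' @param goal "inference" or "reconstruction".
#' @param entropy_weight nonnegative multiplier \eqn{\beta} on the joint
#'   entropy penalty.
#' @param n_bins belief-grid size (default 100).
#' @param n_alpha alpha-grid size (default 50).
#' @param alpha_range candidate interval (default c(0.5, 1); c(0, 1) is also
#'   meaningful).
#' @param n_pairs stimulus pairs per (bin, alpha) cell (default 50000).
#' @param marginalize "quadrature" or "mean" (inference goal only).
#' @param gh_nodes quadrature nodes (default 15).
#' @param seed optional integer seed.
#' @return An object of class \code{"filter_policy"} with \code{alpha_star}
#'   and \code{objective} per belief bin.
#' @export
filter_policy <- function(config, goal = c("inference", "reconstruction"),
                          entropy_weight = 0, n_bins = 100, n_alpha = 50,
                          alpha_range = c(0.5, 1), n_pairs = 50000,
                          marginalize = c("quadrature", "mean"),
                          gh_nodes = 15, seed = NULL) {
  goal <- match.arg(goal)
  marginalize <- match.arg(marginalize)
  stopifnot(entropy_weight >= 0, n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, 1, length.out = n_bins)
  alphas <- seq(alpha_range[1], alpha_range[2], length.out = n_alpha)
  gh <- gauss_hermite(gh_nodes)
  alpha_star <- numeric(n_bins)
  objective <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    p <- grid[b]
    pr <- predicted_params(p, config)
    x_prev <- stats::rnorm(n_pairs, pr$mu, pr$sigma)
    x_now <- stats::rnorm(n_pairs, pr$mu, pr$sigma)
    p_prior <- hazard_propagate(p, config$hazard)
    est_x <- if (goal == "inference")
      point_estimate(likelihood_update(p_prior, x_now, config), config)
    obj <- vapply(alphas, function(a) {
      y <- filter_response(x_now, x_prev, a)
      err <- if (goal == "reconstruction") {
        mean((x_now - y)^2)
      } else {
        dp <- decode_filter_params(y, a, pr$mu, pr$sigma)
        est_y <- if (marginalize == "mean" || dp$sd == 0)
          point_estimate(likelihood_update(p_prior, dp$mean, config), config)
        else
          quadrature_estimate(p_prior, dp$mean, dp$sd, config, gh)
        mean((est_x - est_y)^2)
      }
      err + entropy_weight * filter_joint_entropy(a, pr$sigma)
    }, numeric(1))
    best <- max(which(obj <= min(obj) + 1e-12))  # tie -> larger alpha
    alpha_star[b] <- alphas[best]
    objective[b] <- obj[best]
  }
  structure(list(config = config, goal = goal,
                 entropy_weight = entropy_weight, belief_grid = grid,
                 alpha_grid = alphas, alpha_star = alpha_star,
                 objective = objective, marginalize = marginalize),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat(sprintf(
    "Temporal-filter policy: goal = %s, beta = %g, %d belief bins (%s mode)\n",
    x$goal, x$entropy_weight, length(x$belief_grid), x$config$mode))
  cat(sprintf("  alpha range used: [%g, %g]\n",
              min(x$alpha_star), max(x$alpha_star)))
  invisible(x)
}

#' @export
plot.filter_policy <- function(x, ...) {
  graphics::plot(x$belief_grid, x$alpha_star, type = "s",
                 xlab = "belief P(low)", ylab = expression(alpha^"*"),
                 ylim = range(x$alpha_grid),
                 main = sprintf("%s-optimized filter coefficient", x$goal), ...)
  invisible(x)
}

#' Flatten a filter policy to a table
#'
#' @param policy a \code{\link{filter_policy}}.
#' @return A data.frame with columns bin, belief, alpha_star, objective.
#' @export
policy_table <- function(policy) {
  data.frame(bin = seq_along(policy$belief_grid),
             belief = policy$belief_grid,
             alpha_star = policy$alpha_star,
             objective = policy$objective)
}
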