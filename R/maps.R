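#' Generalized Gaussian density and entropy
#'
#' Density \eqn{p(x; \mu, \alpha, \beta) = \frac{\beta}{2\alpha\Gamma(1/\beta)}
#' \exp[-(|x - \mu|/\alpha)^\beta]} and its differential entropy
#' \eqn{1/\beta + \log(2\alpha\Gamma(1/\beta)/\beta)} in nats. Shape
#' \eqn{\beta = 2} with \eqn{\alpha = \sqrt{2}\sigma} is the Gaussian
#' \eqn{N(\mu, \sigma^2)}; \eqn{\beta = 1} is Laplace; large \eqn{\beta}
#' approaches a flat (uniform-like) distribution.
#'
#' @param x evaluation point(s).
#' @param location,scale,shape distribution parameters (scale, shape > 0).
#' @return Density values / entropy in nats.
#' @export
gengauss_density <- function(x, location = 0, scale = sqrt(2), shape = 2) {
  stopifnot(scale > 0, shape > 0)
  shape / (2 * scale * gamma(1 / shape)) *
    exp(-(abs(x - location) / scale)^shape)
}

#' @rdname gengauss_density
#' @export
gengauss_entropy <- function(scale = sqrt(2), shape = 2) {
  stopifnot(scale > 0, shape > 0)
  1 / shape + log(2 * scale * gamma(1 / shape) / shape)
}

#' Prior parameters attaining a requested entropy
#'
#' Inverts the entropy of the observer's conjugate prior. For location
#' estimation the prior is Gaussian with mean 0 and variance
#' \eqn{\sigma_0^2 = \exp(2H)/(2\pi e)}. For scale estimation the prior is
#' inverse-gamma \eqn{(\alpha_0, \beta_0)} over the scale parameter, with
#' \eqn{\beta_0 = \hat\alpha(\alpha_0 - 1)} fixed by the prior mean
#' \eqn{\hat\alpha = \sqrt{2}} (so that \eqn{\hat\alpha^2/2 = 1}) and
#' \eqn{\alpha_0 > 2} found by root-finding on the entropy
#' \eqn{H = \alpha_0 + \log(\beta_0\Gamma(\alpha_0)) -
#' (1 + \alpha_0)\psi(\alpha_0)} (restricted to the monotonic regime).
#'
#' @param entropy requested prior entropy H in nats.
#' @param parameter "location" or "scale".
#' @return For location: list(type = "gaussian", mean, var). For scale:
#'   list(type = "invgamma", alpha0, beta0, mean).
#' @export
entropy_to_prior <- function(entropy, parameter = c("location", "scale")) {
  parameter <- match.arg(parameter)
  if (parameter == "location") {
    return(list(type = "gaussian", mean = 0,
                var = exp(2 * entropy) / (2 * pi * exp(1))))
  }
  alpha_hat <- sqrt(2)
  ig_entropy <- function(a0) {
    b0 <- alpha_hat * (a0 - 1)
    a0 + log(b0) + lgamma(a0) - (1 + a0) * digamma(a0)
  }
  lo <- 2 + 1e-8
  if (ig_entropy(lo) < entropy)
    stop("requested entropy is not attainable with alpha0 > 2", call. = FALSE)
  hi <- 4
  while (ig_entropy(hi) > entropy && hi < 1e8) hi <- hi * 2
  a0 <- stats::uniroot(function(a) ig_entropy(a) - entropy, c(lo, hi),
                       tol = 1e-10)$root
  list(type = "invgamma", alpha0 = a0, beta0 = alpha_hat * (a0 - 1),
       mean = alpha_hat)
}

#' Stimulus value eliciting a given surprise
#'
#' Solves \eqn{-\log p(x^*) = S} for the positive root under a generalized
#' Gaussian predicted distribution (the negative root is its mirror image).
#'
#' @param surprise requested surprise S in nats (must be at least the
#'   surprise of the density mode).
#' @param location,scale,shape predicted distribution parameters.
#' @return The stimulus value \eqn{x^* \ge} location.
#' @export
surprise_to_stimulus <- function(surprise, location = 0, scale = sqrt(2),
                                 shape = 2) {
  base <- surprise + log(shape / (2 * scale * gamma(1 / shape)))
  if (any(base < -1e-9))
    stop("surprise below the minimum achievable for this distribution",
         call. = FALSE)
  base <- pmax(base, 0)
  location + scale * base^(1 / shape)
}

#' Standard uncertainty/surprise grid
#'
#' @param n_uncertainty,n_surprise grid sizes (default 100 each).
#' @return List with \code{uncertainty} (equally spaced in \[0, 0.7\] nats)
#'   and \code{surprise} (equally spaced in \[1, 10\] nats).
#' @export
map_grid <- function(n_uncertainty = 100, n_surprise = 100) {
  list(uncertainty = seq(0, 0.7, length.out = n_uncertainty),
       surprise = seq(1, 10, length.out = n_surprise))
}

#' Impact of a single stimulus on the stationary Bayesian estimate
#'
#' For every combination of prior uncertainty (entropy) and stimulus
#' surprise, builds the conjugate prior, computes the stimulus \eqn{x^*}
#' eliciting that surprise under the predicted distribution, forms the
#' posterior, and returns the squared change in the posterior-mean estimate:
#' \eqn{(\hat\theta_{prior} - \hat\theta_{post}(x^*))^2}. For location
#' estimation the estimated quantity is the location \eqn{\mu} (prior mean
#' 0, likelihood scale \eqn{\sqrt{2}} i.e. unit variance at shape 2;
#' conjugate closed form used when shape = 2, numeric grid posterior
#' otherwise). For scale estimation it is \eqn{\alpha^2/2} (prior mean 1,
#' likelihood location 0; numeric grid posterior over \eqn{\alpha}).
#'
#' @param uncertainty,surprise grid vectors (see \code{\link{map_grid}}).
#' @param shape generalized-Gaussian shape (1 Laplace, 2 Gaussian, 10 near
#'   flat).
#' @param parameter "location" or "scale".
#' @param grid_points resolution of the numeric posterior grid
#'   (default 2001).
#' @return Matrix of impacts, rows indexed by uncertainty, columns by
#'   surprise (dimnames carry the grid values).
#' @export
impact_map <- function(uncertainty = map_grid()$uncertainty,
                       surprise = map_grid()$surprise,
                       shape = 2,
                       parameter = c("location", "scale"),
                       grid_points = 2001) {
  parameter <- match.arg(parameter)
  scale0 <- sqrt(2)  # likelihood/predicted scale: unit variance at shape 2
  # invert surprise; requested values below the mode's surprise (possible at
  # the low end of the grid for heavy-peaked shapes) clamp to the mode
  base <- pmax(surprise + log(shape / (2 * scale0 * gamma(1 / shape))), 0)
  xs <- scale0 * base^(1 / shape)
  out <- matrix(NA_real_, length(uncertainty), length(surprise),
                dimnames = list(uncertainty = signif(uncertainty, 6),
                                surprise = signif(surprise, 6)))
  for (i in seq_along(uncertainty)) {
    prior <- entropy_to_prior(uncertainty[i], parameter)
    if (parameter == "location") {
      if (shape == 2) {
        # conjugate Gaussian update: posterior mean = s0^2 x / (s0^2 + 1)
        post_mean <- prior$var * xs / (prior$var + 1)
      } else {
        s0 <- sqrt(prior$var)
        mu_g <- seq(-6 * s0, 6 * s0, length.out = grid_points)
        lp0 <- stats::dnorm(mu_g, 0, s0, log = TRUE)
        post_mean <- vapply(xs, function(x) {
          lp <- lp0 + log(gengauss_density(x, mu_g, scale0, shape))
          w <- exp(lp - max(lp))
          sum(w * mu_g) / sum(w)  # trapezoid weights cancel (uniform grid)
        }, numeric(1))
      }
      out[i, ] <- (post_mean - 0)^2
    } else {
      sd0 <- prior$beta0 / ((prior$alpha0 - 1) * sqrt(prior$alpha0 - 2))
      a_g <- seq(max(1e-4, prior$mean - 6 * sd0), prior$mean + 6 * sd0,
                 length.out = grid_points)
      lp0 <- prior$alpha0 * log(prior$beta0) - lgamma(prior$alpha0) -
        (prior$alpha0 + 1) * log(a_g) - prior$beta0 / a_g
      out[i, ] <- vapply(xs, function(x) {
        lp <- lp0 + log(gengauss_density(x, 0, a_g, shape))
        w <- exp(lp - max(lp))
        post_mean_a <- sum(w * a_g) / sum(w)
        (prior$mean^2 / 2 - post_mean_a^2 / 2)^2
      }, numeric(1))
    }
  }
  out
}

#' Encoding error and error-tolerance set (Gaussian location case)
#'
#' The error induced by updating the stationary Gaussian-location estimate
#' with a response \eqn{y} instead of the stimulus \eqn{x} is
#' \eqn{(\hat\theta(x) - \hat\theta(y))^2 = k^2 (x - y)^2} with posterior
#' gain \eqn{k = \sigma_0^2 / (\sigma_0^2 + 1)}. \code{tolerance_set}
#' returns the interval of stimuli that can be mapped onto the response
#' \code{y} with error below \code{e_tol} — wider when the observer is
#' certain (low uncertainty).
#'
#' @param uncertainty prior entropy H in nats.
#' @param x stimulus value(s).
#' @param y response value.
#' @param e_tol error tolerance.
#' @return \code{encoding_error_map}: error value(s).
#'   \code{tolerance_set}: c(lower, upper) interval around \code{y}.
#' @export
encoding_error_map <- function(uncertainty, x, y) {
  v0 <- entropy_to_prior(uncertainty, "location")$var
  k <- v0 / (v0 + 1)
  k^2 * (x - y)^2
}

#' @rdname encoding_error_map
#' @export
tolerance_set <- function(uncertainty, y, e_tol = 0.05) {
  v0 <- entropy_to_prior(uncertainty, "location")$var
  k <- v0 / (v0 + 1)
  half <- sqrt(e_tol) / k
  c(lower = y - half, upper = y + half)
}

#' Write a map matrix as CSV with grid headers
#'
#' @param map matrix from \code{\link{impact_map}}.
#' @param path output file path.
#' @export
write_map <- function(map, path) {
  utils::write.csv(map, path, row.names = TRUE)
  invisible(path)
}
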