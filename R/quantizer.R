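#' Lloyd's algorithm for scalar quantization under a custom distortion
#'
#' Alternates assignment (each training point goes to the level with the
#' smallest distortion) and centroid update (each level is replaced by the
#' mean of its assigned points) until assignments stabilize or
#' \code{max_iter} iterations. Empty cells are reseeded at a random training
#' point. The average distortion is non-increasing across iterations and the
#' per-iteration values are returned for inspection.
#'
#' Both distortion measures used by the encoders have the form
#' \eqn{d(x, y) = (g(x) - g(y))^2} for a scalar map \eqn{g} (identity for
#' reconstruction error; the one-step ideal-observer estimate for inference
#' error). When such a \code{transform} is supplied, assignment is computed
#' exactly as nearest-level in \eqn{g}-space via midpoint boundaries, which
#' is fast. Alternatively an arbitrary vectorized \code{distortion(x, y)} may
#' be given, in which case a full distortion matrix is evaluated per
#' iteration.
#'
#' @param training numeric vector of training samples (size >= n_levels).
#' @param n_levels number of quantization levels N.
#' @param transform scalar map g for squared-transform distortions
#'   (default identity, i.e. squared error).
#' @param distortion optional vectorized function d(x, y) >= 0 overriding
#'   \code{transform}.
#' @param max_iter iteration cap (default 200).
#' @param seed optional integer seed (initialization and reseeding).
#' @return List with \code{levels} (sorted), \code{boundaries} (length N+1;
#'   empirical decision boundaries from the training assignment, outermost
#'   \code{-Inf}/\code{Inf}), \code{assignment} (per training point), and
#'   \code{history} (average distortion per iteration).
#' @examples
#' q <- lloyd_fit(rnorm(5000), 2, seed = 1)
#' q$levels  # close to +/- sqrt(2/pi) for a standard Gaussian
#' @export
lloyd_fit <- function(training, n_levels, transform = identity,
                      distortion = NULL, max_iter = 200, seed = NULL) {
  n <- length(training)
  stopifnot(n >= n_levels, n_levels >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- training
  levels <- sort(sample(x, n_levels))
  use_transform <- is.null(distortion)
  gx <- if (use_transform) transform(x) else NULL

  assign_pts <- function(levels) {
    if (use_transform) {
      gy <- transform(levels)
      o <- order(gy)
      if (n_levels == 1L) return(rep(1L, n))
      mids <- (gy[o][-1] + gy[o][-n_levels]) / 2
      # left-open intervals: a point exactly at a boundary goes to the
      # lower-index cell
      idx <- findInterval(gx, mids, left.open = TRUE) + 1L
      o[idx]
    } else {
      d <- vapply(levels, function(y) distortion(x, rep(y, n)), numeric(n))
      max.col(-d, ties.method = "first")
    }
  }
  avg_distortion <- function(levels, a) {
    if (use_transform) mean((gx - transform(levels)[a])^2)
    else mean(distortion(x, levels[a]))
  }

  a_prev <- NULL
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    a <- assign_pts(levels)
    # reseed empty cells at random training points
    empty <- setdiff(seq_len(n_levels), unique(a))
    while (length(empty) > 0) {
      levels[empty] <- sample(x, length(empty))
      a <- assign_pts(levels)
      empty <- setdiff(seq_len(n_levels), unique(a))
    }
    history <- c(history, avg_distortion(levels, a))
    if (!is.null(a_prev) && identical(a, a_prev)) break
    a_prev <- a
    levels <- as.numeric(tapply(x, factor(a, levels = seq_len(n_levels)), mean))
  }

  o <- order(levels)
  levels <- levels[o]
  a <- match(a, o)  # relabel assignment to sorted order
  # empirical decision boundaries between adjacent (sorted) cells
  if (n_levels > 1L) {
    hi <- as.numeric(tapply(x, factor(a, levels = seq_len(n_levels)), max))
    lo <- as.numeric(tapply(x, factor(a, levels = seq_len(n_levels)), min))
    inner <- (hi[-n_levels] + lo[-1]) / 2
  } else inner <- numeric(0)
  list(levels = levels, boundaries = c(-Inf, inner, Inf),
       assignment = a, history = history)
}

#' Build a bank of belief-conditional quantizers
#'
#' For each of \code{n_bins} belief values equally spaced in \[0, 1\], fits
#' optimal response levels by Lloyd's algorithm on \code{n_train} samples
#' drawn from the predicted stimulus distribution
#' \eqn{p(x | \hat\theta_{bin})}. With \code{goal = "inference"} the
#' distortion is \eqn{(\hat\theta_x - \hat\theta_y)^2}, where the estimates
#' are one-step ideal-observer updates from the bin's (hazard-propagated)
#' belief; with \code{goal = "reconstruction"} it is \eqn{(x - y)^2}. In
#' variance mode levels are defined over the absolute deviation from the
#' mean, \eqn{|x - \mu|} (with \eqn{\mu = 0}), and the outer boundaries are
#' \[0, Inf).
#'
#' @param config an \code{\link{env_config}}.
#' @param goal "inference" or "reconstruction".
#' @param n_levels number of response levels N.
#' @param n_bins size of the belief grid (default 100).
#' @param n_train training samples per bin (default 50000).
#' @param seed optional integer seed.
#' @return An object of class \code{"quantizer_bank"}: lists \code{levels}
#'   and \code{boundaries} indexed by belief bin, plus the belief grid and
#'   configuration.
#' @export
quantizer_bank <- function(config, goal = c("inference", "reconstruction"),
                           n_levels, n_bins = 100, n_train = 50000,
                           seed = NULL) {
  goal <- match.arg(goal)
  stopifnot(inherits(config, "env_config"), n_levels >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, 1, length.out = n_bins)
  levels <- vector("list", n_bins)
  boundaries <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    p <- grid[b]
    pr <- predicted_params(p, config)
    x <- stats::rnorm(n_train, pr$mu, pr$sigma)
    if (config$mode == "variance") x <- abs(x - config$fixed_mu)
    g <- if (goal == "inference")
      function(z) one_step_estimate(p, z, config)
    else identity
    fit <- lloyd_fit(x, n_levels, transform = g)
    if (config$mode == "variance") fit$boundaries[1] <- 0
    levels[[b]] <- fit$levels
    boundaries[[b]] <- fit$boundaries
  }
  structure(list(config = config, goal = goal, n_levels = n_levels,
                 belief_grid = grid, levels = levels,
                 boundaries = boundaries),
            class = "quantizer_bank")
}

#' @export
print.quantizer_bank <- function(x, ...) {
  cat(sprintf("Quantizer bank: N = %d levels, goal = %s, %d belief bins (%s mode)\n",
              x$n_levels, x$goal, length(x$belief_grid), x$config$mode))
  invisible(x)
}

#' @export
plot.quantizer_bank <- function(x, ...) {
  L <- do.call(rbind, x$levels)
  graphics::matplot(x$belief_grid, L, type = "l", lty = 1,
                    xlab = "belief P(low)", ylab = "response level",
                    main = sprintf("%s-optimized response levels", x$goal), ...)
  invisible(x)
}

# nearest belief bin index for a belief value
nearest_bin <- function(p_low, grid) {
  n <- length(grid)
  pmin(pmax(1L, as.integer(round(p_low * (n - 1))) + 1L), n)
}

#' Encode a stimulus with the quantizer bank
#'
#' Maps the stimulus onto the response level of the belief bin nearest to
#' \code{belief}. A stimulus exactly at a cell boundary is assigned to the
#' lower-index level. In variance mode the stimulus enters as its absolute
#' deviation from the fixed mean.
#'
#' @param x stimulus value(s); vectorized.
#' @param bank a \code{\link{quantizer_bank}}.
#' @param belief the observer's current belief (probability of low state).
#' @return Integer level index (attribute \code{"value"} holds the level
#'   value, i.e. the delta-decoded response).
#' @export
encode_discrete <- function(x, bank, belief) {
  b <- nearest_bin(belief, bank$belief_grid)
  if (bank$config$mode == "variance") x <- abs(x - bank$config$fixed_mu)
  bd <- bank$boundaries[[b]]
  idx <- findInterval(x, bd[-c(1, length(bd))], left.open = TRUE) + 1L
  structure(idx, value = bank$levels[[b]][idx])
}

#' Entropy rate of a quantizer under the true stimulus distribution
#'
#' Partitions the true stimulus distribution \eqn{p(x | \theta_{true})} by
#' the cell boundaries (Gaussian CDF differences; folded for the absolute
#' deviation in variance mode) and returns the Shannon entropy of the cell
#' usage probabilities in bits. This is the coding cost: the minimal number
#' of bits per symbol needed to represent the response.
#'
#' @param boundaries numeric vector of N+1 cell edges.
#' @param true_theta the true environmental state.
#' @param config an \code{\link{env_config}}.
#' @return Entropy in bits.
#' @export
entropy_rate <- function(boundaries, true_theta, config) {
  sp <- state_params(true_theta, config)
  if (config$mode == "mean") {
    cdf <- stats::pnorm(boundaries, sp$mu, sp$sigma)
  } else {
    a <- pmax(boundaries, 0)  # absolute-deviation domain
    cdf <- 2 * stats::pnorm(a / sp$sigma) - 1
    cdf[boundaries == Inf] <- 1
  }
  p <- diff(cdf)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Flatten a quantizer bank to a table
#'
#' @param bank a \code{\link{quantizer_bank}}.
#' @return A data.frame with columns bin, belief, level, value, lower, upper.
#' @export
bank_table <- function(bank) {
  n <- bank$n_levels
  do.call(rbind, lapply(seq_along(bank$belief_grid), function(b) {
    bd <- bank$boundaries[[b]]
    data.frame(bin = b, belief = bank$belief_grid[b], level = seq_len(n),
               value = bank$levels[[b]], lower = bd[-(n + 1)], upper = bd[-1])
  }))
}
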