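# deterministic substream seeds from a single run seed (kept below 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483629 * 48271 + k * 10007) %% 2147483629)
}

#' Experiment configuration
#'
#' Bundles the environment, the encoder choice and its constraint
#' parameters, the run length and the seed into a validated, serializable
#' configuration. A configuration plus its seed reproduces a run exactly.
#'
#' @param environment an \code{\link{env_config}}.
#' @param encoder "identity", "discretize", "filter" or "select".
#' @param goal optimization goal for discretize/filter: "inference" or
#'   "reconstruction".
#' @param n_levels response levels N (discretize).
#' @param beta entropy-penalty weight (filter).
#' @param threshold selection threshold V as a fraction of the maximum
#'   analytic misalignment (select).
#' @param window surprise-averaging window T (select; default 10).
#' @param n_cycles probe cycles to simulate.
#' @param mc_samples Monte-Carlo samples for decoding-distribution
#'   marginalization (default 200).
#' @param n_bins belief-grid size for policy fitting (default 100).
#' @param n_train training samples (discretize) or pairs (filter) per
#'   belief bin (default 50000).
#' @param noise_variance Gaussian transmission-noise variance added to the
#'   discretization response (default 0).
#' @param seed integer run seed (NULL = current RNG stream).
#' @return An object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(environment = env_config("mean"),
                              encoder = c("identity", "discretize",
                                          "filter", "select"),
                              goal = c("inference", "reconstruction"),
                              n_levels = 3, beta = 0.1, threshold = 0.5,
                              window = 10, n_cycles = 100, mc_samples = 200,
                              n_bins = 100, n_train = 50000,
                              noise_variance = 0, seed = NULL) {
  encoder <- match.arg(encoder)
  goal <- match.arg(goal)
  stopifnot(inherits(environment, "env_config"))
  check_scalar <- function(v, nm, min = -Inf, integerish = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        (integerish && v != round(v)))
      stop(sprintf("field '%s' must be a %s >= %g", nm,
                   if (integerish) "whole number" else "number", min),
           call. = FALSE)
  }
  check_scalar(n_levels, "n_levels", 1, TRUE)
  check_scalar(beta, "beta", 0)
  check_scalar(threshold, "threshold", 0)
  check_scalar(window, "window", 1, TRUE)
  check_scalar(n_cycles, "n_cycles", 0, TRUE)
  check_scalar(mc_samples, "mc_samples", 1, TRUE)
  check_scalar(n_bins, "n_bins", 2, TRUE)
  check_scalar(n_train, "n_train", 1, TRUE)
  check_scalar(noise_variance, "noise_variance", 0)
  if (!is.null(seed)) check_scalar(seed, "seed", 0, TRUE)
  structure(list(environment = environment, encoder = encoder, goal = goal,
                 n_levels = as.integer(n_levels), beta = beta,
                 threshold = threshold, window = as.integer(window),
                 n_cycles = as.integer(n_cycles),
                 mc_samples = as.integer(mc_samples),
                 n_bins = as.integer(n_bins),
                 n_train = as.integer(n_train),
                 noise_variance = noise_variance,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment: %s encoder, goal = %s, %d cycles, seed = %s\n",
              x$encoder, x$goal, x$n_cycles,
              if (is.null(x$seed)) "none" else x$seed))
  print(x$environment)
  invisible(x)
}

config_fields <- c("mode", "theta_low", "theta_high", "hazard",
                   "fixed_sigma", "fixed_mu", "encoder", "goal", "n_levels",
                   "beta", "threshold", "window", "n_cycles", "mc_samples",
                   "n_bins", "n_train", "noise_variance", "seed")

#' Read / write experiment configurations (YAML)
#'
#' \code{load_config} reads a flat YAML file of configuration keys
#' (environment keys \code{mode}, \code{theta_low}, \code{theta_high},
#' \code{hazard}, \code{fixed_sigma}/\code{fixed_mu} plus the
#' \code{\link{experiment_config}} fields), validates it, and rejects
#' unknown keys. \code{save_config} writes the complement; a round trip is
#' lossless.
#'
#' @param path YAML file path.
#' @return \code{load_config}: an \code{\link{experiment_config}}.
#' @export
load_config <- function(path) {
  raw <- yaml::yaml.load_file(path)
  unknown <- setdiff(names(raw), config_fields)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$mode))
    stop("field 'mode' is required ('mean' or 'variance')", call. = FALSE)
  env_args <- list(mode = raw$mode)
  for (f in c("theta_low", "theta_high", "hazard", "fixed_sigma", "fixed_mu"))
    if (!is.null(raw[[f]])) env_args[[f]] <- raw[[f]]
  env <- do.call(env_config, env_args)
  rest <- raw[setdiff(names(raw),
                      c("mode", "theta_low", "theta_high", "hazard",
                        "fixed_sigma", "fixed_mu"))]
  do.call(experiment_config, c(list(environment = env), rest))
}

#' @rdname load_config
#' @param config an \code{\link{experiment_config}}.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  env <- config$environment
  flat <- list(mode = env$mode, theta_low = env$theta_low,
               theta_high = env$theta_high, hazard = env$hazard)
  if (env$mode == "mean") flat$fixed_sigma <- env$fixed_sigma
  else flat$fixed_mu <- env$fixed_mu
  for (f in c("encoder", "goal", "n_levels", "beta", "threshold", "window",
              "n_cycles", "mc_samples", "n_bins", "n_train",
              "noise_variance"))
    flat[[f]] <- config[[f]]
  if (!is.null(config$seed)) flat$seed <- config$seed
  writeLines(yaml::as.yaml(flat), path)
  invisible(path)
}

#' Write a run manifest (JSON)
#'
#' Records the full configuration and a results summary so that a run can
#' be reproduced bit-for-bit from the manifest alone.
#'
#' @param config an \code{\link{experiment_config}}.
#' @param results named list of summary numbers (optional).
#' @param path output JSON path.
#' @export
write_manifest <- function(config, results = list(), path) {
  stopifnot(inherits(config, "experiment_config"))
  env <- config$environment
  manifest <- list(
    package = "adacode",
    version = as.character(utils::packageVersion("adacode")),
    environment = unclass(env),
    config = config[setdiff(names(config), "environment")],
    results = results)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a simulation trace as CSV
#'
#' @param sim a \code{\link{simulate_coding}} result.
#' @param path output CSV path.
#' @export
write_trace <- function(sim, path) {
  stopifnot(inherits(sim, "coding_sim"))
  utils::write.csv(sim$trace, path, row.names = FALSE)
  invisible(path)
}
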