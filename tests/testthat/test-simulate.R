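test_that("identity encoding is lossless for the observer", {
  for (mode in c("mean", "variance")) {
    sim <- simulate_coding(experiment_config(env_config(mode),
                                             encoder = "identity",
                                             n_cycles = 5, seed = 40))
    expect_true(all(sim$trace$inference_error == 0))
    expect_identical(sim$trace$p_low, sim$trace$p_low_ideal)
  }
})

test_that("simulations are reproducible from the seed", {
  cfg <- experiment_config(mean_env(), encoder = "select", threshold = 0.5,
                           n_cycles = 5, seed = 41)
  s1 <- simulate_coding(cfg)
  s2 <- simulate_coding(cfg)
  expect_identical(s1$trace, s2$trace)
})

test_that("inference-goal discretization spikes its entropy rate after switches", {
  cfg <- mean_env()
  bank <- quantizer_bank(cfg, "inference", 3, n_bins = 21, n_train = 20000,
                         seed = 42)
  sim <- simulate_coding(
    experiment_config(cfg, encoder = "discretize", goal = "inference",
                      n_levels = 3, n_cycles = 60, seed = 43),
    policy = bank)
  avg <- cycle_average(sim, drop_first = TRUE)
  er <- avg$entropy_rate
  baseline <- mean(er[c(51:100, 151:200)])
  peak <- max(c(er[1:10], er[101:110]))
  expect_gt(peak / baseline, 1)
  # mean mode: entropy-rate transients symmetric across the two switches
  expect_equal(max(er[1:10]) / baseline, max(er[101:110]) / baseline,
               tolerance = 0.25)
  # variance mode: baselines differ between states
  bankv <- quantizer_bank(var_env(), "inference", 3, n_bins = 21,
                          n_train = 20000, seed = 44)
  simv <- simulate_coding(
    experiment_config(var_env(), encoder = "discretize", goal = "inference",
                      n_levels = 3, n_cycles = 60, seed = 45),
    policy = bankv)
  avgv <- cycle_average(simv, drop_first = TRUE)
  expect_gt(abs(mean(avgv$entropy_rate[151:200]) -
                mean(avgv$entropy_rate[51:100])), 0.2)
})

test_that("speed and accuracy summarize cycle-averaged posteriors", {
  L <- 100
  # jump to the final value on the first post-switch step: speed = 1
  trace <- c(rep(0.95, L), rep(0.05, L))
  sa <- speed_accuracy(trace, L)
  expect_equal(sa$speed_down, 1)
  expect_equal(sa$speed_up, 1)
  expect_equal(sa$accuracy_low, 0.95)
  expect_equal(sa$accuracy_high, 0.95)
  # a trace that never enters the band gets speed 1/phase-length
  osc <- rep(c(0, 4), L)  # oscillates around its final-window mean of 2
  expect_equal(speed_accuracy(osc, L)$speed_down, 1 / L,
               tolerance = 1e-12)
})

test_that("spike patterns are entropy-coded from level usage", {
  cfg <- mean_env()
  fake_bank <- function(bounds) {
    structure(list(config = cfg, goal = "inference", n_levels = 4L,
                   belief_grid = c(0, 1),
                   levels = list(1:4, 1:4),
                   boundaries = list(bounds, bounds)),
              class = "quantizer_bank")
  }
  fake_sim <- function(bank, levels_used) {
    n <- length(levels_used)
    structure(list(
      trace = data.frame(t = 1:n, cycle = rep(1, n), theta = rep(-1, n),
                         bin = rep(1L, n), level = levels_used),
      config = experiment_config(cfg, encoder = "discretize", n_levels = 4,
                                 n_cycles = 1),
      policy = bank, phase_length = n / 2), class = "coding_sim")
  }
  # uniform level usage: patterns {00,10,01,11} average one spike per symbol
  q <- qnorm(c(0.25, 0.5, 0.75), -1, 1)
  r <- spike_raster(fake_sim(fake_bank(c(-Inf, q, Inf)), rep(1:4, 25)))
  expect_equal(mean(r$spikes), 1)
  # all mass on one level: its pattern is [00], zero spikes
  r0 <- spike_raster(fake_sim(fake_bank(c(-Inf, 50, 60, 70, Inf)),
                              rep(1L, 100)))
  expect_true(all(r0$spikes == 0))
})

test_that("metamer probability peaks when the prediction matches the truth", {
  cfg <- mean_env()
  bank1 <- quantizer_bank(cfg, "inference", 1, n_bins = 11, n_train = 5000,
                          seed = 46)
  m1 <- metamer_probability(bank1, n_grid = 5, n_pairs = 1000, seed = 47)
  expect_true(all(m1$p_metamer == 1))

  bank8 <- quantizer_bank(cfg, "inference", 8, n_bins = 21, n_train = 20000,
                          seed = 48)
  m8 <- metamer_probability(bank8, n_grid = 11, n_pairs = 20000, seed = 49)
  expect_equal(which.max(m8$p_metamer), 1L)  # aligned prediction
  # seed-to-seed stability within 3 binomial SDs
  m8b <- metamer_probability(bank8, n_grid = 11, n_pairs = 20000, seed = 50)
  p <- m8$p_metamer
  expect_true(all(abs(m8b$p_metamer - p) <
                    3 * sqrt(2 * p * (1 - p) / 20000) + 1e-9))
})

test_that("transmission noise degrades inference gracefully", {
  cfg <- mean_env()
  bank <- quantizer_bank(cfg, "inference", 3, n_bins = 21, n_train = 20000,
                         seed = 51)
  run <- function(nv) simulate_coding(
    experiment_config(cfg, encoder = "discretize", goal = "inference",
                      n_levels = 3, n_cycles = 40, noise_variance = nv,
                      seed = 52),
    policy = bank)
  # zero noise variance reproduces the noiseless run exactly
  expect_identical(run(0)$trace, run(0)$trace)
  acc <- vapply(c(0, 25), function(nv) {
    sa <- speed_accuracy(cycle_average(run(nv), drop_first = TRUE)$p_low, 100)
    (sa$accuracy_low + sa$accuracy_high) / 2
  }, numeric(1))
  # noise variance far above the state separation destroys the information
  expect_lt(acc[2], 0.75)
  expect_gt(acc[1], 0.9)
})
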