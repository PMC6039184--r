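test_that("analytic misalignment reproduces the Gaussian closed form", {
  expect_equal(analytic_misalignment(0, 1, 0, 1), 0)
  expect_equal(analytic_misalignment(2, 1, 0, 1), 2)        # (d mu)^2 / 2
  expect_equal(analytic_misalignment(0, 2, 0, 1), 1.5)      # high-var state
  expect_equal(analytic_misalignment(0, 1, 0, 2), -0.375)   # low-var state
  # environment maxima used to scale thresholds
  expect_equal(max_misalignment(mean_env()), 2)
  expect_equal(max_misalignment(var_env()), 1.5)
})

test_that("running misalignment estimates the analytic value", {
  # buffer at exactly the expected surprise gives 0
  expect_equal(running_misalignment(rep(1.3, 10), 0.3, 1), 0)
  expect_equal(running_misalignment(numeric(0), 0, 1), 0)

  # stationary matched environment: long-run average near 0
  set.seed(30)
  x <- rnorm(1e5)
  s <- -dnorm(x, log = TRUE)
  m_bar <- mean(s) - 0.5 * log(2 * pi * exp(1))
  expect_lt(abs(m_bar), 4 * sd(s) / sqrt(1e5))

  # unsignaled mean switch of 2: running M converges to the analytic 2.0
  set.seed(31)
  x2 <- rnorm(5000, mean = 2)
  ms <- vapply(10:5000, function(t)
    running_misalignment(x2[(t - 9):t], 0, 1), numeric(1))
  expect_equal(mean(ms), 2, tolerance = 0.1)

  # variance switches reproduce the asymmetric analytic values
  set.seed(32)
  xh <- rnorm(20000, sd = 2)
  mh <- mean(-dnorm(xh, 0, 1, log = TRUE)) - 0.5 * log(2 * pi * exp(1))
  expect_equal(mh, 1.5, tolerance = 0.1)
  xl <- rnorm(20000, sd = 1)
  ml <- mean(-dnorm(xl, 0, 2, log = TRUE)) - 0.5 * log(2 * pi * exp(1) * 4)
  expect_equal(ml, -0.375, tolerance = 0.05)
})

test_that("selection transmits on threshold crossings with an explicit null", {
  expect_false(select_encode(1.2, 0.8, 0, 2)$null)  # zero threshold
  r <- select_encode(1.2, 0.1, 0.5, 2)
  expect_true(r$null)
  expect_true(is.na(r$value))
  # stationary matched beliefs produce sub-threshold misalignment
  set.seed(33)
  x <- rnorm(1000)
  nulls <- vapply(10:1000, function(t) {
    m <- running_misalignment(x[(t - 9):t], 0, 1)
    select_encode(x[t], m, 1, 2)$null
  }, logical(1))
  expect_gt(mean(nulls), 0.95)
})

test_that("null updates carry no stimulus information beyond the prediction", {
  cfg0 <- mean_env(hazard = 0)
  # exact prediction (confident belief), h = 0: belief essentially unchanged
  set.seed(34)
  upd <- replicate(100, null_observer_update(0.999, cfg0, n_samples = 200))
  expect_equal(mean(upd), 0.999, tolerance = 0.002)
  # the MC marginalization matches a large-sample direct oracle
  p0 <- 0.8
  pr <- predicted_params(p0, cfg0)
  set.seed(35)
  z <- rnorm(1e6, pr$mu, pr$sigma)
  num <- dnorm(z, -1, 1) * p0
  oracle <- mean(num / (num + dnorm(z, 1, 1) * (1 - p0)))
  got <- null_observer_update(p0, cfg0, n_samples = 2e5, seed = 36)
  expect_equal(got, oracle, tolerance = 0.005)
  # a single null moves the belief by at most ~ the hazard step plus MC noise
  cfg <- mean_env()
  p1 <- null_observer_update(0.99, cfg, n_samples = 5000, seed = 37)
  expect_lt(abs(p1 - 0.99), 0.05)
  # consecutive nulls are self-confirming: sampling from its own
  # point-conditioned prediction keeps a confident belief confident, so the
  # estimate persists through long untransmitted stretches
  set.seed(38)
  p <- 0.99
  traj <- replicate(50, p <<- null_observer_update(p, cfg, n_samples = 200))
  expect_gt(mean(traj > 0.8), 0.9)
})

test_that("gated transmissions burst after switches; variance mode favors the high state", {
  cfg <- mean_env()
  sim <- simulate_coding(experiment_config(cfg, encoder = "select",
                                           threshold = 0.5, n_cycles = 60,
                                           seed = 37))
  tr <- sim$trace[sim$trace$t > sim$config$window, ]  # drop warm-up
  pos <- ((tr$t - 1) %% 100) + 1  # position within each phase
  expect_lte(median(pos[tr$transmitted]), 10)

  cfgv <- var_env()
  simv <- simulate_coding(experiment_config(cfgv, encoder = "select",
                                            threshold = 0.5, n_cycles = 60,
                                            seed = 38))
  trv <- simv$trace[simv$trace$t > simv$config$window, ]
  frac_high <- mean(trv$transmitted[trv$theta == 2])
  frac_low <- mean(trv$transmitted[trv$theta == 1])
  expect_gt(frac_high, frac_low)
  # high thresholds bias the high-variance estimate low
  simv9 <- simulate_coding(experiment_config(cfgv, encoder = "select",
                                             threshold = 0.9, n_cycles = 60,
                                             seed = 39))
  avg9 <- cycle_average(simv9, drop_first = TRUE)
  expect_lt(mean(avg9$estimate[151:200]), 2 - 0.05)
})
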