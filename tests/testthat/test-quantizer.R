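test_that("Lloyd fit recovers known Gaussian fixed points", {
  set.seed(1)
  x <- rnorm(50000)
  # N = 1: the single level is the training mean
  q1 <- lloyd_fit(x, 1, seed = 2)
  expect_equal(q1$levels, mean(x))
  # N = 2, squared error: +/- sqrt(2/pi), boundary near 0
  q2 <- lloyd_fit(x, 2, seed = 3)
  oracle <- lloyd_max_gaussian(2)
  expect_equal(q2$levels, oracle, tolerance = 0.03)
  expect_lt(abs(q2$boundaries[2]), 0.05)
  # N = 4 against the density-based oracle
  q4 <- lloyd_fit(x, 4, seed = 4)
  expect_equal(q4$levels, lloyd_max_gaussian(4), tolerance = 0.05)
})

test_that("Lloyd average distortion is non-increasing across iterations", {
  set.seed(5)
  for (n_lev in c(2, 3, 5)) {
    q <- lloyd_fit(rnorm(5000), n_lev)
    expect_true(all(diff(q$history) <= 1e-10))
  }
  # generic distortion-function path agrees with the transform path
  set.seed(6)
  x <- rnorm(2000)
  qa <- lloyd_fit(x, 3, seed = 7)
  qb <- lloyd_fit(x, 3, distortion = function(u, v) (u - v)^2, seed = 7)
  expect_equal(qa$levels, qb$levels, tolerance = 1e-10)
})

test_that("inference-optimized levels mirror under stimulus reflection", {
  cfg <- mean_env()
  g <- function(p) function(z) {
    point_estimate(likelihood_update(hazard_propagate(p, cfg$hazard), z, cfg),
                   cfg)
  }
  set.seed(8)
  pr1 <- predicted_params(0.12, cfg)
  x1 <- rnorm(30000, pr1$mu, pr1$sigma)
  qa <- lloyd_fit(x1, 3, transform = g(0.12), seed = 9)
  qb <- lloyd_fit(-x1, 3, transform = g(0.88), seed = 9)
  expect_equal(qa$levels, -rev(qb$levels), tolerance = 0.05)
})

test_that("bank resolution placement depends on the optimization goal", {
  cfg <- mean_env()
  n_bins <- 21
  bi <- quantizer_bank(cfg, "inference", 5, n_bins = n_bins,
                       n_train = 30000, seed = 10)
  br <- quantizer_bank(cfg, "reconstruction", 5, n_bins = n_bins,
                       n_train = 30000, seed = 11)
  # confident bin: belief ~ 0.95 (predicted mean near theta_L)
  b <- which.min(abs(bi$belief_grid - 0.95))
  mu_pred <- predicted_params(bi$belief_grid[b], cfg)$mu
  narrowest_center <- function(bank) {
    bd <- bank$boundaries[[b]]
    w <- diff(bd)
    interior <- 2:(length(w) - 1)
    k <- interior[which.min(w[interior])]
    (bd[k] + bd[k + 1]) / 2
  }
  # inference devotes resolution to surprising stimuli (far from the
  # predicted mean); reconstruction to likely stimuli (near it)
  expect_gt(abs(narrowest_center(bi) - mu_pred),
            abs(narrowest_center(br) - mu_pred))
  # reconstruction bank depends on belief only through the predicted mean:
  # cell widths are translation-invariant across bins in mean mode
  w1 <- diff(br$boundaries[[3]])[2:4]
  w2 <- diff(br$boundaries[[n_bins - 2]])[2:4]
  expect_equal(w1, w2, tolerance = 0.1)
})

test_that("discrete encoding uses nearest bin, lower-index ties, |x| in variance mode", {
  cfg <- mean_env()
  bank <- quantizer_bank(cfg, "reconstruction", 3, n_bins = 11,
                         n_train = 20000, seed = 12)
  b <- 6  # belief 0.5
  lv <- bank$levels[[b]]
  bd <- bank$boundaries[[b]]
  # a stimulus exactly at a level maps to it
  expect_equal(as.integer(encode_discrete(lv[2], bank, 0.5)), 2L)
  # a stimulus at an interior boundary maps to the lower-index level
  expect_equal(as.integer(encode_discrete(bd[2], bank, 0.5)), 1L)
  # variance mode encodes the absolute deviation
  cfgv <- var_env()
  bankv <- quantizer_bank(cfgv, "reconstruction", 3, n_bins = 11,
                          n_train = 20000, seed = 13)
  expect_identical(as.integer(encode_discrete(1.3, bankv, 0.5)),
                   as.integer(encode_discrete(-1.3, bankv, 0.5)))
})

test_that("entropy rate is the cell-usage Shannon entropy in bits", {
  cfg <- mean_env()
  # boundaries at the quartiles of the true distribution: 2 bits
  q <- qnorm(c(0.25, 0.5, 0.75), mean = 1, sd = 1)
  expect_equal(entropy_rate(c(-Inf, q, Inf), 1, cfg), 2)
  # all mass in one cell: 0 bits
  expect_equal(entropy_rate(c(-Inf, 50, 60, Inf), 1, cfg), 0)
  # variance mode uses the folded distribution
  cfgv <- var_env()
  qv <- 2 * qnorm(0.75)  # median of |x| for sd = 2
  expect_equal(entropy_rate(c(0, qv, Inf), 2, cfgv), 1)
})

test_that("more levels trade lower inference error for higher coding cost", {
  cfg <- mean_env()
  errs <- c(); ents <- c()
  for (n_lev in c(2, 4, 8)) {
    bank <- quantizer_bank(cfg, "inference", n_lev, n_bins = 21,
                           n_train = 10000, seed = 14)
    sim <- simulate_coding(
      experiment_config(cfg, encoder = "discretize", goal = "inference",
                        n_levels = n_lev, n_cycles = 30, seed = 15),
      policy = bank)
    errs <- c(errs, mean(sim$trace$inference_error))
    ents <- c(ents, mean(sim$trace$entropy_rate))
  }
  expect_true(all(diff(errs) < 0))
  expect_true(all(diff(ents) > 0))
})
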