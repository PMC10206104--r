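test_that("correlated OU noise is built from a shared drive", {
  # full correlation: identical series
  full <- ou_noise(1000, corr = 1, seed = 2)
  expect_equal(full$i1, full$i2)
  # no noise magnitude: both constant at the mean
  flat <- ou_noise(500, sigma_noise = 0, mean = 0.003, seed = 2)
  expect_true(all(flat$i1 == 0.003))
  expect_true(all(flat$i2 == 0.003))
  # intermediate correlation is recovered empirically
  long <- ou_noise(200000, corr = 0.5, seed = 5)
  expect_equal(stats::cor(long$i1, long$i2), 0.5, tolerance = 0.05)
  expect_error(ou_noise(100, corr = 1.5), "corr")
  expect_error(ou_noise(100, dt = 3, tau_AMPA = 2), "tau_AMPA")
})

test_that("OU noise is stationary with the configured mean and timescale", {
  x <- ou_noise(400000, dt = 0.5, tau_AMPA = 2, sigma_noise = 0.009,
                mean = -0.002, seed = 9)
  expect_lt(abs(mean(x$i1) - (-0.002)), 3e-4)
  # autocorrelation time: fit log-acf over the first 4 ms
  lags <- 1:8
  ac <- vapply(lags, function(l)
    stats::cor(x$i1[-(1:l)], head(x$i1, -l)), numeric(1))
  tau_hat <- -0.5 / stats::coef(stats::lm(log(ac) ~ lags))[2] # dt = 0.5
  expect_equal(unname(tau_hat), 2, tolerance = 0.3)
  # stationary sd of the Euler-discretized OU process
  k <- 0.5 / 2  # dt / tau_AMPA
  sd_euler <- 0.009 * sqrt(k / (1 - (1 - k)^2))
  expect_equal(stats::sd(x$i1), sd_euler, tolerance = 0.02)
})

test_that("evidence currents implement the contrast", {
  e <- evidence_input(0.0118, 6.4)
  expect_equal(unname(e["A"]), 0.0125552)
  expect_equal(unname(e["B"]), 0.0110448)
  expect_equal(unname(diff(evidence_input(0.0118, 0))), 0)
  expect_equal(unname(evidence_input(0, 6.4)), c(0, 0))
})

test_that("deterministic trials follow the evidence and symmetry", {
  p0 <- dm_params(sigma_noise = 0)
  tr <- dm_trial(p0, seed = 1)
  expect_equal(tr$decision, "A")
  expect_gt(tr$integration_time, 0)
  expect_lte(tr$integration_time, p0$trial_max)
  # repeated call: identical
  expect_identical(dm_trial(p0, seed = 1)$integration_time,
                   tr$integration_time)
  # exact symmetry with zero contrast and no noise: never crosses
  psym <- dm_params(sigma_noise = 0, c_prime = 0)
  expect_equal(dm_trial(psym, seed = 1)$decision, "none")
})

test_that("experiments aggregate trials reproducibly and favor the cued option", {
  p <- dm_params()
  one <- dm_experiment(p, n_trials = 1, seed = 44)
  tr <- dm_trial(p, seed = 44)
  expect_equal(one$pct_correct, 100 * (tr$decision == "A"))
  if (tr$decision != "none")
    expect_equal(one$mean_integration_time, tr$integration_time)
  ex <- dm_experiment(p, n_trials = 400, seed = 3)
  expect_gt(ex$pct_correct, 50)    # positive contrast forces direction
  expect_identical(dm_experiment(p, n_trials = 400, seed = 3), ex)
  # statistical label symmetry: reversing the contrast flips outcomes
  pneg <- dm_params(c_prime = -p$c_prime)
  exn <- dm_experiment(pneg, n_trials = 400, seed = 91)
  expect_equal(ex$pct_correct + exn$pct_correct, 100, tolerance = 8)
})

test_that("zero contrast with noise still decides but at chance", {
  p <- dm_params(c_prime = 0)
  ex <- dm_experiment(p, n_trials = 400, seed = 7)
  expect_gt(ex$n_decided, 300)
  expect_equal(ex$pct_correct, 50, tolerance = 8)
})
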