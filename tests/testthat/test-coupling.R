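test_that("regional drive equals the hand-evaluated current bracket", {
  p <- dmf_params(sigma = 0)
  C <- two_node()
  W <- coupling_weights(2, w_LRE = 0.8, w_FFI = 0.2, J = 1.1)
  S_E0 <- c(0.1, 0.2); S_I0 <- c(0.05, 0.02)
  sim <- simulate_bnm(C, duration = 720, tr = 720, seed = 1, params = p,
                      weights = W, fic = FALSE,
                      init = list(S_E = S_E0, S_I = S_I0),
                      record_nodes = 1:2)
  drive <- region_drive(sim, 1)
  # first recorded step uses the unmodified initial state
  expected <- p$w_plus * p$J_NMDA * S_E0[1] +
    p$J_NMDA * 0.8 * 1 * S_E0[2] - 1.1 * S_I0[1]
  expect_equal(drive[1], expected)
  # identical to the generic current evaluation minus the external term
  cur <- synaptic_currents(S_E0, S_I0, p, C, W)
  expect_equal(drive[1], cur$I_E[1] - p$W_E * p$I_0)
  expect_error(region_drive(sim, 3), "not recorded")
  sim2 <- simulate_bnm(C, duration = 720, seed = 1, params = p)
  expect_error(region_drive(sim2, 1), "drive capture")
})

test_that("cohort percentile range follows the linear-interpolation convention", {
  spec <- coupling_spec(ppc_regions = 1, pfc_regions = 2)
  rng <- cohort_range(1:100, spec)
  expect_equal(unname(rng), c(10.9, 90.1))
  expect_equal(cohort_range(sample(1:100), spec), rng)  # order invariant
  expect_error(cohort_range(c(2, 2), spec), "degenerate")
  expect_error(cohort_range(3, spec), "at least two")
})

test_that("drive normalization is exactly affine with the stated bounds", {
  spec <- coupling_spec(ppc_regions = 1, pfc_regions = 2)
  a <- 0.02; b <- 0.09
  expect_equal(normalize_drive(a, a, b, spec), -0.006)
  expect_equal(normalize_drive(b, a, b, spec), 0.001)
  expect_equal(normalize_drive((a + b) / 2, a, b, spec), -0.0025)
  # no clipping outside the source range
  expect_lt(normalize_drive(a - 0.01, a, b, spec), -0.006)
  # affine inverse recovers the input
  set.seed(20)
  x <- stats::runif(100, -0.1, 0.2)
  y <- normalize_drive(x, a, b, spec)
  inv <- (y - spec$a_MJW) * (b - a) / (spec$b_MJW - spec$a_MJW) + a
  expect_lt(max(abs(inv - x)), 1e-12)
  expect_error(normalize_drive(x, 0.5, 0.2, spec), "exceed")
})

test_that("multiscale experiments are reproducible and exchangeable for identical models", {
  C <- tiny_connectome(6, seed = 2, density = 0.5)
  trg <- synth_target(C, seed = 3, burn_in = 3 * MIN, duration = 4 * MIN)
  models <- list(list(C = C, weights = trg$weights),
                 list(C = C, weights = trg$weights),
                 list(C = C, weights = trg$weights))
  spec <- coupling_spec(ppc_regions = 1:3, pfc_regions = 4:6)
  res <- multiscale_dm(models, spec, ppc_node = 2, pfc_node = 5,
                       n_trials = 80, seed = 6,
                       drive_duration = 30 * 1000)
  expect_equal(nrow(res), 3)
  # exchangeable models: spread within Monte-Carlo error
  expect_lt(diff(range(res$pct_correct)), 20)
  res2 <- multiscale_dm(models, spec, ppc_node = 2, pfc_node = 5,
                        n_trials = 80, seed = 6,
                        drive_duration = 30 * 1000)
  expect_identical(res, res2)
  expect_error(multiscale_dm(models, spec, ppc_node = 5, pfc_node = 2,
                             n_trials = 10, seed = 1,
                             drive_duration = 30 * 1000),
               "ppc_node")
})

test_that("large-scale drive amplitude propagates into the circuit's speed-accuracy trade-off", {
  # shared-connectome cohort spanning E/I-ratio centers; models with a
  # higher realized drive amplitude should decide faster and less
  # accurately (the isolated-circuit mean-amplitude effect, end to end)
  C <- synth_connectome(10, density = 0.4, seed = 21)
  centers <- exp(seq(-1.2, 1.2, length.out = 6))
  models <- lapply(seq_along(centers), function(k) {
    trg <- synth_target(C, seed = 300 + k, ei_center = centers[k],
                        coupling_scale = 3, burn_in = 4 * MIN,
                        duration = 10 * MIN)
    list(C = C, weights = trg$weights)
  })
  spec <- coupling_spec(ppc_regions = 1:5, pfc_regions = 6:10)
  res <- multiscale_dm(models, spec, ppc_node = 2, pfc_node = 7,
                       n_trials = 400, seed = 5,
                       drive_duration = 120 * 1000)
  expect_lt(stats::cor(res$drive_ppc_mean, res$mean_integration_time,
                       method = "spearman"), -0.5)
  expect_lt(stats::cor(res$drive_ppc_mean, res$pct_correct,
                       method = "spearman"), 0)
})
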