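test_that("one tuning update follows the learning rule", {
  n <- 3
  rho_trg <- diag(n)
  rho_trg[1, 2] <- rho_trg[2, 1] <- 0.6
  rho_trg[1, 3] <- rho_trg[3, 1] <- -0.2
  rho_trg[2, 3] <- rho_trg[3, 2] <- 0.1
  rho_sim <- diag(n)
  rho_sim[1, 2] <- rho_sim[2, 1] <- 0.4
  rho_sim[1, 3] <- rho_sim[3, 1] <- 0.3
  rho_sim[2, 3] <- rho_sim[3, 2] <- 0.1
  W <- coupling_weights(n, w_LRE = 1, w_FFI = 0.5)
  eta <- 0.1
  up <- tuning_update(rho_trg, rho_sim, W, eta)
  diff <- rho_trg - rho_sim
  rmse1 <- sqrt(mean(diff[1, 2:3]^2))
  expect_equal(up$w_LRE[1, 2], 1 + eta * diff[1, 2] * rmse1)
  expect_equal(up$w_FFI[1, 2], 0.5 - eta * diff[1, 2] * rmse1)
  # asymmetry: (2,1) uses rmse of row 2, not row 1
  rmse2 <- sqrt(mean(diff[2, c(1, 3)]^2))
  expect_equal(up$w_LRE[2, 1], 1 + eta * diff[2, 1] * rmse2)
  expect_false(isTRUE(all.equal(up$w_LRE[1, 2] - 1, up$w_LRE[2, 1] - 1)))
  # diagonal untouched
  expect_equal(diag(up$w_LRE), diag(W$w_LRE))
})

test_that("tuning update clamps at zero and respects the structural mask", {
  n <- 2
  rho_trg <- matrix(c(1, -0.5, -0.5, 1), 2)
  rho_sim <- matrix(c(1, 0.5, 0.5, 1), 2)   # diff = -1
  W <- coupling_weights(n, w_LRE = 0.005, w_FFI = 0.005)
  up <- tuning_update(rho_trg, rho_sim, W, eta_EI = 0.1)
  expect_equal(up$w_LRE[1, 2], 0)           # would go negative: clamped
  expect_gt(up$w_FFI[1, 2], 0.005)
  # perfect fit changes nothing
  same <- tuning_update(rho_trg, rho_trg, W, eta_EI = 0.1)
  expect_equal(same$w_LRE, W$w_LRE)
  expect_equal(same$w_FFI, W$w_FFI)
  # missing structural connections are never updated
  C <- matrix(c(0, 1, 0, 0), 2, 2)   # only C[2,1] > 0
  up2 <- tuning_update(rho_trg, rho_sim, coupling_weights(n, 1, 1),
                       eta_EI = 0.1, C = C)
  expect_equal(up2$w_LRE[1, 2], 1)          # C[1,2] = 0: untouched
  expect_false(isTRUE(all.equal(up2$w_LRE[2, 1], 1)))
  expect_error(tuning_update(rho_trg, rho_sim * NaN, W, 0.1),
               "non-finite")
})

test_that("zero learning rate leaves weights unchanged with a flat trace", {
  C <- tiny_connectome(6)
  rho <- diag(6)
  fit <- fit_ei(C, rho, seed = 3, validate = FALSE,
                schedule = tuning_schedule(n_stages = 2,
                                           stage_duration = 2 * MIN,
                                           eta_start = 0,
                                           window_start = 20))
  expect_equal(fit$weights$w_LRE, matrix(0.5, 6, 6))
  expect_equal(fit$weights$w_FFI, matrix(0.5, 6, 6))
  expect_true(all(fit$trace$mean_w_lre == fit$trace$mean_w_lre[1]))
})

test_that("E-only mode never touches feedforward inhibition", {
  C <- tiny_connectome(6)
  set.seed(8)
  rho <- diag(6); rho[upper.tri(rho)] <- stats::runif(15, -0.3, 0.5)
  rho[lower.tri(rho)] <- t(rho)[lower.tri(rho)]
  fit <- fit_ei(C, rho, seed = 3, mode = "E_only", validate = FALSE,
                schedule = tuning_schedule(n_stages = 2,
                                           stage_duration = 2 * MIN,
                                           window_start = 20))
  expect_equal(fit$weights$w_FFI, matrix(0, 6, 6))
  expect_false(isTRUE(all.equal(fit$weights$w_LRE, matrix(1, 6, 6))))
  expect_true(all(fit$weights$w_LRE >= 0))
})

test_that("global-scalar variant with a degenerate grid reproduces the untuned model", {
  C <- tiny_connectome(6)
  set.seed(9)
  rho <- diag(6); rho[upper.tri(rho)] <- stats::runif(15, -0.3, 0.5)
  rho[lower.tri(rho)] <- t(rho)[lower.tri(rho)]
  v <- fit_variant(C, rho, mode = "global_scalar", grid = 1.0, seed = 4,
                   scalar_burn = MIN, scalar_duration = 2 * MIN)
  expect_equal(v$summary$G, 1.0)
  # identical to simulating the untuned model directly
  sim <- simulate_bnm(C, duration = 3 * MIN, seed = derive_seed(4, 1),
                      fic = TRUE)
  keep <- seq_len(ncol(sim$bold)) > MIN / sim$tr
  fc <- compute_fc(sim$bold[, keep])
  ut <- upper.tri(fc)
  expect_equal(v$summary$fc_r, stats::cor(fc[ut], rho[ut]))
  expect_error(fit_variant(C, rho, mode = "global_scalar",
                           grid = numeric(0)), "empty grid")
})

test_that("fitted weights stay nonnegative and the trace is well-formed", {
  C <- tiny_connectome(8, seed = 5, density = 0.4)
  set.seed(10)
  rho <- diag(8); rho[upper.tri(rho)] <- stats::runif(28, -0.4, 0.6)
  rho[lower.tri(rho)] <- t(rho)[lower.tri(rho)]
  fit <- fit_ei(C, rho, seed = 6, validate = FALSE,
                schedule = tuning_schedule(n_stages = 3,
                                           stage_duration = 3 * MIN,
                                           window_start = 30))
  expect_true(all(fit$weights$w_LRE >= 0))
  expect_true(all(fit$weights$w_FFI >= 0))
  expect_equal(sort(unique(fit$trace$stage)), 1:3)
  expect_true(all(diff(fit$trace$tr) > 0))
  # learning rate halves and window doubles per stage
  per <- dplyr::distinct(fit$trace, stage, eta, window)
  expect_equal(per$eta, 0.1 / 2^(0:2))
  expect_equal(per$window, 30 * 2^(0:2))
})
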