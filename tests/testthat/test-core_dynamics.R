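test_that("transfer function matches a high-precision reference, including the singularity", {
  p <- dmf_params()
  # removable singularity: limit is 1/d
  expect_equal(transfer_rate(p$b_E / p$a_E, p$a_E, p$b_E, p$d_E),
               1 / p$d_E, tolerance = 1e-12)
  # asymptotic limit: rate goes to zero for strongly negative currents
  expect_lt(transfer_rate(-100, p$a_E, p$b_E, p$d_E), 1e-6)
  # grid of currents including a neighborhood of the singularity
  I_grid <- c(seq(-0.5, 1.5, length.out = 201),
              p$b_E / p$a_E + 10^seq(-12, -2, length.out = 30),
              p$b_E / p$a_E - 10^seq(-12, -2, length.out = 30))
  got <- transfer_rate(I_grid, p$a_E, p$b_E, p$d_E)
  want <- ref_transfer(I_grid, p$a_E, p$b_E, p$d_E)
  expect_lt(max(abs(got - want) / pmax(abs(want), 1e-12)), 1e-10)
  expect_true(all(got >= 0))
  # inhibitory constants too
  gi <- transfer_rate(I_grid, p$a_I, p$b_I, p$d_I)
  wi <- ref_transfer(I_grid, p$a_I, p$b_I, p$d_I)
  expect_lt(max(abs(gi - wi) / pmax(abs(wi), 1e-12)), 1e-10)
  expect_error(transfer_rate(NaN, 310, 125, 0.16), "invalid current")
})

test_that("synaptic currents follow the model equations", {
  p <- dmf_params()
  C <- two_node()
  W <- coupling_weights(2)
  # zero state: currents reduce to the external terms
  z <- synaptic_currents(c(0, 0), c(0, 0), p, C, W)
  expect_equal(z$I_E, rep(p$W_E * p$I_0, 2))
  expect_equal(z$I_I, rep(p$W_I * p$I_0, 2))
  # hand evaluation on the two-node network
  h <- synaptic_currents(c(0.1, 0.2), c(0, 0), p, C, W)
  expect_equal(h$I_E[1], 0.382 + 1.4 * 0.15 * 0.1 + 0.15 * 0.2)  # 0.433
  expect_equal(h$I_E[2], 0.382 + 1.4 * 0.15 * 0.2 + 0.15 * 0.1)
  # with long-range excitation off, I_E is independent of the connectome
  W0 <- coupling_weights(2, w_LRE = 0, w_FFI = 1)
  a <- synaptic_currents(c(0.3, 0.7), c(0.1, 0.1), p, C, W0)
  b <- synaptic_currents(c(0.3, 0.7), c(0.1, 0.1), p, 5 * C, W0)
  expect_equal(a$I_E, b$I_E)
  expect_false(isTRUE(all.equal(a$I_I, b$I_I)))
  expect_error(synaptic_currents(c(0, 0, 0), c(0, 0), p, C, W),
               "dimension mismatch")
})

test_that("deterministic runs are bitwise reproducible and noiseless dynamics settle", {
  C <- two_node()
  s1 <- simulate_bnm(C, duration = 2 * MIN, seed = 77)
  s2 <- simulate_bnm(C, duration = 2 * MIN, seed = 77)
  expect_identical(s1$bold, s2$bold)
  expect_identical(s1$weights$J, s2$weights$J)
  s3 <- simulate_bnm(C, duration = 2 * MIN, seed = 78)
  expect_false(identical(s1$bold, s3$bold))
  # sigma = 0, no FIC: TR samples become identical after transient decay
  p0 <- dmf_params(sigma = 0)
  sd0 <- simulate_bnm(C, duration = 5 * MIN, seed = 1, params = p0,
                      fic = FALSE)
  late <- sd0$gating_E[, 300:ncol(sd0$gating_E)]
  expect_lt(max(apply(late, 1, function(x) diff(range(x)))), 1e-8)
})

test_that("noiseless linear-decay limit follows the gating time constant", {
  # gamma_E = 0 decouples the excitatory gating: pure exponential decay
  p <- dmf_params(sigma = 0, gamma_E = 0)
  C <- two_node()
  s <- simulate_bnm(C, duration = 720, tr = 720, seed = 1, params = p,
                    fic = FALSE,
                    init = list(S_E = c(0.5, 0.5), S_I = c(0.1, 0.1)))
  # Euler product after 720 steps of dt = 1 ms
  expect_equal(s$gating_E[1, 1], 0.5 * (1 - 1 / p$tau_E)^720,
               tolerance = 1e-10)
})

test_that("noiseless steady state matches an independent root-finding oracle", {
  p <- dmf_params(sigma = 0)
  C1 <- matrix(0, 1, 1)
  W <- coupling_weights(1, J = 1)
  f <- function(s) {
    cur <- synaptic_currents(s[1], s[2], p, C1, W)
    rE <- transfer_rate(cur$I_E, p$a_E, p$b_E, p$d_E)
    rI <- transfer_rate(cur$I_I, p$a_I, p$b_I, p$d_I)
    c(-s[1] / p$tau_E + (1 - s[1]) * p$gamma_E * rE,
      -s[2] / p$tau_I + p$gamma_I * rI)
  }
  root <- pracma::fsolve(f, c(0.2, 0.05))$x
  sim <- simulate_bnm(C1, duration = 10 * MIN, seed = 1, params = p,
                      weights = W, fic = FALSE)
  got <- c(sim$state$S_E, sim$state$S_I)
  expect_lt(max(abs(got - root)), 1e-6)
})

test_that("gating stays within [0, 1] and noise increases gating variance", {
  C1 <- matrix(0, 1, 1)
  sims <- lapply(c(0.005, 0.01, 0.02), function(sg)
    simulate_bnm(C1, duration = 5 * MIN, seed = 9,
                 params = dmf_params(sigma = sg), fic = FALSE))
  for (s in sims) {
    expect_true(all(s$gating_E >= 0 & s$gating_E <= 1))
  }
  v <- vapply(sims, function(s) stats::var(s$gating_E[1, ]), numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("euler step size does not change the noiseless steady state", {
  p <- dmf_params(sigma = 0)
  C <- two_node()
  a <- simulate_bnm(C, duration = 5 * MIN, dt = 1, seed = 1, params = p,
                    fic = FALSE)
  b <- simulate_bnm(C, duration = 5 * MIN, dt = 0.1, seed = 1, params = p,
                    fic = FALSE)
  expect_equal(a$state$S_E, b$state$S_E, tolerance = 1e-5)
})

test_that("connectome validation rejects malformed input", {
  expect_error(simulate_bnm(matrix(1, 2, 3), duration = 2000),
               "square")
  expect_error(simulate_bnm(matrix(-1, 2, 2), duration = 2000))
  M <- matrix(1, 2, 2)  # nonzero diagonal
  expect_error(simulate_bnm(M, duration = 2000), "diagonal")
})
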