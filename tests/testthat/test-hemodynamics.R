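test_that("resting drive keeps BOLD at baseline", {
  drive <- matrix(0, 2, 20000)
  b <- bold_from_gating(drive, dt = 1, tr = 720)
  expect_lt(max(abs(b)), 1e-12)
})

test_that("a boxcar drive produces one positive transient that returns to baseline", {
  drive <- matrix(0, 1, 40000)
  drive[1, 5001:5500] <- 0.1
  b <- bold_from_gating(drive, dt = 1, tr = 720)
  expect_gt(max(b), 1e-4)              # clear positive response
  expect_lt(abs(b[1, ncol(b)]), 1e-4)  # back near baseline at the end
  peak <- which.max(b[1, ])
  expect_gt(peak, 5000 / 720)          # peak after stimulus onset
  expect_lt(peak, ncol(b))             # and before the end
})

test_that("hemodynamic integration agrees with an independent ODE solver", {
  p <- hemo_params()
  tmax <- 30000
  drive_fun <- function(t) ifelse(t >= 5000 & t < 5500, 0.1, 0)
  rhs <- function(t, y, parms) {
    s <- y[1]; f <- y[2]; v <- y[3]; q <- y[4]
    dts <- 1 / 1000  # states evolve in seconds; t is in ms
    list(dts * c(drive_fun(t) - p$kappa * s - p$gamma_h * (f - 1),
                 s,
                 (f - v^(1 / p$alpha)) / p$tau_h,
                 (f * (1 - (1 - p$rho_h)^(1 / f)) / p$rho_h -
                    v^(1 / p$alpha) * q / v) / p$tau_h))
  }
  sol <- deSolve::lsoda(c(0, 1, 1, 1), seq(0, tmax, by = 720), rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  ref_bold <- p$V0 * (p$k1 * (1 - sol[, 5]) + p$k2 * (1 - sol[, 5] /
                        sol[, 4]) + p$k3 * (1 - sol[, 4]))
  drive <- matrix(drive_fun(seq_len(tmax) - 1), 1)
  got <- bold_from_gating(drive, dt = 1, tr = 720, params = p)
  # Euler at 1 ms vs adaptive high-accuracy solution
  scale <- max(abs(ref_bold))
  expect_lt(sqrt(mean((got[1, ] - ref_bold[-1])^2)) / scale, 5e-3)
})

test_that("nodes are independent and permutation-equivariant", {
  set.seed(4)
  drive <- matrix(stats::runif(3 * 10000, 0, 0.2), 3)
  b <- bold_from_gating(drive, dt = 1, tr = 500)
  bp <- bold_from_gating(drive[c(2, 3, 1), ], dt = 1, tr = 500)
  expect_equal(bp, b[c(2, 3, 1), ])
  # identical drives give identical BOLD rows
  b2 <- bold_from_gating(drive[c(1, 1), ], dt = 1, tr = 500)
  expect_equal(b2[1, ], b2[2, ])
})

test_that("halving dt changes the BOLD by less than 0.1 percent RMS", {
  set.seed(5)
  slow <- stats::filter(stats::rnorm(8000, 0.1, 0.02), rep(1 / 50, 50),
                        sides = 1)
  slow[is.na(slow)] <- 0.1
  drive1 <- matrix(as.numeric(slow), 1)
  drive05 <- matrix(rep(drive1[1, ], each = 2), 1)
  b1 <- bold_from_gating(drive1, dt = 1, tr = 400)
  b05 <- bold_from_gating(drive05, dt = 0.5, tr = 400)
  rel <- sqrt(mean((b1 - b05)^2)) / stats::sd(b1)
  expect_lt(rel, 1e-3)
})

test_that("dt must divide tr", {
  expect_error(bold_from_gating(matrix(0, 1, 100), dt = 7, tr = 720),
               "divide")
})
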