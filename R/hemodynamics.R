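#' Balloon-Windkessel BOLD forward model
#'
#' Integrates the four hemodynamic state equations (vasodilatory signal s,
#' inflow f, venous volume v, deoxyhemoglobin q) per node with the neural
#' drive given by the excitatory synaptic gating, and emits the static
#' nonlinear BOLD readout sampled every `tr`. Explicit Euler at the neural
#' step `dt` is used; the dynamics are slow relative to any sensible `dt`.
#'
#' @param S_E_series Neural drive, matrix node x time at resolution `dt`.
#' @param dt Step of the input series (ms); must divide `tr`.
#' @param tr Output sampling period (ms).
#' @param params A [hemo_params()] list.
#' @param state Optional initial 4 x n state (rows s, f, v, q); default
#'   rest (0, 1, 1, 1).
#' @return Matrix node x TR of BOLD signal (in units of the resting blood
#'   volume fraction V0).
#' @export
#' @examples
#' drive <- matrix(0.0, 1, 20000)
#' drive[1, 2001:2500] <- 0.1   # 500 ms boxcar
#' b <- bold_from_gating(drive, dt = 1, tr = 720)
bold_from_gating <- function(S_E_series, dt, tr, params = hemo_params(),
                             state = NULL) {
  S_E_series <- as.matrix(S_E_series)
  if (any(!is.finite(S_E_series))) stop("drive series must be finite")
  steps_per_tr <- tr / dt
  if (abs(steps_per_tr - round(steps_per_tr)) > 1e-9)
    stop("dt must divide tr")
  steps_per_tr <- round(steps_per_tr)
  n <- nrow(S_E_series)
  nt <- ncol(S_E_series)
  n_tr <- nt %/% steps_per_tr
  if (is.null(state)) {
    state <- rbind(s = rep(0, n), f = rep(1, n), v = rep(1, n),
                   q = rep(1, n))
  }
  s <- state[1, ]; f <- state[2, ]; v <- state[3, ]; q <- state[4, ]
  p <- params
  dts <- dt / 1000
  out <- matrix(NA_real_, n, n_tr)
  k <- 0L
  for (t in seq_len(nt)) {
    fv <- v^(1 / p$alpha)
    Ef <- 1 - (1 - p$rho_h)^(1 / f)
    s_new <- s + dts * (S_E_series[, t] - p$kappa * s - p$gamma_h * (f - 1))
    f_new <- f + dts * s
    v_new <- v + dts * (f - fv) / p$tau_h
    q_new <- q + dts * (f * Ef / p$rho_h - fv * q / v) / p$tau_h
    if (any(f_new <= 0) || any(v_new <= 0) || any(q_new <= 0))
      stop("hemodynamic state became non-positive: use a smaller dt")
    s <- s_new; f <- f_new; v <- v_new; q <- q_new
    if (t %% steps_per_tr == 0) {
      k <- k + 1L
      out[, k] <- p$V0 * (p$k1 * (1 - q) + p$k2 * (1 - q / v) +
                            p$k3 * (1 - v))
    }
  }
  out
}
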