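#' Firing-rate transfer function
#'
#' Converts an input current into a population firing rate via
#' `(a I - b) / (1 - exp(-d (a I - b)))`. The removable singularity at
#' `a I = b` is evaluated by its limit `1/d`; the function is continuous
#' and nonnegative on the physical branch.
#'
#' @param I Input current (nA); may be a vector.
#' @param a Gain (Hz/nA), > 0.
#' @param b Threshold (Hz).
#' @param d Shape constant (s), > 0.
#' @return Firing rate(s) in Hz.
#' @export
#' @examples
#' transfer_rate(0.382, 310, 125, 0.16)
transfer_rate <- function(I, a, b, d) {
  stopifnot(a > 0, d > 0)
  if (any(!is.finite(I))) stop("invalid current: non-finite input")
  vapply(I, transfer_rate_cpp, numeric(1), a = a, b = b, d = d)
}

#' Synaptic input currents of the large-scale model
#'
#' Evaluates the excitatory and inhibitory input currents of every node
#' given the instantaneous gating state: local recurrence, long-range
#' excitation weighted by `w_LRE`, feedforward inhibition weighted by
#' `w_FFI`, and local inhibitory feedback `J`.
#'
#' @param S_E,S_I Gating vectors (one entry per node, in `[0, 1]`).
#' @param params A [dmf_params()] list.
#' @param C Structural connectome matrix (n x n, nonnegative, zero
#'   diagonal).
#' @param W A [coupling_weights()] list.
#' @return A list with numeric vectors `I_E` and `I_I` (nA).
#' @export
synaptic_currents <- function(S_E, S_I, params, C, W) {
  n <- length(S_E)
  if (length(S_I) != n || nrow(C) != n || ncol(C) != n || W$n != n)
    stop("dimension mismatch between state, connectome and weights")
  I_E <- params$W_E * params$I_0 +
    params$w_plus * params$J_NMDA * S_E +
    params$J_NMDA * as.vector((W$w_LRE * C) %*% S_E) -
    W$J * S_I
  I_I <- params$W_I * params$I_0 +
    params$J_NMDA * S_E +
    params$J_NMDA * as.vector((W$w_FFI * C) %*% S_E) -
    S_I
  list(I_E = I_E, I_I = I_I)
}

#' Inhibitory-plasticity weight change
#'
#' The feedback-inhibition-control rule
#' `delta = eta_FIC * (pre * post - rho_0 * pre)`: inhibition onto an
#' excitatory population strengthens while that population fires above the
#' `rho_0` set point and weakens below it, gated by the presynaptic
#' (inhibitory) rate.
#'
#' @param pre Presynaptic (inhibitory) window-averaged rate(s), Hz.
#' @param post Postsynaptic (excitatory) window-averaged rate(s), Hz.
#' @param p A [fic_params()] list.
#' @return Weight change(s) in nA.
#' @export
#' @examples
#' fic_delta(2, 6, fic_params())  # 0.004
fic_delta <- function(pre, post, p = fic_params()) {
  if (any(pre < 0) || any(post < 0)) stop("rates must be nonnegative")
  p$eta_FIC * (pre * post - p$rho_0 * pre)
}

#' Apply one FIC update to the inhibitory weight vector
#'
#' @param J Current local inhibitory weights (nA).
#' @param pre,post Window-averaged inhibitory / excitatory rates per node.
#' @param p A [fic_params()] list.
#' @return Updated weight vector, clamped at `p$J_min`.
#' @export
apply_fic <- function(J, pre, post, p = fic_params()) {
  pmax(p$J_min, J + fic_delta(pre, post, p))
}

#' One synchronous E/I-tuning update
#'
#' For every connected pair (i, j) the difference between the target and
#' the windowed simulated FC is scaled by the learning rate and by the
#' row-wise FC misfit `rmse_i` (the RMS deviation between rows i of the
#' two FC matrices, diagonal excluded), added to `w_LRE` and subtracted
#' from `w_FFI`; weights falling to or below zero are clamped at zero.
#' Connections (i, j) and (j, i) receive different step sizes through
#' `rmse_i` versus `rmse_j`. All updates use the same FC snapshot.
#'
#' @param rho_trg,rho_sim Target and windowed simulated FC matrices.
#' @param W A [coupling_weights()] list.
#' @param eta_EI Learning rate.
#' @param C Optional connectome; updates are restricted to entries with
#'   `C > 0` (self-connections are never updated).
#' @return The updated [coupling_weights()] list.
#' @export
tuning_update <- function(rho_trg, rho_sim, W, eta_EI, C = NULL) {
  n <- W$n
  stopifnot(all(dim(rho_trg) == n), all(dim(rho_sim) == n))
  if (any(!is.finite(rho_sim)))
    stop("windowed FC contains non-finite values (zero-variance window): ",
         "increase the FC window or burn-in")
  diff <- rho_trg - rho_sim
  off <- diff; diag(off) <- NA
  rmse <- sqrt(rowMeans(off^2, na.rm = TRUE))
  step <- eta_EI * diff * rmse          # row i scaled by rmse_i
  mask <- if (is.null(C)) !diag(n) else (C > 0 & !diag(n))
  step[!mask] <- 0
  w_lre <- W$w_LRE + step
  w_ffi <- W$w_FFI - step
  w_lre[w_lre <= 0] <- 0
  w_ffi[w_ffi <= 0] <- 0
  coupling_weights(n, w_lre, w_ffi, W$J)
}

#' Evidence currents to the two parietal populations
#'
#' Returns the stimulus currents `I_e (1 + c'/100)` to the favored
#' population A and `I_e (1 - c'/100)` to population B.
#'
#' @param I_e Evidence scale (nA), >= 0.
#' @param c_prime Contrast in percent.
#' @return Named numeric vector `c(A = , B = )` (nA).
#' @export
#' @examples
#' evidence_input(0.0118, 6.4)
evidence_input <- function(I_e, c_prime) {
  stopifnot(I_e >= 0)
  c(A = I_e * (1 + c_prime / 100), B = I_e * (1 - c_prime / 100))
}

#' E/I-ratio to coupling weights under the unit-sum constraint
#'
#' Maps a ratio `q = w_LRE / w_FFI` onto the pair
#' `w_LRE = q / (1 + q)`, `w_FFI = 1 / (1 + q)`, which keeps the total
#' long-range input `w_LRE + w_FFI = 1` constant while the ratio varies.
#'
#' @param q E/I ratio(s), > 0.
#' @return A tibble with columns `ratio`, `w_lre`, `w_ffi`.
#' @export
ei_ratio_weights <- function(q) {
  stopifnot(all(q > 0))
  tibble::tibble(ratio = q, w_lre = q / (1 + q), w_ffi = 1 / (1 + q))
}
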