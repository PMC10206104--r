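#' Dynamic mean-field model parameters
#'
#' Canonical parameter set of the reduced Wong-Wang excitatory/inhibitory
#' neural-mass model used for each network node. Every node holds one
#' excitatory and one inhibitory population; currents are in nA, times in
#' ms, rates in Hz.
#'
#' @param W_E,W_I External-input scaling of the excitatory / inhibitory
#'   population (dimensionless).
#' @param I_0 Overall effective external current (nA).
#' @param w_plus Local excitatory recurrence (dimensionless).
#' @param J_NMDA Excitatory synaptic coupling strength (nA).
#' @param a_E,b_E,d_E Gain (Hz/nA), threshold (Hz) and shape (s) of the
#'   excitatory transfer function.
#' @param a_I,b_I,d_I Same for the inhibitory transfer function.
#' @param tau_E,tau_I Synaptic gating time constants (ms).
#' @param gamma_E,gamma_I Saturation rates (1/ms per Hz).
#' @param sigma Noise amplitude of the gating dynamics (nA).
#' @return A named list of class `dmf_params`.
#' @export
#' @examples
#' p <- dmf_params()
#' transfer_rate(p$b_E / p$a_E, p$a_E, p$b_E, p$d_E)  # 1/d_E = 6.25 Hz
dmf_params <- function(W_E = 1.0, W_I = 0.7, I_0 = 0.382, w_plus = 1.4,
                       J_NMDA = 0.15,
                       a_E = 310, b_E = 125, d_E = 0.16,
                       a_I = 615, b_I = 177, d_I = 0.087,
                       tau_E = 100, tau_I = 10,
                       gamma_E = 0.641e-3, gamma_I = 1.0e-3,
                       sigma = 0.01) {
  stopifnot(tau_E > 0, tau_I > 0, a_E > 0, a_I > 0, d_E > 0, d_I > 0,
            sigma >= 0)
  structure(list(W_E = W_E, W_I = W_I, I_0 = I_0, w_plus = w_plus,
                 J_NMDA = J_NMDA, a_E = a_E, b_E = b_E, d_E = d_E,
                 a_I = a_I, b_I = b_I, d_I = d_I, tau_E = tau_E,
                 tau_I = tau_I, gamma_E = gamma_E, gamma_I = gamma_I,
                 sigma = sigma),
            class = "dmf_params")
}

#' Balloon-Windkessel hemodynamic parameters
#'
#' Constants of the hemodynamic forward model that converts excitatory
#' synaptic gating into BOLD signal (Friston-type balloon model).
#'
#' @param kappa Vasodilatory signal decay rate (1/s).
#' @param gamma_h Flow-dependent elimination rate (1/s).
#' @param tau_h Hemodynamic transit time (s).
#' @param alpha Grubb vessel stiffness exponent, in (0, 1).
#' @param rho_h Resting oxygen extraction fraction.
#' @param V0 Resting blood volume fraction.
#' @param k1,k2,k3 BOLD readout coefficients; defaults follow the classic
#'   1.5T readout `k1 = 7 rho_h`, `k2 = 2`, `k3 = 2 rho_h - 0.2`.
#' @return A named list of class `hemo_params`.
#' @export
hemo_params <- function(kappa = 0.65, gamma_h = 0.41, tau_h = 0.98,
                        alpha = 0.32, rho_h = 0.34, V0 = 0.02,
                        k1 = 7 * rho_h, k2 = 2, k3 = 2 * rho_h - 0.2) {
  stopifnot(kappa > 0, gamma_h > 0, tau_h > 0, alpha > 0, alpha < 1,
            rho_h > 0, V0 > 0)
  structure(list(kappa = kappa, gamma_h = gamma_h, tau_h = tau_h,
                 alpha = alpha, rho_h = rho_h, V0 = V0,
                 k1 = k1, k2 = k2, k3 = k3),
            class = "hemo_params")
}

#' Feedback inhibition control (FIC) parameters
#'
#' Homeostatic inhibitory-plasticity settings that drive each excitatory
#' population's long-term firing rate to the `rho_0` set point by adjusting
#' the local inhibitory weight `J_i`.
#'
#' @param eta_FIC Learning rate of the plasticity rule.
#' @param rho_0 Target excitatory firing rate (Hz).
#' @param update_interval Time between plasticity updates (ms).
#' @param J_min Lower clamp on the inhibitory weights (nA).
#' @return A named list of class `fic_params`.
#' @export
fic_params <- function(eta_FIC = 0.001, rho_0 = 4.0, update_interval = 720,
                       J_min = 0.001) {
  stopifnot(eta_FIC > 0, rho_0 > 0, update_interval > 0, J_min >= 0)
  structure(list(eta_FIC = eta_FIC, rho_0 = rho_0,
                 update_interval = update_interval, J_min = J_min),
            class = "fic_params")
}

#' Per-connection coupling weights
#'
#' Container for the long-range excitation multipliers `w_LRE`, the
#' feedforward inhibition multipliers `w_FFI` (both n x n, multiplying the
#' structural connectome entrywise) and the per-node local inhibitory
#' feedback strengths `J` (nA). The default state `w_LRE = 1`,
#' `w_FFI = 0` reproduces the classical model without feedforward
#' inhibition.
#'
#' @param n Number of nodes.
#' @param w_LRE,w_FFI Scalars or n x n nonnegative matrices.
#' @param J Scalar or length-n nonnegative vector (nA).
#' @return A list of class `coupling_weights`.
#' @export
coupling_weights <- function(n, w_LRE = 1, w_FFI = 0, J = 1) {
  if (length(w_LRE) == 1) w_LRE <- matrix(w_LRE, n, n)
  if (length(w_FFI) == 1) w_FFI <- matrix(w_FFI, n, n)
  J <- as.vector(J)
  if (length(J) == 1) J <- rep(J, n)
  stopifnot(is.matrix(w_LRE), is.matrix(w_FFI),
            all(dim(w_LRE) == n), all(dim(w_FFI) == n), length(J) == n,
            all(is.finite(w_LRE)), all(is.finite(w_FFI)), all(is.finite(J)),
            all(w_LRE >= 0), all(w_FFI >= 0), all(J >= 0))
  structure(list(w_LRE = w_LRE, w_FFI = w_FFI, J = J, n = n),
            class = "coupling_weights")
}

#' Staged learning schedule for E/I-tuning
#'
#' The fit proceeds in stages; per stage the learning rate is halved and
#' the trailing FC window doubled. The reference configuration uses six
#' stages of 10 h biological time each; the default here is a desk-scale
#' schedule of six stages of 20 min that retains the same staging rules.
#'
#' @param n_stages Number of stages (>= 1).
#' @param stage_duration Biological time per stage (ms).
#' @param eta_start Initial learning rate.
#' @param window_start Initial FC window (TR count, >= 2).
#' @return A list of class `tuning_schedule`.
#' @export
tuning_schedule <- function(n_stages = 6, stage_duration = 20 * 60 * 1000,
                            eta_start = 0.1, window_start = 150) {
  stopifnot(n_stages >= 1, stage_duration > 0, eta_start >= 0,
            window_start >= 2)
  structure(list(n_stages = n_stages, stage_duration = stage_duration,
                 eta_start = eta_start, window_start = window_start),
            class = "tuning_schedule")
}

#' Paper-faithful tuning schedule (six stages of 10 hours)
#' @rdname tuning_schedule
#' @export
tuning_schedule_full <- function() {
  tuning_schedule(n_stages = 6, stage_duration = 10 * 3600 * 1000,
                  eta_start = 0.1, window_start = 150)
}

#' Frontoparietal decision-circuit parameters
#'
#' Constants of the four-population winner-take-all circuit (populations
#' A/B in PPC and A/B in PFC). The 4 x 4 coupling matrix `J_syn` is built
#' from six structural couplings: within-module self-excitation `J_s` and
#' cross-inhibition `J_c`, feedforward (PPC to PFC) same-label excitation
#' `J_ff` and opposite-label inhibition `J_ffc`, and the feedback
#' (PFC to PPC) counterparts `J_fb`, `J_fbc`.
#'
#' @param J_s,J_c,J_ff,J_ffc,J_fb,J_fbc Structural couplings (nA).
#' @param I0_dm Background current (nA).
#' @param a,b,c Transfer-function gain (Hz/nA), threshold (Hz), shape (s).
#' @param tau NMDA gating time constant (ms).
#' @param gamma Saturation rate (1/ms per Hz).
#' @param tau_AMPA OU noise time constant (ms).
#' @param sigma_noise OU noise magnitude (nA).
#' @param threshold Decision firing-rate threshold (Hz).
#' @param I_e Evidence input scale (nA).
#' @param c_prime Evidence contrast (percent); option A is favored.
#' @param trial_max Maximum trial duration after stimulus onset (ms).
#' @param settle Noise-only settling time before stimulus onset (ms).
#' @param dt Integration step of the circuit (ms).
#' @param J_syn Optional explicit 4 x 4 coupling matrix overriding the six
#'   structural couplings (rows receive, columns send; population order
#'   A_PPC, B_PPC, A_PFC, B_PFC).
#' @return A list of class `dm_params`.
#' @export
dm_params <- function(J_s = 0.373, J_c = 0.0798, J_ff = 0.0777,
                      J_ffc = 0.0927, J_fb = 0.0407, J_fbc = 0.0173,
                      I0_dm = 0.323, a = 270, b = 108, c = 0.154,
                      tau = 60, gamma = 0.641e-3, tau_AMPA = 2,
                      sigma_noise = 0.018,
                      threshold = 40, I_e = 0.0118, c_prime = 6.4,
                      trial_max = 3000, settle = 500, dt = 0.5,
                      J_syn = NULL) {
  stopifnot(threshold > 0, tau > 0, tau_AMPA > 0, trial_max > 0, dt > 0,
            dt < tau_AMPA)
  if (is.null(J_syn)) {
    J_syn <- matrix(0, 4, 4)
    J_syn[1, 1] <- J_syn[2, 2] <- J_syn[3, 3] <- J_syn[4, 4] <- J_s
    J_syn[1, 2] <- J_syn[2, 1] <- J_syn[3, 4] <- J_syn[4, 3] <- -J_c
    J_syn[3, 1] <- J_syn[4, 2] <- J_ff
    J_syn[3, 2] <- J_syn[4, 1] <- -J_ffc
    J_syn[1, 3] <- J_syn[2, 4] <- J_fb
    J_syn[1, 4] <- J_syn[2, 3] <- -J_fbc
  }
  stopifnot(all(dim(J_syn) == c(4, 4)))
  structure(list(J_syn = J_syn, J_s = J_s, J_c = J_c, J_ff = J_ff,
                 J_ffc = J_ffc, J_fb = J_fb, J_fbc = J_fbc,
                 I0_dm = I0_dm, a = a, b = b, c = c, tau = tau,
                 gamma = gamma, tau_AMPA = tau_AMPA,
                 sigma_noise = sigma_noise, threshold = threshold,
                 I_e = I_e, c_prime = c_prime, trial_max = trial_max,
                 settle = settle, dt = dt),
            class = "dm_params")
}

#' Input-noise specification for the decision circuit
#'
#' Mean offsets and within-module correlations of the Ornstein-Uhlenbeck
#' noise drives to the two PPC and the two PFC populations.
#'
#' @param mean_ppc,mean_pfc Mean offsets added to the OU processes (nA).
#' @param corr_ppc,corr_pfc Target noise correlation within each module,
#'   in `[0, 1]`.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(mean_ppc = 0, mean_pfc = 0,
                       corr_ppc = 0, corr_pfc = 0) {
  stopifnot(is.finite(mean_ppc), is.finite(mean_pfc),
            corr_ppc >= 0, corr_ppc <= 1, corr_pfc >= 0, corr_pfc <= 1)
  structure(list(mean_ppc = mean_ppc, mean_pfc = mean_pfc,
                 corr_ppc = corr_ppc, corr_pfc = corr_pfc),
            class = "noise_spec")
}

#' Large-scale-to-circuit coupling specification
#'
#' Settings for range-normalizing regional synaptic drives from a cohort of
#' large-scale models into the operating range of the decision circuit.
#'
#' @param ppc_regions,pfc_regions Node indices eligible as PPC / PFC
#'   sources (nonempty, disjoint).
#' @param a_MJW,b_MJW Target range bounds of the circuit input (nA).
#' @param lo_pct,hi_pct Cohort percentiles defining the source range.
#' @return A list of class `coupling_spec`.
#' @export
coupling_spec <- function(ppc_regions, pfc_regions,
                          a_MJW = -0.006, b_MJW = 0.001,
                          lo_pct = 10, hi_pct = 90) {
  stopifnot(length(ppc_regions) >= 1, length(pfc_regions) >= 1,
            length(intersect(ppc_regions, pfc_regions)) == 0,
            a_MJW < b_MJW, lo_pct >= 0, hi_pct <= 100, lo_pct < hi_pct)
  structure(list(ppc_regions = as.integer(ppc_regions),
                 pfc_regions = as.integer(pfc_regions),
                 a_MJW = a_MJW, b_MJW = b_MJW,
                 lo_pct = lo_pct, hi_pct = hi_pct),
            class = "coupling_spec")
}
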