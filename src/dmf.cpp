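// Dynamic mean-field whole-brain network engine.
//
// Integrates the coupled excitatory/inhibitory neural-mass equations with
// Euler-Maruyama, runs the Balloon-Windkessel hemodynamic model per node at
// the neural time step, and (optionally) applies feedback inhibition control
// (FIC) and the online E/I-tuning rule at every repetition time (TR).

#include <RcppArmadillo.h>
#include "rng.h"

using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// [[Rcpp::export]]
double transfer_rate_cpp(double I, double a, double b, double d) {
  return bnm::transfer(I, a, b, d);
}

static inline void check_finite(const arma::vec &x, const char *what,
                                long step, double dt) {
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    if (!std::isfinite(x(i))) {
      stop("non-finite %s at node %d, step %ld (t = %.1f ms): "
           "simulation diverged; reduce dt or coupling strengths",
           what, (int)(i + 1), step, step * dt);
    }
  }
}

// Pearson correlation matrix of the rows of X (nodes x time).
static arma::mat row_cor(const arma::mat &X) {
  const arma::uword n = X.n_rows;
  arma::mat Xc = X.each_col() - arma::mean(X, 1);
  arma::vec sd = arma::sqrt(arma::sum(arma::square(Xc), 1));
  arma::mat R = Xc * Xc.t();
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j)
      R(i, j) /= (sd(i) * sd(j));
  return R;
}

// [[Rcpp::export]]
List dmf_engine_cpp(const arma::mat &C,
                    arma::mat wLRE, arma::mat wFFI, arma::vec J,
                    const List &par, const List &hpar,
                    double duration, double dt, double tr,
                    double seed,
                    bool fic, const List &fpar,
                    bool tuning, const arma::mat &rho_trg,
                    double eta_EI, int fc_window, bool update_ffi,
                    arma::vec S_E, arma::vec S_I,
                    arma::mat hemo, arma::mat bold_hist,
                    const arma::ivec &fine_nodes) {
  const arma::uword n = C.n_rows;
  if (C.n_cols != n || wLRE.n_rows != n || wFFI.n_rows != n || J.n_elem != n)
    stop("connectome/weight dimension mismatch");

  const double W_E = par["W_E"], W_I = par["W_I"], I_0 = par["I_0"];
  const double w_plus = par["w_plus"], J_NMDA = par["J_NMDA"];
  const double a_E = par["a_E"], b_E = par["b_E"], d_E = par["d_E"];
  const double a_I = par["a_I"], b_I = par["b_I"], d_I = par["d_I"];
  const double tau_E = par["tau_E"], tau_I = par["tau_I"];
  const double gamma_E = par["gamma_E"], gamma_I = par["gamma_I"];
  const double sigma = par["sigma"];

  const double kappa = hpar["kappa"], gamma_h = hpar["gamma_h"];
  const double tau_h = hpar["tau_h"], alpha = hpar["alpha"];
  const double rho_h = hpar["rho_h"], V0 = hpar["V0"];
  const double k1 = hpar["k1"], k2 = hpar["k2"], k3 = hpar["k3"];

  double eta_fic = 0.001, rho_0 = 4.0, fic_interval = 720.0, J_min = 0.001;
  if (fic) {
    eta_fic = fpar["eta_FIC"];
    rho_0 = fpar["rho_0"];
    fic_interval = fpar["update_interval"];
    J_min = fpar["J_min"];
  }

  if (duration < tr || tr < dt || dt <= 0)
    stop("require duration >= tr >= dt > 0");

  const long n_steps = (long)std::llround(duration / dt);
  const long steps_per_tr = (long)std::llround(tr / dt);
  const long steps_per_fic = fic ? (long)std::llround(fic_interval / dt) : 0;
  const long n_tr = n_steps / steps_per_tr;

  bnm::Rng rng((uint64_t)seed);

  if (S_E.n_elem == 0) {
    S_E.set_size(n); S_I.set_size(n);
    for (arma::uword i = 0; i < n; ++i) S_E(i) = 0.1 + 0.02 * (rng.runif() - 0.5);
    for (arma::uword i = 0; i < n; ++i) S_I(i) = 0.1 + 0.02 * (rng.runif() - 0.5);
  }
  if (hemo.n_elem == 0) {
    hemo.set_size(4, n);
    hemo.row(0).zeros();          // s
    hemo.row(1).ones();           // f
    hemo.row(2).ones();           // v
    hemo.row(3).ones();           // q
  }

  arma::mat B_E = J_NMDA * (wLRE % C);   // long-range excitation
  arma::mat B_I = J_NMDA * (wFFI % C);   // feedforward inhibition
  const arma::umat mask = (C > 0);       // tunable connections

  // outputs (TR resolution)
  arma::mat bold(n, n_tr), rates_E(n, n_tr), rates_I(n, n_tr);
  arma::mat currents_E(n, n_tr), gating_E(n, n_tr);

  // trailing BOLD buffer for windowed FC (history from previous stages first)
  arma::mat fcbuf;
  if (tuning) {
    fcbuf.set_size(n, bold_hist.n_cols + n_tr);
    if (bold_hist.n_cols > 0) fcbuf.cols(0, bold_hist.n_cols - 1) = bold_hist;
  }
  long fc_filled = (long)bold_hist.n_cols;

  // tuning trace
  std::vector<double> tr_fc_r, tr_fc_rmse, tr_mean_lre, tr_mean_ffi;
  std::vector<int> tr_index;

  // fine recording (per-step I_E for selected nodes; used for circuit coupling)
  const arma::uword n_fine = fine_nodes.n_elem;
  arma::mat fine_IE;
  if (n_fine > 0) fine_IE.set_size(n_fine, n_steps);

  arma::vec tr_sum_rE(n, arma::fill::zeros), tr_sum_rI(n, arma::fill::zeros);
  arma::vec tr_sum_IE(n, arma::fill::zeros);
  arma::vec fic_sum_rE(n, arma::fill::zeros), fic_sum_rI(n, arma::fill::zeros);
  long fic_count = 0;

  arma::vec I_E(n), I_I(n), r_E(n), r_I(n);
  const double sq_dt = std::sqrt(dt);
  const double dts = dt / 1000.0;  // hemodynamics run in seconds
  const double inv_alpha = 1.0 / alpha;

  long tr_idx = 0;

  for (long step = 1; step <= n_steps; ++step) {
    // synaptic input currents
    I_E = W_E * I_0 + w_plus * J_NMDA * S_E + B_E * S_E - J % S_I;
    I_I = W_I * I_0 + J_NMDA * S_E + B_I * S_E - S_I;
    for (arma::uword i = 0; i < n; ++i) {
      r_E(i) = bnm::transfer(I_E(i), a_E, b_E, d_E);
      r_I(i) = bnm::transfer(I_I(i), a_I, b_I, d_I);
    }

    tr_sum_rE += r_E; tr_sum_rI += r_I; tr_sum_IE += I_E;
    if (fic) { fic_sum_rE += r_E; fic_sum_rI += r_I; ++fic_count; }
    if (n_fine > 0)
      for (arma::uword k = 0; k < n_fine; ++k)
        fine_IE(k, step - 1) = I_E(fine_nodes(k) - 1);

    // Euler-Maruyama gating update, one independent normal per population
    for (arma::uword i = 0; i < n; ++i) {
      S_E(i) += dt * (-S_E(i) / tau_E + (1.0 - S_E(i)) * gamma_E * r_E(i)) +
                sigma * sq_dt * rng.rnorm();
      if (S_E(i) < 0.0) S_E(i) = 0.0; else if (S_E(i) > 1.0) S_E(i) = 1.0;
    }
    for (arma::uword i = 0; i < n; ++i) {
      S_I(i) += dt * (-S_I(i) / tau_I + gamma_I * r_I(i)) +
                sigma * sq_dt * rng.rnorm();
      if (S_I(i) < 0.0) S_I(i) = 0.0; else if (S_I(i) > 1.0) S_I(i) = 1.0;
    }

    // Balloon-Windkessel, driven by excitatory gating
    for (arma::uword i = 0; i < n; ++i) {
      double s = hemo(0, i), f = hemo(1, i), v = hemo(2, i), q = hemo(3, i);
      const double fv = std::pow(v, inv_alpha);
      const double Ef = 1.0 - std::pow(1.0 - rho_h, 1.0 / f);
      hemo(0, i) = s + dts * (S_E(i) - kappa * s - gamma_h * (f - 1.0));
      hemo(1, i) = f + dts * s;
      hemo(2, i) = v + dts * (f - fv) / tau_h;
      hemo(3, i) = q + dts * (f * Ef / rho_h - fv * q / v) / tau_h;
      if (hemo(1, i) <= 0.0 || hemo(2, i) <= 0.0 || hemo(3, i) <= 0.0)
        stop("hemodynamic state became non-positive at node %d, step %ld: "
             "use a smaller dt", (int)(i + 1), step);
    }

    if (step % 100 == 0) {
      check_finite(S_E, "excitatory gating", step, dt);
      check_finite(S_I, "inhibitory gating", step, dt);
    }

    // FIC update on its own clock
    if (fic && step % steps_per_fic == 0) {
      const arma::vec pre = fic_sum_rI / (double)fic_count;
      const arma::vec post = fic_sum_rE / (double)fic_count;
      J += eta_fic * (pre % post - rho_0 * pre);
      for (arma::uword i = 0; i < n; ++i) if (J(i) < J_min) J(i) = J_min;
      fic_sum_rE.zeros(); fic_sum_rI.zeros(); fic_count = 0;
    }

    // TR boundary: BOLD sample, window means, tuning update
    if (step % steps_per_tr == 0) {
      for (arma::uword i = 0; i < n; ++i) {
        const double v = hemo(2, i), q = hemo(3, i);
        bold(i, tr_idx) = V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) +
                                k3 * (1.0 - v));
      }
      rates_E.col(tr_idx) = tr_sum_rE / (double)steps_per_tr;
      rates_I.col(tr_idx) = tr_sum_rI / (double)steps_per_tr;
      currents_E.col(tr_idx) = tr_sum_IE / (double)steps_per_tr;
      gating_E.col(tr_idx) = S_E;
      tr_sum_rE.zeros(); tr_sum_rI.zeros(); tr_sum_IE.zeros();

      if (tuning) {
        fcbuf.col(fc_filled) = bold.col(tr_idx);
        ++fc_filled;
        if (fc_filled >= fc_window) {
          const arma::mat win = fcbuf.cols(fc_filled - fc_window, fc_filled - 1);
          arma::mat rho_sim = row_cor(win);
          if (!rho_sim.is_finite())
            stop("windowed FC is undefined (zero-variance BOLD in window "
                 "ending at TR %ld): increase the window or burn-in",
                 (long)(tr_idx + 1));
          const arma::mat diff = rho_trg - rho_sim;
          arma::vec rmse(n);
          for (arma::uword i = 0; i < n; ++i) {
            double ss = 0.0;
            for (arma::uword j = 0; j < n; ++j)
              if (j != i) ss += diff(i, j) * diff(i, j);
            rmse(i) = std::sqrt(ss / (double)(n - 1));
          }
          // synchronous update over all connected pairs
          for (arma::uword i = 0; i < n; ++i) {
            for (arma::uword j = 0; j < n; ++j) {
              if (i == j || !mask(i, j)) continue;
              const double d = eta_EI * diff(i, j) * rmse(i);
              wLRE(i, j) += d;
              if (wLRE(i, j) <= 0.0) wLRE(i, j) = 0.0;
              if (update_ffi) {
                wFFI(i, j) -= d;
                if (wFFI(i, j) <= 0.0) wFFI(i, j) = 0.0;
              }
            }
          }
          B_E = J_NMDA * (wLRE % C);
          B_I = J_NMDA * (wFFI % C);

          // trace
          double srr = 0, srt = 0, stt = 0, sr = 0, st = 0, sd2 = 0;
          long m = 0;
          for (arma::uword i = 0; i < n; ++i)
            for (arma::uword j = i + 1; j < n; ++j) {
              const double x = rho_sim(i, j), y = rho_trg(i, j);
              sr += x; st += y; srr += x * x; stt += y * y; srt += x * y;
              sd2 += (x - y) * (x - y);
              ++m;
            }
          const double num = srt - sr * st / m;
          const double den = std::sqrt((srr - sr * sr / m) *
                                       (stt - st * st / m));
          tr_index.push_back((int)(tr_idx + 1));
          tr_fc_r.push_back(den > 0 ? num / den : NA_REAL);
          tr_fc_rmse.push_back(std::sqrt(sd2 / m));
          tr_mean_lre.push_back(arma::accu(wLRE % mask) / arma::accu(mask));
          tr_mean_ffi.push_back(arma::accu(wFFI % mask) / arma::accu(mask));
        }
      }
      ++tr_idx;
    }
  }

  List trace = List::create(
      _["tr"] = tr_index, _["fc_r"] = tr_fc_r, _["fc_rmse"] = tr_fc_rmse,
      _["mean_w_lre"] = tr_mean_lre, _["mean_w_ffi"] = tr_mean_ffi);

  return List::create(
      _["bold"] = bold, _["rates_E"] = rates_E, _["rates_I"] = rates_I,
      _["currents_E"] = currents_E, _["gating_E"] = gating_E,
      _["S_E"] = S_E, _["S_I"] = S_I, _["hemo"] = hemo,
      _["J"] = J, _["w_LRE"] = wLRE, _["w_FFI"] = wFFI,
      _["trace"] = trace,
      _["fine_currents_E"] = fine_IE);
}
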