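// Frontoparietal winner-take-all circuit: four populations (A/B in PPC and
// PFC) with NMDA gating dynamics, correlated Ornstein-Uhlenbeck AMPA noise,
// decision trials (threshold crossing in PFC) and working-memory trials
// (target stimulus, delayed distractor, persistence classification).

#include <RcppArmadillo.h>
#include "rng.h"

using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// Two OU processes sharing a common white-noise component so that their
// drives have correlation `corr`; each shifted by `mean`.
// [[Rcpp::export]]
arma::mat ou_pair_cpp(long n_steps, double dt, double tau_AMPA,
                      double sigma_noise, double corr, double mean,
                      double seed) {
  if (corr < 0.0 || corr > 1.0) stop("corr must be in [0, 1]");
  if (dt >= tau_AMPA) stop("dt must be smaller than tau_AMPA");
  bnm::Rng rng((uint64_t)seed);
  arma::mat out(2, n_steps);
  double I1 = 0.0, I2 = 0.0;
  const double sc = sigma_noise * std::sqrt(dt / tau_AMPA);
  const double ws = std::sqrt(corr), wi = std::sqrt(1.0 - corr);
  for (long t = 0; t < n_steps; ++t) {
    const double sh = rng.rnorm(), e1 = rng.rnorm(), e2 = rng.rnorm();
    I1 += -I1 * dt / tau_AMPA + sc * (ws * sh + wi * e1);
    I2 += -I2 * dt / tau_AMPA + sc * (ws * sh + wi * e2);
    out(0, t) = mean + I1;
    out(1, t) = mean + I2;
  }
  return out;
}

struct CircuitPar {
  arma::mat Jsyn;   // 4x4, input current to row i from gating of col j
  double I0, a, b, c, tau, gamma, tau_AMPA, sigma_noise;
};

static CircuitPar unpack(const List &p) {
  CircuitPar cp;
  cp.Jsyn = as<arma::mat>(p["J_syn"]);
  if (cp.Jsyn.n_rows != 4 || cp.Jsyn.n_cols != 4) stop("J_syn must be 4x4");
  cp.I0 = p["I0_dm"]; cp.a = p["a"]; cp.b = p["b"]; cp.c = p["c"];
  cp.tau = p["tau"]; cp.gamma = p["gamma"];
  cp.tau_AMPA = p["tau_AMPA"]; cp.sigma_noise = p["sigma_noise"];
  return cp;
}

// One circuit integration. Populations: 0 A_PPC, 1 B_PPC, 2 A_PFC, 3 B_PFC.
// stim: k x 4 matrix (pop [1-4], t_on ms, t_off ms, amplitude nA).
// If drive_ppc/drive_pfc are non-empty they replace the OU mean offsets
// (external large-scale drive at circuit dt, read from `offset`).
static void run_circuit(const CircuitPar &cp, double dt, long n_steps,
                        const arma::mat &stim,
                        double mean_ppc, double mean_pfc,
                        double corr_ppc, double corr_pfc,
                        const arma::vec &drive_ppc, const arma::vec &drive_pfc,
                        long offset, bnm::Rng &rng,
                        double threshold, long check_from,
                        int &decision, double &rt,
                        arma::mat *traj, long rec_every,
                        arma::vec &S) {
  arma::vec In(4, arma::fill::zeros);   // OU states
  const double sc = cp.sigma_noise * std::sqrt(dt / cp.tau_AMPA);
  const double wsP = std::sqrt(corr_ppc), wiP = std::sqrt(1.0 - corr_ppc);
  const double wsF = std::sqrt(corr_pfc), wiF = std::sqrt(1.0 - corr_pfc);
  const bool external = drive_ppc.n_elem > 0;
  arma::vec I(4), r(4);
  decision = 0; rt = NA_REAL;

  for (long t = 0; t < n_steps; ++t) {
    const double shP = rng.rnorm(), e0 = rng.rnorm(), e1 = rng.rnorm();
    const double shF = rng.rnorm(), e2 = rng.rnorm(), e3 = rng.rnorm();
    In(0) += -In(0) * dt / cp.tau_AMPA + sc * (wsP * shP + wiP * e0);
    In(1) += -In(1) * dt / cp.tau_AMPA + sc * (wsP * shP + wiP * e1);
    In(2) += -In(2) * dt / cp.tau_AMPA + sc * (wsF * shF + wiF * e2);
    In(3) += -In(3) * dt / cp.tau_AMPA + sc * (wsF * shF + wiF * e3);

    double offP = mean_ppc, offF = mean_pfc;
    if (external) {
      offP = drive_ppc(offset + t);
      offF = drive_pfc(offset + t);
    }

    // label-mirrored operand order keeps exactly symmetric states exactly
    // symmetric (the A/B saddle is not broken by rounding noise)
    const arma::mat &Jm = cp.Jsyn;
    I(0) = (Jm(0, 0) * S(0) + Jm(0, 1) * S(1)) +
           (Jm(0, 2) * S(2) + Jm(0, 3) * S(3));
    I(1) = (Jm(1, 1) * S(1) + Jm(1, 0) * S(0)) +
           (Jm(1, 3) * S(3) + Jm(1, 2) * S(2));
    I(2) = (Jm(2, 2) * S(2) + Jm(2, 3) * S(3)) +
           (Jm(2, 0) * S(0) + Jm(2, 1) * S(1));
    I(3) = (Jm(3, 3) * S(3) + Jm(3, 2) * S(2)) +
           (Jm(3, 1) * S(1) + Jm(3, 0) * S(0));
    I += cp.I0;
    I(0) += offP + In(0); I(1) += offP + In(1);
    I(2) += offF + In(2); I(3) += offF + In(3);

    const double tnow = t * dt;
    for (arma::uword k = 0; k < stim.n_rows; ++k) {
      if (tnow >= stim(k, 1) && tnow < stim(k, 2))
        I((arma::uword)stim(k, 0) - 1) += stim(k, 3);
    }

    for (int k = 0; k < 4; ++k) r(k) = bnm::transfer(I(k), cp.a, cp.b, cp.c);
    for (int k = 0; k < 4; ++k) {
      S(k) += dt * (-S(k) / cp.tau + cp.gamma * (1.0 - S(k)) * r(k));
      if (S(k) < 0.0) S(k) = 0.0; else if (S(k) > 1.0) S(k) = 1.0;
      if (!std::isfinite(S(k)))
        stop("non-finite circuit state in population %d at t = %.1f ms",
             k + 1, tnow);
    }

    if (traj && (t % rec_every == 0)) {
      const long col = t / rec_every;
      if (col < (long)traj->n_cols) traj->col(col) = r;
    }

    if (check_from >= 0 && t >= check_from) {
      const bool hitA = r(2) >= threshold, hitB = r(3) >= threshold;
      if (hitA || hitB) {
        if (hitA && hitB) {
          if (r(2) > r(3)) decision = 1;
          else if (r(3) > r(2)) decision = 2;
          else decision = 0;            // exact tie: no decision
        } else decision = hitA ? 1 : 2;
        if (decision != 0) rt = (t - check_from) * dt;
        return;
      }
    }
  }
}

// [[Rcpp::export]]
List dm_trials_cpp(const List &p, int n_trials, double seed,
                   double mean_ppc, double mean_pfc,
                   double corr_ppc, double corr_pfc,
                   double I_e, double c_prime,
                   double threshold, double trial_max,
                   double settle, double dt,
                   const arma::vec &drive_ppc, const arma::vec &drive_pfc,
                   const arma::ivec &drive_offsets,
                   bool record, double record_every) {
  const CircuitPar cp = unpack(p);
  const long settle_steps = (long)std::llround(settle / dt);
  const long trial_steps = (long)std::llround(trial_max / dt);
  const long n_steps = settle_steps + trial_steps;
  const long rec_every = std::max(1L, (long)std::llround(record_every / dt));

  // evidence boxcars: favored option A (population 1)
  arma::mat stim(2, 4);
  stim(0, 0) = 1; stim(0, 1) = settle; stim(0, 2) = settle + trial_max;
  stim(0, 3) = I_e * (1.0 + c_prime / 100.0);
  stim(1, 0) = 2; stim(1, 1) = settle; stim(1, 2) = settle + trial_max;
  stim(1, 3) = I_e * (1.0 - c_prime / 100.0);

  IntegerVector decisions(n_trials);
  NumericVector rts(n_trials);
  List trajs;

  for (int tr = 0; tr < n_trials; ++tr) {
    bnm::Rng rng(bnm::mix_seed((uint64_t)seed, (uint64_t)tr));
    arma::vec S(4); S.fill(0.1);
    int dec; double rt;
    arma::mat traj;
    arma::mat *tp = nullptr;
    if (record) {
      traj.set_size(4, n_steps / rec_every + 1);
      traj.fill(NA_REAL);
      tp = &traj;
    }
    long offset = 0;
    if (drive_offsets.n_elem > 0) offset = drive_offsets(tr % drive_offsets.n_elem);
    run_circuit(cp, dt, n_steps, stim, mean_ppc, mean_pfc, corr_ppc, corr_pfc,
                drive_ppc, drive_pfc, offset, rng, threshold, settle_steps,
                dec, rt, tp, rec_every, S);
    decisions[tr] = dec;
    rts[tr] = rt;
    if (record) trajs.push_back(traj);
  }
  return List::create(_["decision"] = decisions, _["rt"] = rts,
                      _["traj"] = trajs);
}

// [[Rcpp::export]]
List wm_trial_cpp(const List &p, double seed,
                  double I_app, double I_dist,
                  double input_amplitude, double corr,
                  double t_target, double stim_dur, double delay,
                  double post, double dt, bool record,
                  double record_every) {
  const CircuitPar cp = unpack(p);
  const double t_dist = t_target + delay;
  const double t_end = t_dist + stim_dur + post;
  const long n_steps = (long)std::llround(t_end / dt);
  const long rec_every = std::max(1L, (long)std::llround(record_every / dt));

  arma::mat stim(2, 4);
  stim(0, 0) = 1; stim(0, 1) = t_target; stim(0, 2) = t_target + stim_dur;
  stim(0, 3) = I_app;
  stim(1, 0) = 2; stim(1, 1) = t_dist; stim(1, 2) = t_dist + stim_dur;
  stim(1, 3) = I_dist;

  bnm::Rng rng((uint64_t)seed);
  arma::vec S(4); S.fill(0.1);
  int dec; double rt;
  arma::mat traj(4, n_steps / rec_every + 1);
  traj.fill(NA_REAL);
  arma::vec empty;
  run_circuit(cp, dt, n_steps, stim, input_amplitude, input_amplitude,
              corr, corr, empty, empty, 0, rng, 0.0, -1,
              dec, rt, &traj, rec_every, S);

  // window means of recorded rates for classification
  auto win_mean = [&](int pop, double t0, double t1) {
    long a = (long)std::floor(t0 / dt / rec_every);
    long b = (long)std::floor(t1 / dt / rec_every) - 1;
    if (a < 0) a = 0;
    if (b >= (long)traj.n_cols) b = traj.n_cols - 1;
    double s = 0; long m = 0;
    for (long k = a; k <= b; ++k)
      if (std::isfinite(traj(pop, k))) { s += traj(pop, k); ++m; }
    return m > 0 ? s / m : NA_REAL;
  };

  return List::create(
      _["pre_target"] = win_mean(0, t_dist - 300.0, t_dist),
      _["pre_rival"] = win_mean(1, t_dist - 300.0, t_dist),
      _["final_target"] = win_mean(0, t_end - 500.0, t_end),
      _["final_rival"] = win_mean(1, t_end - 500.0, t_end),
      _["traj"] = record ? wrap(traj) : R_NilValue,
      _["t_end"] = t_end);
}
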