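---
title: "Tuning excitation-inhibition balance in whole-brain network models"
author: "bnmtune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning excitation-inhibition balance in whole-brain network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`bnmtune` simulates whole-brain networks of reduced Wong-Wang neural
masses. Each node holds one excitatory (E) and one inhibitory (I)
population described by synaptic gating variables $S^E_i, S^I_i \in
[0,1]$. The input currents are

$$I^E_i = W_E I_0 + w_+ J_{NMDA} S^E_i +
  J_{NMDA}\textstyle\sum_j w^{LRE}_{ij} C_{ij} S^E_j - J_i S^I_i,$$
$$I^I_i = W_I I_0 + J_{NMDA} S^E_i +
  J_{NMDA}\textstyle\sum_j w^{FFI}_{ij} C_{ij} S^E_j - S^I_i,$$

where $C$ is the structural connectome. Every connection carries two
multipliers: long-range excitation $w^{LRE}_{ij}$ (E$\to$E) and
feedforward inhibition $w^{FFI}_{ij}$ (E$\to$I). Their quotient, the
**E/I-ratio** of the connection, controls the sign and strength of the
synchrony between the two nodes. Currents are converted to rates by the
sigmoidal transfer $r(I) = (aI-b)/(1-e^{-d(aI-b)})$ (the removable
singularity at $aI=b$ is evaluated by its limit $1/d$), and the gating
evolves as

$$\dot S^E = -S^E/\tau_E + (1-S^E)\gamma_E r^E + \sigma\upsilon(t),
\qquad
\dot S^I = -S^I/\tau_I + \gamma_I r^I + \sigma\upsilon(t).$$

Integration is Euler-Maruyama at `dt = 1` ms with one independent
standard-normal draw per population per step, scaled by
$\sigma\sqrt{dt}$; gating is clipped to $[0,1]$ after each step (the
drift has no intrinsic upper bound for $S^I$). A convergence test in the
suite checks that the noiseless steady state is unchanged at `dt = 0.1`
ms. The noise draws in the E and I equations are independent; the
equations are agnostic to whether they share a draw, and independence is
the conservative reading.

Parameter defaults are the canonical dynamic mean-field values
($W_E=1$, $W_I=0.7$, $I_0=0.382$ nA, $w_+=1.4$, $J_{NMDA}=0.15$ nA,
$a_E=310$, $b_E=125$, $d_E=0.16$, $a_I=615$, $b_I=177$, $d_I=0.087$,
$\tau_E=100$ ms, $\tau_I=10$ ms, $\gamma_E=0.641\times10^{-3}$,
$\gamma_I=10^{-3}$, $\sigma=0.01$ nA), all overridable through
`dmf_params()`.

BOLD is produced by feeding $S^E_i$ into the Balloon-Windkessel model
(four states per node: vasodilatory signal, inflow, venous volume,
deoxyhemoglobin; $\kappa=0.65\,s^{-1}$, $\gamma_h=0.41\,s^{-1}$,
$\tau_h=0.98$ s, $\alpha=0.32$, $\rho_h=0.34$, $V_0=0.02$, classic
$k_1,k_2,k_3$ readout), integrated with explicit Euler at the neural
step — the hemodynamics are two orders of magnitude slower than `dt`,
and the suite cross-checks against an adaptive high-accuracy solver.
BOLD is sampled once per repetition time, `tr = 720` ms.

## Feedback inhibition control

The local inhibitory weight $J_i$ is regulated by inhibitory synaptic
plasticity: once every 720 ms,

$$\Delta J_i = \eta_{FIC}\,(\mathrm{pre}_i \cdot \mathrm{post}_i -
  \rho_0\,\mathrm{pre}_i),$$

with $\eta_{FIC}=0.001$, set point $\rho_0 = 4$ Hz, `pre` and `post`
the window-averaged inhibitory and excitatory rates of the node (the
arithmetic mean over the update interval; the estimator is not dictated
by the rule itself). $J_i$ is clamped below at 0.001 nA and initialized
at 1 nA. This homeostat is what makes the FC-versus-E/I-ratio
relationship monotonic: with it disabled, the two-node tuning curve is
visibly non-monotonic, which would break gradient-style fitting.

We treat FIC as part of the model everywhere in the FC pipeline: it is
active while a ground-truth target is measured, during tuning, and
during validation runs. Freezing $J$ at an arbitrary instant of its
trajectory and simulating afresh leaves the network several tenths of a
Hz to several Hz away from the homeostatic state and materially changes
the FC, so frozen-$J$ validation would compare mismatched models. For
circuit-coupled decision experiments (`multiscale_dm()`) the fitted $J$
is frozen instead: there the quantity of interest is the drive
statistics of a fixed model, and ongoing plasticity would conflate the
two scales.

## The E/I-tuning algorithm

Fitting adjusts $w^{LRE}$ and $w^{FFI}$ online so that the windowed FC
of the simulated BOLD approaches a target correlation matrix
$\rho^{trg}$. After every new TR, for each structural connection
$(i,j)$ with $C_{ij}>0$:

```
diff    = rho_trg[i,j] - rho_sim[i,j]
rmse_i  = RMS deviation of row i of rho_trg vs rho_sim (diagonal excluded)
w_LRE[i,j] += eta * diff * rmse_i ; clamp at 0
w_FFI[i,j] -= eta * diff * rmse_i ; clamp at 0
```

All updates within one TR use the same FC snapshot (the update is
synchronous; the per-connection steps are independent given the
snapshot, so in-place and synchronous sweeps coincide). The row factor
`rmse_i` anneals steps as a row's fit improves and deliberately makes
the $(i,j)$ and $(j,i)$ steps unequal. The windowed FC is the Pearson
correlation over the trailing window of TRs; tuning starts once one
full window of history exists (the fitter front-loads a settling period
of one window with FIC active).

The schedule runs six stages; per stage the learning rate halves and
the window doubles, from $\eta = 0.1$ and 150 TRs. The reference
configuration simulates 10 h of biological time per stage
(`tuning_schedule_full()`); the package default is a desk-scale
schedule of 20 min per stage, which a laptop CPU completes in about two
minutes for 30 nodes.

The fitter initializes the weights *balanced*, `w_LRE = w_FFI = 0.5`:
the per-connection total stays at the untuned value 1 while the
E/I-ratio starts at 1, so both weight families are adjustable from the
first update. (Starting from the untuned model state `w_LRE = 1,
w_FFI = 0` leaves every connection that needs net inhibition stuck
behind the zero clamp; on targets with substantial anticorrelation
this is the difference between a failed and a successful fit.) The `E_only`
comparison variant keeps the classical `(1, 0)` start, since it never
updates `w_FFI`.

Two further properties of the rule matter in practice and are
documented here deliberately:

* **Sum conservation and the zero-clamp ratchet.** The paired update
  conserves $w^{LRE}_{ij} + w^{FFI}_{ij}$ except when a clamp fires at
  zero. Starting from the untuned state ($w^{LRE}=1, w^{FFI}=0$), large
  per-connection totals are reached only through repeated clamping.
  Targets whose generating weights have moderate totals are therefore
  fit much faster than extreme ones.
* **Noise-driven weight inflation.** Because the windowed FC is a noisy
  estimate, the clamp also rectifies gradient noise into slow upward
  drift of both weight families. Over the desk-scale schedule this is
  negligible; greatly lengthened stages at a fixed learning rate
  eventually inflate weights and degrade the fit. The staged halving of
  $\eta$ is what keeps the endpoint stable.

`fit_variant()` provides the two comparison modes: `E_only` updates
only $w^{LRE}$ (feedforward inhibition stays at its default 0), and
`global_scalar` performs the classical grid search over one scalar $G$
rescaling $C$.

## Synthetic study conditions

No empirical data ships with the package; the `synth_*` generators
define the study conditions.

* `synth_connectome(n, density, ...)` draws a symmetric nonnegative
  zero-diagonal matrix, connected by construction (random spanning tree
  before density fill), log-normal edge weights, normalized so the
  maximum row sum is 1. Default density 0.25 — sparse enough that
  individual connections carry tangible weight after row normalization,
  dense enough that the fitting problem has a few hundred free
  parameters at 30 nodes.
* `synth_target(C, ...)` draws per-connection E/I-ratios
  $q_{ij}\sim\mathrm{LogNormal}(\log q_0,\ 1.0)$ on the edges of $C$
  and maps them to $w^{LRE} = s\,q/(1+q)$, $w^{FFI}=s/(1+q)$. The
  per-connection total $s$ defaults to $0.45/\overline{C_{>0}}$, which
  keeps the typical coupling mass $w\cdot C$ comparable across sizes
  and densities; at 30 nodes and density 0.25 this gives $s\approx
  5.5$, producing target FCs with off-diagonal structure well above
  the finite-sample FC noise floor, yet with weight totals the staged
  schedule can traverse from its starting state (larger spreads or
  totals slow the zero-clamp ratchet and degrade the reachable fit). The model is run with FIC through a burn-in
  (convergence of every node to $4\pm1.5$ Hz is verified), then the FC
  of a long measurement period (default 30 min; the acceptance workflow
  uses 4 h) becomes the target. Because the target comes from the model
  itself, a near-perfect fit exists by construction; random correlation
  matrices can be supplied to `fit_ei()` directly as a stress mode with
  no such guarantee.
* `synth_cohort(K, ...)` spaces the generating E/I-ratio centers
  log-evenly across `±heterogeneity`, which maps monotonically onto the
  cohort's mean FC.

What the generator does **not** emulate: tractography biases, distance
rules, hub structure, parcellation effects, subject-level measurement
noise, or scanner artifacts. Passing tests on these targets shows the
algorithmic pipeline recovers model-expressible FC structure; it says
nothing about fit quality on empirical human FC.

A practical note on measurement noise: FC estimated from finite BOLD is
itself stochastic (hemodynamic autocorrelation cuts the effective
sample size roughly fourfold, and the slow wander of the FIC weights
adds a long-timescale component). With 30 nodes, the FC of two independent multi-hour runs of the *same*
model correlates noticeably below 1; this measurement floor, as much
as the optimizer, bounds what a validation run can report. The acceptance
workflow therefore measures target and validation FC over 4 h each.

## The frontoparietal decision circuit

The circuit has four populations — A/B in PPC and A/B in PFC — with
NMDA gating dynamics $\dot S = -S/\tau + \gamma(1-S)r(I)$
($\tau = 60$ ms, $\gamma = 0.641\times10^{-3}$ per ms, $a=270$,
$b=108$, shape 0.154, integrated at `dt = 0.5` ms). AMPA-like noise is
an Ornstein-Uhlenbeck process per population
($\tau_{AMPA} = 2$ ms, magnitude $\sigma_{noise}$), and the two drives
within a module share a common white-noise component
$\eta_k = \sqrt{c}\,\eta_{sh} + \sqrt{1-c}\,\eta_k$ so their
correlation is $c$.

The couplings follow the winner-take-all scheme: within a module,
self-excitation $J_s$ and cross-inhibition $-J_c$; between modules,
same-label excitation and opposite-label inhibition (feedforward
$J_{ff}, -J_{ffc}$; feedback $J_{fb}, -J_{fbc}$). The source circuit
publication defers the coupling values to supplementary material, so
the defaults here were fixed once, during model construction, by a
randomized search for the qualitative operating regime the science
requires: decisions inside the 3-s trial window at threshold 40 Hz,
accuracy rising with PPC noise correlation, an inverted-U of
integration time over that correlation, and a speed-accuracy trade-off
in the noise mean. The frozen values are $J_s=0.373$, $J_c=0.0798$,
$J_{ff}=0.0777$, $J_{ffc}=0.0927$, $J_{fb}=0.0407$, $J_{fbc}=0.0173$,
$I_0=0.323$ nA, $\sigma_{noise}=0.018$ nA — note the cross-label
feedforward inhibition slightly exceeds the same-label feedforward
excitation, making the PPC$\to$PFC projection approximately a
differential amplifier; this is what lets intermediate input
correlation maximize integration time (common-mode input is largely
cancelled, so decisions slow as differential noise is removed, while at
very high correlation the residual common push dominates and decisions
speed up again).

Evidence enters as $I_e(1\pm c'/100)$ to the two PPC populations
($I_e = 0.0118$ nA, contrast $c' = 6.4\%$, option A favored). A
decision registers when a PFC population reaches 40 Hz; ties at the
same step go to the higher instantaneous rate, exact ties decide
nothing. The inverted-U of integration time is shallow (~25 ms over a
~900 ms mean), so experiments that locate its peak use thousands of
trials per correlation level; `dm_experiment()` derives per-trial seeds
from one master seed and is bitwise reproducible.

Working-memory trials apply a 250-ms target boxcar to one PPC
population and an identical distractor to the rival 1.5 s later.
Memory is scored present when the population's mean rate over the
scoring window exceeds 20 Hz and the rival's by 10 Hz (the source text
states no numeric criterion; these values sit comfortably between the
low and persistent branches of the circuit). Regimes: `no_induction`,
`disrupted`, `robust`. `bifurcation_map()` varies the net recurrent
strength $J_S = J_s - J_c$ (shifted symmetrically onto both couplings)
against stimulus amplitude.

## Coupling the scales

`multiscale_dm()` drives the circuit with large-scale activity instead
of mean offsets. The regional drive is the excitatory current without
the constant external term, $w_+J_{NMDA}S^E_i + J_{NMDA}\sum_j
w^{LRE}_{ij}C_{ij}S^E_j - J_iS^I_i$, recorded at full resolution and
zero-order-held to the circuit step. For each region, the 10th-90th
percentile range of mean amplitudes across the cohort (linear
interpolation percentiles) is mapped affinely onto
$[-0.006, 0.001]$ nA; values outside map linearly beyond the bounds
without clipping. Both populations of a module receive the same
normalized drive, each with its own independent OU realization. Trials
start at seeded random offsets into the drive recording.

## Numerical choices and degenerate inputs

* Zero-variance BOLD rows, constant current series, and NaN windowed FC
  raise errors naming the offending node rather than propagating NaN.
* Non-finite network state aborts with the step and node in the
  message; hemodynamic state going non-positive advises a smaller `dt`.
* The per-trial RNG is a dedicated xoshiro256++ stream per simulation,
  seeded from the user-facing integer; results are independent of R's
  global RNG state. Seeds derived internally stay below $2^{31}$.
* Matrix I/O is header-free TSV with 17 significant digits
  (bit-lossless round trip); simulation artifacts are TSV matrices plus
  a JSON metadata sidecar.

## Desk-scale problem sizes

The test suite and the reproduction script run, by design, at sizes a
single CPU handles in minutes: two-node and 30-node networks, 6 x 20-min
tuning schedules, 4-h FC measurements, 500-2500 decision trials per
condition, and cohorts of 3-10 synthetic models. The 379-node,
10-h-per-stage configuration of the reference pipeline is expressible
(`tuning_schedule_full()`, `synth_connectome(379, ...)`) but is not
exercised by the tests.

## Known limitations

* The online rule fits FC structure the model can express; it does not
  recover the generating weights (refits from different seeds reach
  equally good, visibly different weight matrices — a property the
  suite asserts rather than fights).
* Fit quality at desk scale is bounded by FC sampling noise plus the
  FIC wander described above; validation correlations around 0.95 on
  30-node targets (as computed by the reproduction script) reflect
  that bound, not a failure to converge.
* The WM classification thresholds are heuristic; near regime
  boundaries the majority vote across seeds decides.
* BOLD units are arbitrary (proportional to $V_0$); only correlations
  are interpreted.
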