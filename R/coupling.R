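#' Regional synaptic drive for circuit coupling
#'
#' Extracts the excitatory synaptic drive of one node at full integration
#' resolution: local recurrent excitation plus global network input minus
#' local recurrent inhibition (the excitatory input current without the
#' constant external term `W_E I_0`). Requires the node to have been
#' recorded via `record_nodes` in [simulate_bnm()].
#'
#' @param sim A `bnm_sim` object.
#' @param node Node index.
#' @return Numeric vector of drive currents (nA) at resolution `sim$dt`.
#' @export
region_drive <- function(sim, node) {
  k <- match(node, sim$record_nodes)
  if (is.na(k))
    stop("node ", node, " was not recorded: simulate with drive capture ",
         "enabled (record_nodes)")
  sim$fine_currents_E[k, ] - sim$params$W_E * sim$params$I_0
}

#' Cohort percentile range of regional drive amplitudes
#'
#' @param drives Per-model mean drive amplitudes for one region (length
#'   >= 2).
#' @param spec A [coupling_spec()].
#' @return Named numeric vector `c(a_BNM = lo, b_BNM = hi)` — the
#'   `lo_pct` and `hi_pct` percentiles (linear-interpolation convention).
#' @export
cohort_range <- function(drives, spec) {
  if (length(drives) < 2) stop("need at least two models in the cohort")
  qs <- stats::quantile(drives, c(spec$lo_pct, spec$hi_pct) / 100,
                        names = FALSE, type = 7)
  if (qs[2] <= qs[1])
    stop("degenerate cohort: zero spread between the ",
         spec$lo_pct, "th and ", spec$hi_pct, "th percentiles")
  c(a_BNM = qs[1], b_BNM = qs[2])
}

#' Range-normalize a drive series into the circuit's operating range
#'
#' Affine map sending the cohort source range `[a_BNM, b_BNM]` onto the
#' circuit target range `[a_MJW, b_MJW]`; values outside the source range
#' map linearly beyond the target bounds (no clipping). The circuit's own
#' OU noise is added later, per population.
#'
#' @param x Drive current series (nA).
#' @param a_BNM,b_BNM Source range bounds (nA), `b_BNM > a_BNM`.
#' @param spec A [coupling_spec()].
#' @return Rescaled series (nA).
#' @export
normalize_drive <- function(x, a_BNM, b_BNM, spec) {
  if (b_BNM <= a_BNM) stop("b_BNM must exceed a_BNM")
  (spec$b_MJW - spec$a_MJW) * (x - a_BNM) / (b_BNM - a_BNM) + spec$a_MJW
}

#' Decision-making experiments driven by a cohort of large-scale models
#'
#' For every model in the cohort, simulates the large-scale network with
#' drive capture at the chosen PPC and PFC nodes, range-normalizes the
#' regional drives against the cohort percentile ranges, feeds both
#' populations of each circuit module the same normalized drive (each
#' with its own independent OU noise), and runs a decision experiment.
#'
#' @param models A list of model descriptions, each a list with elements
#'   `C` (connectome) and `weights` ([coupling_weights()], e.g. from
#'   [fit_ei()] or [synth_target()]); or a [synth_cohort()] tibble.
#' @param spec A [coupling_spec()] whose region lists contain the chosen
#'   nodes.
#' @param ppc_node,pfc_node Node indices used as drive sources.
#' @param p A [dm_params()] list.
#' @param n_trials Decision trials per model.
#' @param seed Master seed.
#' @param drive_duration Biological time of large-scale drive recorded
#'   per model (ms); must exceed `settle + trial_max` of the circuit.
#' @param noise A [noise_spec()] providing the within-module OU noise
#'   correlations (means are replaced by the normalized drive).
#' @return A tibble of class `multiscale_dm`: `model_id`, `mean_fc` (of
#'   the model's simulated BOLD), `drive_ppc_mean`, `drive_pfc_mean`,
#'   and the [dm_experiment()] summaries.
#' @export
multiscale_dm <- function(models, spec, ppc_node, pfc_node,
                          p = dm_params(), n_trials = 200, seed = 1,
                          drive_duration = 120 * 1000,
                          noise = noise_spec()) {
  if (tibble::is_tibble(models) && "target" %in% names(models)) {
    models <- purrr::map2(models$C, models$target,
                          function(C, t) list(C = C, weights = t$weights))
  }
  if (!(ppc_node %in% spec$ppc_regions))
    stop("ppc_node must be listed in spec$ppc_regions")
  if (!(pfc_node %in% spec$pfc_regions))
    stop("pfc_node must be listed in spec$pfc_regions")
  K <- length(models)

  runs <- purrr::map(seq_len(K), function(k) {
    m <- models[[k]]
    sim <- simulate_bnm(m$C, duration = drive_duration,
                        seed = derive_seed(seed, k),
                        weights = m$weights, fic = FALSE,
                        record_nodes = c(ppc_node, pfc_node))
    list(ppc = region_drive(sim, ppc_node),
         pfc = region_drive(sim, pfc_node),
         mean_fc = mean_fc(compute_fc(sim$bold)),
         dt = sim$dt)
  })
  rng_ppc <- cohort_range(vapply(runs, function(r) mean(r$ppc),
                                 numeric(1)), spec)
  rng_pfc <- cohort_range(vapply(runs, function(r) mean(r$pfc),
                                 numeric(1)), spec)

  zoh <- function(x, from_dt, to_dt) rep(x, each = round(from_dt / to_dt))
  need <- round((p$settle + p$trial_max) / p$dt)

  res <- purrr::map_dfr(seq_len(K), function(k) {
    r <- runs[[k]]
    dp <- zoh(normalize_drive(r$ppc, rng_ppc[1], rng_ppc[2], spec),
              r$dt, p$dt)
    df <- zoh(normalize_drive(r$pfc, rng_pfc[1], rng_pfc[2], spec),
              r$dt, p$dt)
    max_off <- length(dp) - need
    if (max_off < 0) stop("drive_duration shorter than one circuit trial")
    offs <- withr::with_seed(derive_seed(seed, 5000 + k),
                             sample.int(max_off + 1, n_trials,
                                        replace = TRUE) - 1L)
    ex <- dm_experiment(p, noise, n_trials, derive_seed(seed, 9000 + k),
                        drive_ppc = dp, drive_pfc = df,
                        drive_offsets = offs)
    dplyr::bind_cols(tibble::tibble(model_id = k, mean_fc = r$mean_fc,
                                    drive_ppc_mean = mean(r$ppc),
                                    drive_pfc_mean = mean(r$pfc)), ex)
  })
  class(res) <- c("multiscale_dm", class(res))
  res
}

#' @exportS3Method ggplot2::autoplot
autoplot.multiscale_dm <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("pct_correct", "mean_integration_time"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_fc, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "model mean FC", y = NULL)
}
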