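#' Correlated Ornstein-Uhlenbeck noise pair
#'
#' Builds two OU current series whose white-noise drives share a common
#' component (`eta_k = sqrt(corr) eta_shared + sqrt(1 - corr) eta_k`), so
#' their sample correlation approaches `corr`; both are shifted by
#' `mean`.
#'
#' @param duration Length of the series (ms).
#' @param dt Step (ms), smaller than `tau_AMPA`.
#' @param tau_AMPA OU time constant (ms).
#' @param sigma_noise Noise magnitude (nA).
#' @param corr Target correlation in `[0, 1]`.
#' @param mean Mean offset (nA).
#' @param seed Integer seed.
#' @return A tibble with columns `time_ms`, `i1`, `i2` (nA).
#' @export
ou_noise <- function(duration, dt = 0.5, tau_AMPA = 2, sigma_noise = 0.018,
                     corr = 0, mean = 0, seed = 1) {
  if (corr < 0 || corr > 1) stop("corr must be in [0, 1]")
  n <- round(duration / dt)
  m <- ou_pair_cpp(n, dt, tau_AMPA, sigma_noise, corr, mean, seed)
  tibble::tibble(time_ms = seq_len(n) * dt, i1 = m[1, ], i2 = m[2, ])
}

decode_decision <- function(code) c("none", "A", "B")[code + 1L]

#' Run one decision trial of the frontoparietal circuit
#'
#' Integrates the four-population winner-take-all circuit with evidence
#' currents favoring option A and correlated OU noise. The first PFC
#' population to reach the firing-rate threshold fixes the decision and
#' the integration time (measured from stimulus onset); if neither
#' crosses before `trial_max`, the decision is `"none"`.
#'
#' @param p A [dm_params()] list.
#' @param noise A [noise_spec()] list.
#' @param seed Integer seed.
#' @param record Record rate trajectories (5 ms resolution).
#' @return A list of class `dm_trial` with `decision` (`"A"`, `"B"` or
#'   `"none"`), `integration_time` (ms, `NA` when none) and optionally
#'   `trajectories` (tibble: time_ms, population, rate).
#' @export
dm_trial <- function(p = dm_params(), noise = noise_spec(), seed = 1,
                     record = FALSE) {
  res <- dm_trials_cpp(unclass(p), 1L, seed,
                       noise$mean_ppc, noise$mean_pfc,
                       noise$corr_ppc, noise$corr_pfc,
                       p$I_e, p$c_prime, p$threshold, p$trial_max,
                       p$settle, p$dt,
                       numeric(0), numeric(0), integer(0),
                       record, 5)
  out <- list(decision = decode_decision(res$decision[1]),
              integration_time = res$rt[1])
  if (record) {
    tr <- res$traj[[1]]
    keep <- !is.na(tr[1, ])
    out$trajectories <- tibble::tibble(
      time_ms = rep((which(keep) - 1) * 5, each = 4) - p$settle,
      population = rep(c("A_PPC", "B_PPC", "A_PFC", "B_PFC"),
                       times = sum(keep)),
      rate = as.vector(tr[, keep]))
  }
  structure(out, class = "dm_trial")
}

#' Repeated decision trials: accuracy and integration time
#'
#' Runs `n_trials` independent decision trials (per-trial seeds derived
#' from the master seed) and summarizes the percentage of correct
#' (option A) decisions and the mean integration time over decided
#' trials.
#'
#' @param p A [dm_params()] list.
#' @param noise A [noise_spec()] list.
#' @param n_trials Number of trials (>= 1).
#' @param seed Master seed.
#' @param drive_ppc,drive_pfc Optional external drive series (nA, at the
#'   circuit `dt`) replacing the OU mean offsets; used for multiscale
#'   coupling.
#' @param drive_offsets Optional per-trial 0-based start offsets into the
#'   drive series.
#' @return A one-row tibble: `pct_correct`, `mean_integration_time`
#'   (ms), `n_decided`, `n_none`, `n_trials`, `flag` (`"ok"` or
#'   `"no_decisions"`).
#' @export
dm_experiment <- function(p = dm_params(), noise = noise_spec(),
                          n_trials = 1000, seed = 1,
                          drive_ppc = numeric(0), drive_pfc = numeric(0),
                          drive_offsets = integer(0)) {
  stopifnot(n_trials >= 1)
  if (length(drive_ppc) > 0) {
    need <- round((p$settle + p$trial_max) / p$dt)
    if (length(drive_offsets) == 0) drive_offsets <- 0L
    if (length(drive_ppc) < need + max(drive_offsets) ||
        length(drive_pfc) < need + max(drive_offsets))
      stop("external drive series shorter than settle + trial_max")
  }
  res <- dm_trials_cpp(unclass(p), as.integer(n_trials), seed,
                       noise$mean_ppc, noise$mean_pfc,
                       noise$corr_ppc, noise$corr_pfc,
                       p$I_e, p$c_prime, p$threshold, p$trial_max,
                       p$settle, p$dt,
                       drive_ppc, drive_pfc, as.integer(drive_offsets),
                       FALSE, 5)
  dec <- res$decision
  decided <- dec != 0L
  tibble::tibble(
    pct_correct = 100 * sum(dec == 1L) / n_trials,
    mean_integration_time = if (any(decided))
      mean(res$rt[decided]) else NA_real_,
    n_decided = sum(decided), n_none = sum(!decided),
    n_trials = n_trials,
    flag = if (any(decided)) "ok" else "no_decisions")
}

#' Sweep noise conditions of the decision circuit
#'
#' Crosses the supplied grids of mean offsets and noise correlations and
#' runs a [dm_experiment()] at every combination.
#'
#' @param p A [dm_params()] list.
#' @param means Grid of mean offsets applied to both modules (nA), or a
#'   two-column data frame with `mean_ppc`, `mean_pfc`.
#' @param corr_ppc,corr_pfc Correlation grids.
#' @param n_trials Trials per condition.
#' @param seed Master seed; condition seeds derived reproducibly.
#' @return A tibble of class `dm_sweep`: one row per condition with the
#'   noise settings and the [dm_experiment()] summaries.
#' @export
dm_sweep <- function(p = dm_params(), means = 0, corr_ppc = 0,
                     corr_pfc = 0, n_trials = 500, seed = 1) {
  if (is.data.frame(means)) {
    grid <- tidyr::expand_grid(.m = seq_len(nrow(means)),
                               corr_ppc = corr_ppc, corr_pfc = corr_pfc)
    grid$mean_ppc <- means$mean_ppc[grid$.m]
    grid$mean_pfc <- means$mean_pfc[grid$.m]
    grid$.m <- NULL
  } else {
    grid <- tidyr::expand_grid(mean_ppc = means, corr_ppc = corr_ppc,
                               corr_pfc = corr_pfc)
    grid$mean_pfc <- grid$mean_ppc
  }
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    ns <- noise_spec(g$mean_ppc, g$mean_pfc, g$corr_ppc, g$corr_pfc)
    dplyr::bind_cols(g, dm_experiment(p, ns, n_trials,
                                      derive_seed(seed, i)))
  })
  class(res) <- c("dm_sweep", class(res))
  res
}

#' @exportS3Method ggplot2::autoplot
autoplot.dm_sweep <- function(object, x = NULL, ...) {
  if (is.null(x)) {
    x <- if (dplyr::n_distinct(object$corr_ppc) > 1) "corr_ppc"
    else if (dplyr::n_distinct(object$mean_ppc) > 1) "mean_ppc"
    else "corr_pfc"
  }
  long <- tidyr::pivot_longer(object,
                              c("pct_correct", "mean_integration_time"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[x]], y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = x, y = NULL)
}
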