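#' Working-memory trial with target and distractor
#'
#' Applies a boxcar target stimulus to one PPC population, a distractor
#' of the same shape to the rival population 1.5 s later, and classifies
#' the outcome from the persistent activity: `no_induction` if the target
#' population shows no elevated persistent activity before the
#' distractor, `robust` if its persistent activity survives the
#' distractor, `disrupted` otherwise. Memory is scored as present when
#' the population's window-averaged rate exceeds 20 Hz and exceeds the
#' rival's by 10 Hz.
#'
#' @param p A [dm_params()] list.
#' @param J_S Net within-module recurrent strength (nA): self-excitation
#'   minus cross-inhibition. The default couplings are shifted
#'   symmetrically (`J_s + delta/2`, `J_c - delta/2`) to reach `J_S`.
#' @param I_app Target stimulus amplitude (nA).
#' @param input_amplitude Mean offset of the OU input noise to all
#'   populations (nA).
#' @param seed Integer seed.
#' @param I_dist Distractor amplitude (nA); defaults to `I_app`.
#' @param t_target Target onset (ms).
#' @param stim_dur Stimulus boxcar duration (ms).
#' @param delay Target-to-distractor delay (ms).
#' @param post Time simulated after distractor offset (ms); the final
#'   500 ms are the classification window.
#' @param record Return rate trajectories.
#' @return A list of class `wm_trial` with `regime` (one of
#'   `"no_induction"`, `"disrupted"`, `"robust"`), the window-averaged
#'   rates used for classification, and optionally `trajectories`.
#' @export
wm_trial <- function(p = dm_params(), J_S = p$J_s - p$J_c, I_app = 0.02,
                     input_amplitude = 0, seed = 1, I_dist = I_app,
                     t_target = 500, stim_dur = 250, delay = 1500,
                     post = 1250, record = FALSE) {
  delta <- J_S - (p$J_s - p$J_c)
  p2 <- dm_params(J_s = p$J_s + delta / 2, J_c = p$J_c - delta / 2,
                  J_ff = p$J_ff, J_ffc = p$J_ffc, J_fb = p$J_fb,
                  J_fbc = p$J_fbc, I0_dm = p$I0_dm, a = p$a, b = p$b,
                  c = p$c, tau = p$tau, gamma = p$gamma,
                  tau_AMPA = p$tau_AMPA, sigma_noise = p$sigma_noise,
                  threshold = p$threshold, I_e = p$I_e,
                  c_prime = p$c_prime, trial_max = p$trial_max,
                  settle = p$settle, dt = p$dt)
  res <- wm_trial_cpp(unclass(p2), seed, I_app, I_dist, input_amplitude,
                      0, t_target, stim_dur, delay, post, p$dt, record, 5)
  has_mem <- function(a, b) is.finite(a) && a > 20 && (a - b) > 10
  induced <- has_mem(res$pre_target, res$pre_rival)
  persisted <- has_mem(res$final_target, res$final_rival)
  regime <- if (!induced) "no_induction"
  else if (persisted) "robust" else "disrupted"
  out <- list(regime = regime, J_S = J_S, I_app = I_app,
              input_amplitude = input_amplitude,
              pre_target = res$pre_target, pre_rival = res$pre_rival,
              final_target = res$final_target,
              final_rival = res$final_rival)
  if (record) {
    tr <- res$traj
    keep <- !is.na(tr[1, ])
    out$trajectories <- tibble::tibble(
      time_ms = rep((which(keep) - 1) * 5, each = 4),
      population = rep(c("A_PPC", "B_PPC", "A_PFC", "B_PFC"),
                       times = sum(keep)),
      rate = as.vector(tr[, keep]))
  }
  structure(out, class = "wm_trial")
}

#' Working-memory bifurcation map
#'
#' Classifies the [wm_trial()] outcome on a grid of net recurrent
#' strength `J_S` and stimulus amplitude `I_app`, taking the majority
#' regime over the supplied seeds at each grid point.
#'
#' @param p A [dm_params()] list.
#' @param J_S_grid,I_app_grid Nonempty parameter grids.
#' @param input_amplitude Mean input-noise offset (nA).
#' @param seeds Integer seeds (majority vote across them).
#' @param ... Passed to [wm_trial()].
#' @return A tibble of class `wm_map` with columns `J_S`, `I_app`,
#'   `regime`.
#' @export
bifurcation_map <- function(p = dm_params(), J_S_grid, I_app_grid,
                            input_amplitude = 0, seeds = 1:3, ...) {
  stopifnot(length(J_S_grid) > 0, length(I_app_grid) > 0)
  grid <- tidyr::expand_grid(J_S = J_S_grid, I_app = I_app_grid)
  res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    regimes <- vapply(seeds, function(s)
      wm_trial(p, J_S = g$J_S, I_app = g$I_app,
               input_amplitude = input_amplitude, seed = s, ...)$regime,
      character(1))
    tab <- sort(table(factor(regimes, c("no_induction", "disrupted",
                                        "robust"))), decreasing = TRUE)
    tibble::tibble(J_S = g$J_S, I_app = g$I_app,
                   regime = names(tab)[1])
  })
  class(res) <- c("wm_map", class(res))
  res
}

#' @exportS3Method ggplot2::autoplot
autoplot.wm_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$J_S, y = .data$I_app,
                                       fill = .data$regime)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "net recurrent strength J_S (nA)",
                  y = "stimulus amplitude I_app (nA)")
}

#' Minimum stimulus inducing working memory
#'
#' Convenience reduction of a [bifurcation_map()]: for each `J_S`, the
#' smallest `I_app` whose majority regime is not `no_induction`
#' (induction threshold), and the smallest whose regime is `robust`.
#'
#' @param map A `wm_map` tibble.
#' @return A tibble with `J_S`, `induction_threshold`,
#'   `robustness_threshold` (NA when never reached on the grid).
#' @export
wm_thresholds <- function(map) {
  map |>
    dplyr::group_by(.data$J_S) |>
    dplyr::summarise(
      induction_threshold = suppressWarnings(
        min(.data$I_app[.data$regime != "no_induction"])),
      robustness_threshold = suppressWarnings(
        min(.data$I_app[.data$regime == "robust"])),
      .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::ends_with("threshold"),
                                ~ifelse(is.infinite(.x), NA_real_, .x)))
}
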