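#' Functional connectivity from BOLD series
#'
#' Pairwise Pearson correlations between the node rows of a BOLD matrix.
#'
#' @param bold Matrix node x TR with at least two columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
compute_fc <- function(bold) {
  bold <- as.matrix(bold)
  if (ncol(bold) < 2) stop("need at least two TRs")
  v <- apply(bold, 1, stats::var)
  if (any(v <= 0)) {
    stop("zero-variance BOLD at node ", paste(which(v <= 0), collapse = ", "))
  }
  fc <- stats::cor(t(bold))
  diag(fc) <- 1
  unname(fc)
}

#' Mean functional connectivity
#'
#' Average of the strictly-upper-triangle entries of an FC matrix; the
#' constant unit diagonal is excluded.
#'
#' @param fc Square correlation matrix.
#' @return Scalar mean FC.
#' @export
mean_fc <- function(fc) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  if (n < 2) stop("mean FC needs at least two nodes")
  mean(fc[upper.tri(fc)])
}

#' Amplitude and synchrony summary of synaptic currents
#'
#' @param currents_E Matrix node x time of excitatory input currents.
#' @return A tibble with `mean_amplitude` (grand mean, nA) and
#'   `mean_correlation` (average pairwise Pearson correlation between the
#'   node series).
#' @export
input_summary <- function(currents_E) {
  currents_E <- as.matrix(currents_E)
  if (ncol(currents_E) < 2) stop("need at least two time points")
  v <- apply(currents_E, 1, stats::var)
  if (any(v <= 0))
    stop("constant current series at node ",
         paste(which(v <= 0), collapse = ", "), ": correlation undefined")
  rho <- stats::cor(t(currents_E))
  tibble::tibble(
    mean_amplitude = mean(currents_E),
    mean_correlation = mean(rho[upper.tri(rho)]))
}

#' E/I-ratio tuning curves on the two-node network
#'
#' For each ratio `q` on the grid, sets `w_LRE = q/(1+q)` and
#' `w_FFI = 1/(1+q)` on both connections of the two-node network (so the
#' total long-range input is constant at 1), simulates the model with or
#' without feedback inhibition control, and summarizes FC, input-current
#' synchrony, amplitude and variance, and the local inhibitory weights.
#'
#' @param ratios E/I-ratio grid (within `[0.01, 100]`).
#' @param fic Logical, feedback inhibition control on or off.
#' @param repeats Number of repeated simulations per grid point (averaged
#'   when `summarize = TRUE`).
#' @param seed Master seed; per-run seeds are derived reproducibly.
#' @param duration Measurement time per run (ms).
#' @param burn_in Discarded initial time per run (ms).
#' @param summarize Average the repeats per grid point (default) or
#'   return one row per run.
#' @param params,fic_par Model parameter lists.
#' @return A tibble with columns `ratio`, `w_lre`, `w_ffi`, `fc`,
#'   `input_correlation`, `input_amplitude`, `input_variance`, `mean_J`
#'   (and `rep` when `summarize = FALSE`).
#' @export
two_node_sweep <- function(ratios = 10^seq(-2, 2, length.out = 9),
                           fic = TRUE, repeats = 3, seed = 1,
                           duration = 6 * 60 * 1000,
                           burn_in = 4 * 60 * 1000,
                           summarize = TRUE,
                           params = dmf_params(), fic_par = fic_params()) {
  stopifnot(all(ratios >= 0.01), all(ratios <= 100), repeats >= 1)
  C <- two_node_connectome()
  grid <- tidyr::expand_grid(ratio = ratios, rep = seq_len(repeats))
  res <- purrr::pmap_dfr(grid, function(ratio, rep) {
    w <- ei_ratio_weights(ratio)
    W <- coupling_weights(2, w$w_lre, w$w_ffi, 1)
    sim <- simulate_bnm(C, duration = burn_in + duration,
                        seed = derive_seed(seed, rep * 1000 +
                                             match(ratio, ratios)),
                        weights = W, params = params, fic = fic,
                        fic_par = fic_par)
    keep <- seq_len(ncol(sim$bold)) > burn_in / sim$tr
    cur <- sim$currents_E[, keep, drop = FALSE]
    isum <- input_summary(cur)
    tibble::tibble(
      ratio = ratio, rep = rep, w_lre = w$w_lre, w_ffi = w$w_ffi,
      fc = compute_fc(sim$bold[, keep, drop = FALSE])[1, 2],
      input_correlation = isum$mean_correlation,
      input_amplitude = isum$mean_amplitude,
      input_variance = mean(apply(cur, 1, stats::var)),
      mean_J = mean(sim$weights$J))
  })
  if (summarize) {
    res <- res |>
      dplyr::group_by(.data$ratio, .data$w_lre, .data$w_ffi) |>
      dplyr::summarise(dplyr::across(c("fc", "input_correlation",
                                       "input_amplitude", "input_variance",
                                       "mean_J"), mean),
                       n_reps = dplyr::n(), .groups = "drop")
  }
  class(res) <- c("bnm_sweep", class(res))
  res
}

#' @exportS3Method ggplot2::autoplot
autoplot.bnm_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "ratio", "fc", "input_correlation",
                  "input_amplitude", "input_variance", "mean_J"),
    -"ratio", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ratio, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "E/I ratio (w_LRE / w_FFI)", y = NULL)
}
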