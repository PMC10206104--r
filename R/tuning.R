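# Staged online E/I-tuning: the learning loop runs inside the C++ engine
# (one update per TR); this file orchestrates stages, carries state and
# trailing BOLD history across them, and runs the tuning-free validation.

#' Fit coupling weights so simulated FC matches a target FC
#'
#' Runs the online learning rule that adjusts the long-range excitation
#' and feedforward inhibition multipliers of every structural connection
#' after each new BOLD sample, scaled by the row-wise FC misfit. The fit
#' proceeds through the staged schedule (learning rate halved, FC window
#' doubled per stage). Feedback inhibition control stays active
#' throughout. The reported fit quality comes from a tuning-free
#' validation run with a fresh seed and frozen weights.
#'
#' @param C Structural connectome matrix.
#' @param rho_trg Target FC: symmetric correlation matrix, unit diagonal,
#'   same dimension as `C`.
#' @param schedule A [tuning_schedule()].
#' @param seed Integer master seed (stage and validation seeds derived).
#' @param mode `"EI"` updates both weight families; `"E_only"` updates
#'   only `w_LRE` and leaves `w_FFI` frozen.
#' @param weights Initial [coupling_weights()]; default balanced,
#'   `w_LRE = w_FFI = 0.5` and `J = 1`. The balanced start keeps the
#'   per-connection total at the untuned value 1 while placing the
#'   E/I-ratio at 1, so both weight families are adjustable from the
#'   first update (the clamp at zero makes a `w_FFI = 0` start slow to
#'   build feedforward inhibition where the target needs it).
#' @param params,hemo,fic_par Model parameter lists.
#' @param tr,dt Sampling period and integration step (ms).
#' @param settle Pre-tuning settling time (ms); defaults to one initial
#'   FC window so tuning can start immediately in stage 1.
#' @param validate Run the tuning-free validation simulation.
#' @param validate_duration Validation length (ms).
#' @param validate_seed Seed of the validation run; supply a common value
#'   to compare refits under shared noise. Default: derived from `seed`.
#' @param validate_burn TRs discarded at the start of the validation run.
#' @param validate_fic Keep FIC plasticity running during validation;
#'   the homeostat is part of the model, and the target FC of a
#'   ground-truth run is itself measured with it active.
#' @return An object of class `ei_fit` with elements `weights`, `trace`
#'   (tibble: stage, tr, fc_r, fc_rmse, mean_w_lre, mean_w_ffi, eta,
#'   window), `validation` (list: `fc`, `r`, `rmse`, `seed`), plus the
#'   inputs.
#' @export
fit_ei <- function(C, rho_trg, schedule = tuning_schedule(), seed = 1,
                   mode = c("EI", "E_only"), weights = NULL,
                   params = dmf_params(), hemo = hemo_params(),
                   fic_par = fic_params(), tr = 720, dt = 1,
                   settle = NULL, validate = TRUE,
                   validate_duration = 30 * 60 * 1000,
                   validate_seed = NULL, validate_burn = 150,
                   validate_fic = TRUE) {
  mode <- match.arg(mode)
  C <- validate_connectome(C)
  n <- nrow(C)
  stopifnot(all(dim(rho_trg) == n))
  if (is.null(weights)) {
    # E-only tuning starts from the classical untuned state (no
    # feedforward inhibition, which it never updates)
    weights <- if (mode == "E_only") coupling_weights(n, 1, 0)
    else coupling_weights(n, 0.5, 0.5)
  }
  if (is.null(settle)) settle <- schedule$window_start * tr

  w_lre <- weights$w_LRE; w_ffi <- weights$w_FFI; J <- weights$J
  S_E <- S_I <- numeric(0)
  hstate <- matrix(numeric(0), 0, 0)
  hist <- matrix(numeric(0), n, 0)
  trace <- list()
  tr_offset <- 0L

  run_stage <- function(duration, tuning, eta, window, stage_seed) {
    dmf_engine_cpp(C, w_lre, w_ffi, J, unclass(params), unclass(hemo),
                   duration, dt, tr, stage_seed,
                   TRUE, unclass(fic_par),
                   tuning, rho_trg, eta, as.integer(window),
                   mode == "EI",
                   S_E, S_I, hstate, hist, integer(0))
  }

  # settle: FIC active, no tuning; fills the first FC window
  if (settle > 0) {
    res <- run_stage(settle, FALSE, 0, 2L, derive_seed(seed, 0))
    w_lre <- res$w_LRE; w_ffi <- res$w_FFI; J <- res$J
    S_E <- res$S_E; S_I <- res$S_I; hstate <- res$hemo
    hist <- cbind(hist, res$bold)
    tr_offset <- tr_offset + ncol(res$bold)
  }

  max_window <- schedule$window_start * 2^(schedule$n_stages - 1)
  for (k in seq_len(schedule$n_stages)) {
    eta_k <- schedule$eta_start / 2^(k - 1)
    window_k <- schedule$window_start * 2^(k - 1)
    keep <- min(ncol(hist), window_k)
    hist_k <- hist[, seq(ncol(hist) - keep + 1, length.out = keep),
                   drop = FALSE]
    res <- dmf_engine_cpp(C, w_lre, w_ffi, J, unclass(params),
                          unclass(hemo),
                          schedule$stage_duration, dt, tr,
                          derive_seed(seed, k),
                          TRUE, unclass(fic_par),
                          TRUE, rho_trg, eta_k, as.integer(window_k),
                          mode == "EI",
                          S_E, S_I, hstate, hist_k, integer(0))
    w_lre <- res$w_LRE; w_ffi <- res$w_FFI; J <- res$J
    S_E <- res$S_E; S_I <- res$S_I; hstate <- res$hemo
    hist <- cbind(hist, res$bold)
    if (ncol(hist) > max_window)
      hist <- hist[, seq(ncol(hist) - max_window + 1,
                         length.out = max_window), drop = FALSE]
    tt <- res$trace
    if (length(tt$tr) > 0) {
      trace[[k]] <- tibble::tibble(
        stage = k, tr = tr_offset + unlist(tt$tr),
        fc_r = unlist(tt$fc_r), fc_rmse = unlist(tt$fc_rmse),
        mean_w_lre = unlist(tt$mean_w_lre),
        mean_w_ffi = unlist(tt$mean_w_ffi),
        eta = eta_k, window = window_k)
    }
    tr_offset <- tr_offset + round(schedule$stage_duration / tr)
  }

  fitted <- coupling_weights(n, w_lre, w_ffi, J)
  validation <- NULL
  if (validate) {
    vseed <- if (is.null(validate_seed)) derive_seed(seed, 999) else
      validate_seed
    vsim <- simulate_bnm(C, duration = validate_duration, dt = dt, tr = tr,
                         seed = vseed, weights = fitted, params = params,
                         hemo = hemo, fic = validate_fic,
                         fic_par = fic_par)
    keep <- seq_len(ncol(vsim$bold)) > validate_burn
    fc <- compute_fc(vsim$bold[, keep, drop = FALSE])
    ut <- upper.tri(fc)
    validation <- list(fc = fc,
                       r = stats::cor(fc[ut], rho_trg[ut]),
                       rmse = sqrt(mean((fc[ut] - rho_trg[ut])^2)),
                       mean_rate_E = mean(vsim$rates_E[, keep]),
                       seed = vseed)
  }
  structure(list(weights = fitted, trace = dplyr::bind_rows(trace),
                 validation = validation, rho_trg = rho_trg, C = C,
                 schedule = schedule, mode = mode, seed = seed,
                 params = params, tr = tr, dt = dt),
            class = "ei_fit")
}

#' @export
print.ei_fit <- function(x, ...) {
  cat(sprintf("<ei_fit> %s tuning, %d nodes, %d stages\n", x$mode,
              nrow(x$C), x$schedule$n_stages))
  if (!is.null(x$validation))
    cat(sprintf("  validation FC vs target: r = %.4f, RMSE = %.4f\n",
                x$validation$r, x$validation$rmse))
  invisible(x)
}

#' @export
tidy.ei_fit <- function(x, ...) x$trace

#' @export
glance.ei_fit <- function(x, ...) {
  mask <- x$C > 0
  tibble::tibble(
    mode = x$mode, n_nodes = nrow(x$C),
    n_stages = x$schedule$n_stages,
    fc_r = if (is.null(x$validation)) NA_real_ else x$validation$r,
    fc_rmse = if (is.null(x$validation)) NA_real_ else x$validation$rmse,
    mean_w_lre = mean(x$weights$w_LRE[mask]),
    mean_w_ffi = mean(x$weights$w_FFI[mask]),
    mean_J = mean(x$weights$J), seed = x$seed)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ei_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              c("fc_r", "fc_rmse"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tr, y = .data$value,
                                     color = factor(.data$stage))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "TR", y = NULL, color = "stage")
}

#' Compare fitting variants on one target
#'
#' `"EI"` runs the full algorithm, `"E_only"` updates only the long-range
#' excitation weights, and `"global_scalar"` grid-searches a single
#' scalar `G` rescaling the whole connectome (the classical approach),
#' each reporting the validation FC correlation and RMSE.
#'
#' @param C,rho_trg Connectome and target FC.
#' @param mode One of `"EI"`, `"E_only"`, `"global_scalar"`.
#' @param schedule Schedule for the learning-based modes.
#' @param grid Scalar grid for `"global_scalar"` (nonempty).
#' @param seed Integer seed.
#' @param scalar_burn,scalar_duration Burn-in and measurement time per
#'   grid point (ms).
#' @param ... Passed to [fit_ei()].
#' @return A list with `summary` (tibble: mode, fc_r, fc_rmse, and for
#'   the scalar mode `G`), and `fit` (the `ei_fit` object, learning modes
#'   only).
#' @export
fit_variant <- function(C, rho_trg, mode = c("EI", "E_only",
                                             "global_scalar"),
                        schedule = tuning_schedule(),
                        grid = 2^seq(-3, 3, length.out = 13),
                        seed = 1, scalar_burn = 4 * 60 * 1000,
                        scalar_duration = 10 * 60 * 1000, ...) {
  mode <- match.arg(mode)
  if (mode %in% c("EI", "E_only")) {
    fit <- fit_ei(C, rho_trg, schedule = schedule, seed = seed,
                  mode = mode, ...)
    return(list(summary = tibble::tibble(mode = mode,
                                         fc_r = fit$validation$r,
                                         fc_rmse = fit$validation$rmse),
                fit = fit))
  }
  if (length(grid) == 0) stop("empty grid for global_scalar mode")
  ut <- upper.tri(rho_trg)
  per_g <- purrr::map_dfr(seq_along(grid), function(gi) {
    G <- grid[gi]
    sim <- simulate_bnm(C * G, duration = scalar_burn + scalar_duration,
                        seed = derive_seed(seed, gi), fic = TRUE)
    keep <- seq_len(ncol(sim$bold)) > scalar_burn / sim$tr
    fc <- compute_fc(sim$bold[, keep, drop = FALSE])
    tibble::tibble(G = G, fc_r = stats::cor(fc[ut], rho_trg[ut]),
                   fc_rmse = sqrt(mean((fc[ut] - rho_trg[ut])^2)))
  })
  best <- per_g[which.max(per_g$fc_r), ]
  list(summary = tibble::tibble(mode = mode, fc_r = best$fc_r,
                                fc_rmse = best$fc_rmse, G = best$G),
       grid_results = per_g, fit = NULL)
}
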