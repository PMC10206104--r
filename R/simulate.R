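#' Simulate the large-scale brain network model
#'
#' Integrates the coupled excitatory/inhibitory neural-mass network with
#' Euler-Maruyama at step `dt`, runs the Balloon-Windkessel hemodynamic
#' model per node, and samples BOLD plus window-averaged rates and currents
#' once every repetition time `tr`. Feedback inhibition control (FIC) can
#' be switched on to regulate the local inhibitory weights online.
#' Identical seed and inputs give bitwise-identical output.
#'
#' @param C Structural connectome: square nonnegative matrix with zero
#'   diagonal.
#' @param duration Biological time to simulate (ms).
#' @param dt Integration step (ms).
#' @param tr Sampling period / repetition time (ms).
#' @param seed Integer seed for the simulation noise.
#' @param weights A [coupling_weights()] list; default `w_LRE = 1`,
#'   `w_FFI = 0`, `J = 1`.
#' @param params,hemo,fic_par Parameter lists ([dmf_params()],
#'   [hemo_params()], [fic_params()]).
#' @param fic Logical: apply feedback inhibition control during the run.
#' @param init Optional list with elements `S_E`, `S_I` (initial gating)
#'   and optionally `hemo` (4 x n hemodynamic state); default: gating 0.1
#'   plus seeded uniform jitter of +/- 0.01, hemodynamics at rest.
#' @param record_nodes Integer node indices whose excitatory input current
#'   is additionally recorded at full `dt` resolution (used for coupling a
#'   decision circuit).
#' @return An object of class `bnm_sim`: a list with TR-sampled matrices
#'   `bold`, `rates_E`, `rates_I`, `currents_E` (window averages),
#'   `gating_E` (instantaneous), the final `weights` (including the
#'   FIC-adapted `J`), `fine_currents_E` for `record_nodes`, and the
#'   simulation metadata `dt`, `tr`, `seed`.
#' @export
#' @examples
#' C <- two_node_connectome()
#' sim <- simulate_bnm(C, duration = 60 * 720, seed = 1)
#' mean_fc(compute_fc(sim$bold))
simulate_bnm <- function(C, duration, dt = 1, tr = 720, seed = 1,
                         weights = NULL, params = dmf_params(),
                         hemo = hemo_params(), fic = TRUE,
                         fic_par = fic_params(), init = NULL,
                         record_nodes = integer(0)) {
  C <- validate_connectome(C)
  n <- nrow(C)
  if (is.null(weights)) weights <- coupling_weights(n)
  stopifnot(weights$n == n, duration >= tr, tr >= dt, dt > 0)
  S_E <- S_I <- numeric(0)
  hstate <- matrix(numeric(0), 0, 0)
  if (!is.null(init)) {
    S_E <- init$S_E; S_I <- init$S_I
    if (!is.null(init$hemo)) hstate <- init$hemo
  }
  res <- dmf_engine_cpp(C, weights$w_LRE, weights$w_FFI, weights$J,
                        unclass(params), unclass(hemo),
                        duration, dt, tr, seed,
                        fic, unclass(fic_par),
                        FALSE, matrix(0, 1, 1), 0, 2L, TRUE,
                        S_E, S_I, hstate,
                        matrix(numeric(0), n, 0),
                        as.integer(record_nodes))
  structure(list(bold = res$bold, rates_E = res$rates_E,
                 rates_I = res$rates_I, currents_E = res$currents_E,
                 gating_E = res$gating_E,
                 weights = coupling_weights(n, res$w_LRE, res$w_FFI, res$J),
                 state = list(S_E = res$S_E, S_I = res$S_I,
                              hemo = res$hemo),
                 fine_currents_E = res$fine_currents_E,
                 record_nodes = as.integer(record_nodes),
                 C = C, params = params, hemo_par = hemo,
                 fic = fic, dt = dt, tr = tr, seed = seed,
                 duration = duration),
            class = "bnm_sim")
}

#' @export
print.bnm_sim <- function(x, ...) {
  cat(sprintf(
    "<bnm_sim> %d nodes, %.1f min biological time, %d TRs (tr = %g ms, dt = %g ms)\n",
    nrow(x$bold), x$duration / 60000, ncol(x$bold), x$tr, x$dt))
  cat(sprintf("  FIC %s | mean r_E = %.2f Hz | mean FC = %.3f | seed %s\n",
              if (x$fic) "on" else "off", mean(x$rates_E),
              tryCatch(mean_fc(compute_fc(x$bold)), error = function(e) NA),
              format(x$seed)))
  invisible(x)
}

#' @export
tidy.bnm_sim <- function(x, series = c("bold", "rates_E", "currents_E",
                                       "gating_E"), ...) {
  series <- match.arg(series)
  m <- x[[series]]
  tibble::tibble(
    node = rep(seq_len(nrow(m)), times = ncol(m)),
    time_ms = rep(seq_len(ncol(m)) * x$tr, each = nrow(m)),
    value = as.vector(m),
    series = series)
}

#' @export
glance.bnm_sim <- function(x, ...) {
  fc <- tryCatch(mean_fc(compute_fc(x$bold)), error = function(e) NA_real_)
  tibble::tibble(
    n_nodes = nrow(x$bold), n_tr = ncol(x$bold),
    duration_min = x$duration / 60000, fic = x$fic,
    mean_rate_E = mean(x$rates_E), mean_fc = fc,
    mean_current_E = mean(x$currents_E), seed = x$seed)
}

# shared input validation for connectome matrices
validate_connectome <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("connectome must be square")
  if (any(!is.finite(C))) stop("connectome entries must be finite")
  if (any(C < 0)) stop("connectome entries must be nonnegative")
  if (any(diag(C) != 0)) stop("connectome diagonal must be zero")
  unname(C)
}

#' The canonical two-node connectome
#'
#' Two nodes with mutual coupling strength 1, the reduced network used for
#' E/I-ratio tuning curves.
#' @return A 2 x 2 matrix.
#' @export
two_node_connectome <- function() {
  matrix(c(0, 1, 1, 0), 2, 2)
}
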