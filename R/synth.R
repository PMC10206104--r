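#' Generate a synthetic structural connectome
#'
#' Draws a symmetric, nonnegative, zero-diagonal coupling matrix:
#' connectivity is guaranteed by a random spanning tree, additional edges
#' are added to the requested density, edge weights are log-normal, and
#' the matrix is normalized so that the maximum row sum equals 1.
#'
#' @param n Number of nodes (>= 2).
#' @param density Fraction of nonzero off-diagonal pairs, in (0, 1].
#' @param mu,sigma_w Log-normal weight parameters (meanlog, sdlog).
#' @param seed Integer seed.
#' @return An n x n connectome matrix.
#' @export
#' @examples
#' C <- synth_connectome(10, density = 0.4, seed = 1)
synth_connectome <- function(n, density = 0.25, mu = -0.5, sigma_w = 0.6,
                             seed = 1) {
  stopifnot(n >= 2, density > 0, density <= 1)
  n_pairs <- n * (n - 1) / 2
  m_target <- round(density * n_pairs)
  if (m_target < n - 1)
    stop("density too low to connect ", n, " nodes: need at least ",
         (n - 1) / n_pairs)
  withr::with_seed(seed, {
    perm <- sample(n)
    edges <- matrix(NA_integer_, m_target, 2)
    for (k in 2:n) {
      e <- sort(c(perm[k], perm[sample.int(k - 1, 1)]))
      edges[k - 1, ] <- e
    }
    all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    key <- function(i, j) (i - 1) * n + j
    used <- key(edges[seq_len(n - 1), 1], edges[seq_len(n - 1), 2])
    free <- which(!(key(all_pairs[, 1], all_pairs[, 2]) %in% used))
    extra <- m_target - (n - 1)
    if (extra > 0) {
      pick <- free[sample.int(length(free), extra)]
      edges[n:(n - 1 + extra), ] <- all_pairs[pick, , drop = FALSE]
    }
    w <- stats::rlnorm(m_target, mu, sigma_w)
    C <- matrix(0, n, n)
    C[edges] <- w
    C[edges[, 2:1, drop = FALSE]] <- w
    C / max(rowSums(C))
  })
}

#' Generate a ground-truth target FC from a known-weight model
#'
#' Draws random per-connection E/I-ratios (log-normal, supported only on
#' the connectome's edges), maps them to `w_LRE`/`w_FFI` under the
#' unit-sum convention, runs the model with feedback inhibition control
#' through a burn-in until the inhibitory weights settle, and returns the
#' FC of a subsequent measurement period as the fitting target, together
#' with the generating weights. Because the target comes from the model
#' itself, it is attainable by construction.
#'
#' @param C Connectome matrix.
#' @param seed Integer seed.
#' @param ei_center Center of the generating E/I-ratio distribution (the
#'   log-normal median).
#' @param ei_spread sdlog of the generating E/I-ratio distribution.
#' @param coupling_scale Total long-range weight per connection
#'   (`w_LRE + w_FFI`). Default `0.45 / mean(C[C > 0])`: the typical
#'   per-connection coupling mass `w * C` is then comparable across
#'   network sizes and densities, which row-normalized connectomes
#'   otherwise dilute, while keeping weight totals that the staged
#'   online fit can traverse from the untuned state.
#' @param burn_in FIC settling time discarded before measurement (ms).
#' @param duration Measurement time for the target FC (ms).
#' @param params,hemo,fic_par Model parameter lists.
#' @param rate_tol FIC convergence check: the time-averaged excitatory
#'   rate of every node over the final quarter of the burn-in must lie
#'   within `rate_tol` of the FIC set point, otherwise an error is raised.
#' @return A list of class `bnm_target` with elements `rho_trg`,
#'   `weights` (generating weights incl. converged `J`), `C`, `mean_fc`
#'   and `seed`.
#' @export
synth_target <- function(C, seed = 1, ei_center = 1, ei_spread = 1.0,
                         coupling_scale = NULL,
                         burn_in = 6 * 60 * 1000,
                         duration = 30 * 60 * 1000,
                         params = dmf_params(), hemo = hemo_params(),
                         fic_par = fic_params(), rate_tol = 1.5) {
  C <- validate_connectome(C)
  n <- nrow(C)
  if (is.null(coupling_scale)) coupling_scale <- 0.45 / mean(C[C > 0])
  q <- withr::with_seed(seed, {
    qm <- matrix(0, n, n)
    idx <- which(C > 0)
    qm[idx] <- stats::rlnorm(length(idx), log(ei_center), ei_spread)
    qm
  })
  w_lre <- w_ffi <- matrix(0, n, n)
  idx <- which(C > 0)
  w_lre[idx] <- coupling_scale * q[idx] / (1 + q[idx])
  w_ffi[idx] <- coupling_scale / (1 + q[idx])
  W <- coupling_weights(n, w_lre, w_ffi, 1)
  sim <- simulate_bnm(C, duration = burn_in + duration, seed = seed,
                      weights = W, params = params, hemo = hemo,
                      fic = TRUE, fic_par = fic_par)
  trs <- ncol(sim$bold)
  burn_trs <- round(burn_in / sim$tr)
  check <- seq(max(1, round(burn_trs * 0.75)), burn_trs)
  r_check <- rowMeans(sim$rates_E[, check, drop = FALSE])
  if (any(abs(r_check - fic_par$rho_0) > rate_tol))
    stop("FIC did not converge during burn-in: node rates ",
         paste(sprintf("%.2f", r_check), collapse = ", "),
         " Hz vs target ", fic_par$rho_0, " Hz; lengthen burn_in")
  keep <- seq(burn_trs + 1, trs)
  rho <- compute_fc(sim$bold[, keep, drop = FALSE])
  structure(list(rho_trg = rho, weights = sim$weights, C = C,
                 mean_fc = mean_fc(rho), ei_center = ei_center,
                 seed = seed),
            class = "bnm_target")
}

#' @export
print.bnm_target <- function(x, ...) {
  cat(sprintf(
    "<bnm_target> %d nodes | mean FC %.3f | off-diagonal SD %.3f | seed %s\n",
    nrow(x$rho_trg), x$mean_fc, sd(x$rho_trg[upper.tri(x$rho_trg)]),
    format(x$seed)))
  invisible(x)
}

#' Generate a synthetic cohort of ground-truth models
#'
#' Builds `K` connectome/target pairs whose generating E/I-ratio centers
#' span `exp(-heterogeneity)` to `exp(+heterogeneity)` on a log grid, so
#' the cohort's mean FC spans a controlled range (higher E/I-ratios give
#' more positive FC). `heterogeneity = 0` gives exchangeable models.
#'
#' @param K Number of models (>= 2).
#' @param n Nodes per model.
#' @param heterogeneity Half-width of the log E/I-ratio center grid.
#' @param seed Master seed; member seeds are derived reproducibly.
#' @param ... Passed to [synth_target()] (e.g. shorter `duration` for
#'   small experiments) and `density` to [synth_connectome()].
#' @param density Connectome density.
#' @return A tibble with one row per model: `model_id`, `ei_center`,
#'   `mean_fc`, and list-columns `C`, `target`.
#' @export
synth_cohort <- function(K, n = 10, heterogeneity = 0.8, seed = 1,
                         density = 0.4, ...) {
  stopifnot(K >= 2)
  centers <- exp(seq(-heterogeneity, heterogeneity, length.out = K))
  purrr::map_dfr(seq_len(K), function(k) {
    C <- synth_connectome(n, density = density, seed = derive_seed(seed, k))
    trg <- synth_target(C, seed = derive_seed(seed, 1000 + k),
                        ei_center = centers[k], ...)
    tibble::tibble(model_id = k, ei_center = centers[k],
                   mean_fc = trg$mean_fc,
                   C = list(C), target = list(trg))
  })
}
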