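#' Read and write matrices as header-free TSV
#'
#' The plain-text matrix dialect used throughout: tab-separated, no
#' header, one row per node, '.' decimal, scientific notation allowed.
#' Round-trips 64-bit doubles losslessly (values written with 17
#' significant digits).
#'
#' @param path File path.
#' @return `read_matrix_tsv`: a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' @param x Numeric matrix.
#' @rdname read_matrix_tsv
#' @return `write_matrix_tsv`: `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  xf <- format(as.matrix(x), digits = 17, scientific = TRUE,
               trim = TRUE)
  utils::write.table(xf, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Persist a simulation result as TSV matrices plus JSON metadata
#'
#' Writes `bold.tsv`, `currents_E.tsv`, `rates_E.tsv`, `gating_E.tsv`,
#' `J.tsv`, `w_LRE.tsv`, `w_FFI.tsv` and a `meta.json` holding `dt`,
#' `tr`, `seed` and dimensions into a directory.
#'
#' @param sim A `bnm_sim` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("bold", "currents_E", "rates_E", "gating_E"))
    write_matrix_tsv(sim[[nm]], file.path(dir, paste0(nm, ".tsv")))
  write_matrix_tsv(sim$weights$w_LRE, file.path(dir, "w_LRE.tsv"))
  write_matrix_tsv(sim$weights$w_FFI, file.path(dir, "w_FFI.tsv"))
  write_matrix_tsv(matrix(sim$weights$J, ncol = 1),
                   file.path(dir, "J.tsv"))
  jsonlite::write_json(
    list(dt = sim$dt, tr = sim$tr, seed = sim$seed,
         duration = sim$duration, fic = sim$fic,
         n_nodes = nrow(sim$bold), n_tr = ncol(sim$bold)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @param dir Directory written by [write_sim()].
#' @rdname write_sim
#' @return `read_sim`: a list with the stored matrices and metadata.
#' @export
read_sim <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  out <- lapply(setNames(nm = c("bold", "currents_E", "rates_E",
                                "gating_E", "w_LRE", "w_FFI")),
                function(nm) read_matrix_tsv(file.path(dir,
                                                       paste0(nm, ".tsv"))))
  out$J <- as.vector(read_matrix_tsv(file.path(dir, "J.tsv")))
  c(out, meta)
}

#' Persist fitted coupling weights
#'
#' @param W A [coupling_weights()] list.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_weights <- function(W, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(W$w_LRE, file.path(dir, "w_LRE.tsv"))
  write_matrix_tsv(W$w_FFI, file.path(dir, "w_FFI.tsv"))
  write_matrix_tsv(matrix(W$J, ncol = 1), file.path(dir, "J.tsv"))
  invisible(dir)
}

#' @rdname write_weights
#' @param dir Directory written by [write_weights()].
#' @return `read_weights`: a [coupling_weights()] list.
#' @export
read_weights <- function(dir) {
  w_lre <- read_matrix_tsv(file.path(dir, "w_LRE.tsv"))
  coupling_weights(nrow(w_lre), w_lre,
                   read_matrix_tsv(file.path(dir, "w_FFI.tsv")),
                   as.vector(read_matrix_tsv(file.path(dir, "J.tsv"))))
}
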