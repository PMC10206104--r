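# Shared fixtures: everything is generated in code at test time.

two_node <- function() two_node_connectome()

# a small connected connectome used across tests
tiny_connectome <- function(n = 6, seed = 3, density = 0.5) {
  synth_connectome(n, density = density, seed = seed)
}

# independent reference for the transfer function, written against expm1
# (accurate arbitrarily close to the removable singularity)
ref_transfer <- function(I, a, b, d) {
  x <- a * I - b
  ifelse(x == 0, 1 / d, x / (-expm1(-d * x)))
}

# brute-force double-loop Pearson correlation
ref_cor_matrix <- function(m) {
  n <- nrow(m)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) out[i, j] <- stats::cor(m[i, ], m[j, ])
  }
  out
}

# short simulation defaults used in fast tests (ms)
MIN <- 60 * 1000
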