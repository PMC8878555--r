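# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Exhaustive three-point neighbour scan (no plateau handling; use on signals
# without ties).
extrema_oracle <- function(x) {
  n <- length(x)
  mx <- mn <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) mx <- c(mx, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) mn <- c(mn, i)
  }
  list(maxima = mx, minima = mn)
}

# O(n^2) direct template-count oracle for sample entropy: templates start at
# i = 1..n-m (so every one has an m+1 extension), pairs i < j, Chebyshev
# distance, inclusive tolerance.
sampen_counts_oracle <- function(x, m, tol) {
  n <- length(x)
  ntpl <- n - m
  A <- 0; B <- 0
  for (i in 1:(ntpl - 1)) {
    for (j in (i + 1):ntpl) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= tol) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

# AUC as the normalized Mann-Whitney pairwise concordance (ties count 1/2).
auc_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

# Small in-memory dataset of short records for fast pipeline tests.
make_mini_records <- function(n_term, n_preterm, seed = 7, duration = 480) {
  pt <- generator_params("term", duration = duration)
  pp <- generator_params("preterm", duration = duration)
  ds <- generate_dataset(n_term = n_term, n_preterm = n_preterm,
                         params_term = pt, params_preterm = pp, seed = seed)
  ds$records
}

# A feature matrix that is trivially separable, for classifier plumbing
# tests that should not depend on the generator.
make_toy_matrix <- function(n_term = 40, n_preterm = 12, seed = 3, gap = 6) {
  set.seed(seed)
  n <- n_term + n_preterm
  lab <- c(rep("term", n_term), rep("preterm", n_preterm))
  X <- matrix(rnorm(n * 6), n, 6)
  X[lab == "preterm", ] <- X[lab == "preterm", ] + gap # two clusters
  fm <- data.frame(record_id = sprintf("r%02d", 1:n), channel = "CH1",
                   label = lab, X, n_windows_averaged = 24L,
                   check.names = FALSE)
  names(fm)[4:9] <- c("RMS_IMF1", "RMS_IMF2", "SampEn_IMF1", "SampEn_IMF2",
                      "MTKE_IMF1", "MTKE_IMF2")
  attr(fm, "normalized") <- FALSE
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
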