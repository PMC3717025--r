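# Shared fixtures, built in code.

default_table <- default_parameter_table()

# A table where every input is degenerate at its point estimate; sampling from
# it must give identical draws every iteration.
all_fixed_table <- local({
  specs <- lapply(default_table, function(s)
    parameter_spec(s$name, "deterministic value", "fixed",
                   point = if (s$family == "dirichlet") s$point / sum(s$point)
                           else unname(s$point)))
  names(specs) <- names(default_table)
  structure(specs, class = "parameter_table", param_source = "hyperparams")
})

# One cached moderate PSA reused by several invariant tests.
small_psa <- run_psa(default_table, n = 400, seed = 2024)

# Brute-force EVPI by explicit loops, kept deliberately naive and separate
# from both enumerate-based implementations in the package.
brute_evpi <- function(nb) {
  best_mean <- -Inf
  for (j in seq_len(ncol(nb))) {
    m <- 0
    for (i in seq_len(nrow(nb))) m <- m + nb[i, j]
    best_mean <- max(best_mean, m / nrow(nb))
  }
  mean_best <- 0
  for (i in seq_len(nrow(nb))) {
    row_best <- -Inf
    for (j in seq_len(ncol(nb))) row_best <- max(row_best, nb[i, j])
    mean_best <- mean_best + row_best
  }
  mean_best / nrow(nb) - best_mean
}
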