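# Quadrature-derived profile for the running Beta(1.33, 1.75) example;
# seed-free, so usable as a deterministic oracle input across test files.
beta_example_spec <- function(n_sim = 1e5, seed = 11) {
  pop_spec(beta_risk(1.33, 1.75), n_sim = n_sim, seed = seed)
}

beta_profile_quad <- function(threshold) {
  true_performance(beta_example_spec(), threshold, method = "quadrature")
}

# random valid integer confusion matrices with all cells positive
random_matrices <- function(n, seed = 401) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cells <- as.numeric(sample(1:200, 4, replace = TRUE))
    confusion_matrix(cells[1], cells[2], cells[3], cells[4])
  })
}
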