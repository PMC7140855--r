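# small in-code fixtures shared across test files

make_expr <- function(m, ranked = FALSE) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  df <- tibble::tibble(gene = rownames(m), tibble::as_tibble(as.data.frame(m)))
  as_expression(df, ranked = ranked)
}

# a small noiseless cohort used by several end-to-end tests
noiseless_cohort <- function(seed = 4) {
  simulate_cohort(sim_config(
    n_genes = 200, n_cell_lines = 24, n_patients = 16, n_drugs = 10,
    n_clusters = 4, noise_sd = 0, label_noise = 0, missing_rate = 0,
    seed = seed
  ))
}

# pocket-sized cohort for the grid-search brute-force comparisons
tiny_cohort <- function(seed = 11) {
  simulate_cohort(sim_config(
    n_genes = 120, n_cell_lines = 15, n_patients = 12, n_drugs = 6,
    n_clusters = 3, n_kb_drugs = 3, noise_sd = 0.6, label_noise = 0.1,
    missing_rate = 0.05, seed = seed
  ))
}
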