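# Small fixtures shared across test files. Everything is built in code.

write_tsv_text <- function(text, file = tempfile(fileext = ".tsv")) {
  writeLines(text, file)
  file
}

# tiny three-ingredient compendium with hand-traceable herb composition
tiny_compendium <- function() {
  ings <- ingredient_set(
    c("i1", "i2", "i3"),
    herbs = list(c("RP", "CT"), "CL", c("CT", "OF")),
    ob = c(40, 50, 35), dl = c(0.3, 0.2, 0.25), source = "tcmsp")
  validated <- data.frame(
    ingredient = c("i1", "i1", "i2"),
    gene = c("AKT1", "TNF", "AKT1"),
    evidence = "validated", similarity = NA_real_,
    prediction_score = NA_real_, stringsAsFactors = FALSE)
  predicted <- data.frame(
    ingredient = c("i1", "i3", "i3"),
    gene = c("AKT1", "IL6", "TNF"),
    evidence = "predicted", similarity = c(1.5, 1.2, 1.3),
    prediction_score = c(0.5, 0.9, 0.1), stringsAsFactors = FALSE)
  build_compendium(validated, predicted, ings)
}

# deterministic two-group matrix with two planted genes and flat genes
tiny_expression <- function(n_per_group = 4) {
  genes <- c("UP1", "DOWN1", "FLAT1", "FLAT2")
  case <- cbind(c(10, 6, 5, 7), c(10.1, 6.2, 5.1, 7.1),
                c(9.9, 5.9, 4.9, 6.9), c(10.2, 6.1, 5.2, 7.0))
  ctrl <- cbind(c(8, 8, 5.1, 7.1), c(8.1, 8.1, 5.0, 7.0),
                c(7.9, 7.9, 5.05, 6.95), c(8.0, 8.2, 5.15, 7.05))
  values <- cbind(case[, seq_len(n_per_group)], ctrl[, seq_len(n_per_group)])
  rownames(values) <- genes
  colnames(values) <- c(paste0("case", seq_len(n_per_group)),
                        paste0("ctrl", seq_len(n_per_group)))
  expression_matrix(values, rep(c("case", "control"), each = n_per_group))
}

# small parameter set so whole-pipeline tests run in well under a second
small_params <- function(...) {
  synth_params(n_tcmsp = 60, n_hit = 10, n_universe = 200, n_core = 20,
               fanout_mean = 8, fanout_validated = 6,
               n_curated = 15, n_curated_core = 8,
               n_genes_expr = 300, n_up = 8, n_down = 8,
               deg_core_up = 3, deg_core_down = 3,
               n_proteins = 60, ppi_noise_edges = 80,
               n_kegg_terms = 6, n_mf_terms = 4,
               kegg_term_size = 12, planted_kegg_core = 9,
               mf_term_size = 8, planted_mf_core = 5, ...)
}

# brute-force hypergeometric upper tail by enumerating all size-n draws
enum_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # first K elements are "in the term"
  mean(hits >= k)
}
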