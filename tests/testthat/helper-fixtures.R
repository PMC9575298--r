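# Small programmatic fixtures shared across the test files.

toy_counts <- function(n = 3L, p = 2L, seed = 42L,
                        modality = "taxon") {
  set.seed(seed)
  m <- matrix(rpois(n * p, 20), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("F%02d", seq_len(p))))
  abundance_table(m + 0, modality = modality, unit = "count")
}

toy_metadata <- function(n = 6L, seed = 7L) {
  set.seed(seed)
  sample_metadata(data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    age = 30 + seq_len(n),
    sex = rep_len(c(0, 1), n),
    diagnosis = rep_len(c("CD", "UC"), n),
    crp = round(runif(n, 1, 40), 1),
    fcal = round(runif(n, 50, 600)),
    steroid = rep_len(c(0, 0, 1), n),
    mesalamine = rep_len(c(1, 0), n),
    immunosuppressant = rep_len(c(0, 1, 0), n),
    contraceptive = rep_len(c(0, 0, 0, 1), n),
    antidepressant = rep_len(c(1, 0, 0), n),
    ppi = rep_len(c(0, 1), n),
    hads_d = rep_len(c(3, 8, 12, 5), n),
    weimus = rep_len(c(20, 35, 41, 15, 28), n),
    stringsAsFactors = FALSE))
}

# random edge list over a tripartite node set, for motif enumeration tests
random_tripartite_edges <- function(n_t, n_m, n_pp = 2L, p_edge = 0.3,
                                    seed = 1L) {
  set.seed(seed)
  nodes <- data.frame(
    id = c(sprintf("t%02d", seq_len(n_t)), sprintf("m%02d", seq_len(n_m)),
           sprintf("pp%d", seq_len(n_pp))),
    modality = c(rep("T", n_t), rep("M", n_m), rep("PP", n_pp)),
    stringsAsFactors = FALSE)
  pairs <- t(combn(nrow(nodes), 2L))
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(node_a = nodes$id[pairs[, 1L]],
             node_b = nodes$id[pairs[, 2L]],
             modality_a = nodes$modality[pairs[, 1L]],
             modality_b = nodes$modality[pairs[, 2L]],
             n_obs = 57L,
             log10_bf = round(runif(nrow(pairs), -0.5, 1.5), 3),
             rho = round(runif(nrow(pairs), -0.6, 0.6), 3),
             stringsAsFactors = FALSE)
}
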