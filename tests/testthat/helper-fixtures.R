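# Small fixture builders shared across tests. Everything is generated in
# code; no data files.

# registry with arbitrary per-dataset classes/weights/hits
toy_registry <- function(classes, weights, hits, n_genes,
                         tf_groups = NULL) {
  k <- length(classes)
  if (is.null(tf_groups))
    tf_groups <- ifelse(classes == "chipseq", "ebox", "none")
  clock_registry(data.frame(
    dataset_id = sprintf("d%02d", seq_len(k)),
    source_label = sprintf("toy dataset %d", seq_len(k)),
    data_class = classes,
    weight = weights,
    tf_group = tf_groups,
    expected_hits = hits,
    stringsAsFactors = FALSE
  ), n_genes = n_genes)
}

# hit matrix from a list of per-gene dataset-id vectors
make_hits <- function(registry, gene_hits) {
  ids <- registry$records$dataset_id
  m <- matrix(0L, length(gene_hits), length(ids),
              dimnames = list(names(gene_hits), ids))
  for (g in seq_along(gene_hits)) m[g, gene_hits[[g]]] <- 1L
  m
}

# random hit matrix over a registry (independent of simulate_hit_matrix,
# used for round-trip and invariance checks)
random_hits <- function(registry, n_genes_obs = 20, p = 0.3) {
  ids <- registry$records$dataset_id
  m <- matrix(rbinom(n_genes_obs * length(ids), 1L, p),
              n_genes_obs, length(ids),
              dimnames = list(sprintf("gene%03d", seq_len(n_genes_obs)), ids))
  storage.mode(m) <- "integer"
  m
}
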