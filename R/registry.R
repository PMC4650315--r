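#' Evidence dataset registry
#'
#' A registry describes the evidence datasets entering the meta-analysis: for
#' each dataset its class (ChIP-seq, proteomics or protein-protein
#' interaction), its weight in the total score, the transcription-factor group
#' its ChIP-seq targets belong to (E-box, D-box, RRE, or none), and the number
#' of master-list genes it contains ("expected hits", used by the permutation
#' null). The registry also fixes the master-list size `n_genes`.
#'
#' @param records data.frame with columns `dataset_id`, `source_label`,
#'   `data_class` (one of `"chipseq"`, `"proteomics"`, `"ppi"`), `weight`
#'   (positive integer), `tf_group` (one of `"ebox"`, `"dbox"`, `"rre"`,
#'   `"none"`) and `expected_hits` (non-negative integer, at most `n_genes`).
#' @param n_genes master-list size (positive integer).
#'
#' @return An object of class `clock_registry`: a list with elements
#'   `records` and `n_genes`.
#' @seealso [default_registry()], [read_registry()], [total_scores()]
#' @export
clock_registry <- function(records, n_genes) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("dataset_id", "source_label", "data_class", "weight",
                "tf_group", "expected_hits")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L)
    stop("registry records lack field(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$dataset_id))
    stop("duplicate dataset_id: ",
         paste(unique(records$dataset_id[duplicated(records$dataset_id)]),
               collapse = ", "))
  bad_class <- !records$data_class %in% c("chipseq", "proteomics", "ppi")
  if (any(bad_class))
    stop("invalid data_class for dataset ",
         paste(records$dataset_id[bad_class], collapse = ", "))
  bad_group <- !records$tf_group %in% c("ebox", "dbox", "rre", "none")
  if (any(bad_group))
    stop("invalid tf_group for dataset ",
         paste(records$dataset_id[bad_group], collapse = ", "))
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1 ||
      n_genes != round(n_genes))
    stop("n_genes must be a positive integer")
  records$weight <- as.numeric(records$weight)
  if (any(records$weight <= 0) || any(records$weight != round(records$weight)))
    stop("weights must be positive integers (dataset ",
         paste(records$dataset_id[records$weight <= 0 |
                                  records$weight != round(records$weight)],
               collapse = ", "), ")")
  records$expected_hits <- as.numeric(records$expected_hits)
  bad_hits <- records$expected_hits < 0 |
    records$expected_hits != round(records$expected_hits) |
    records$expected_hits > n_genes
  if (any(bad_hits))
    stop("expected_hits must be integers in [0, n_genes] (dataset ",
         paste(records$dataset_id[bad_hits], collapse = ", "), ")")
  rownames(records) <- NULL
  structure(list(records = records, n_genes = as.integer(n_genes)),
            class = "clock_registry")
}

#' @export
print.clock_registry <- function(x, ...) {
  cat("Evidence dataset registry:", nrow(x$records), "datasets,",
      x$n_genes, "master-list genes\n")
  tab <- table(x$records$data_class)
  cat("  classes:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  cat("  total attainable score:", sum(x$records$weight), "\n")
  invisible(x)
}

#' The mouse circadian evidence registry
#'
#' The 19-dataset registry used for candidate clock gene screening in mouse:
#' 14 ChIP-seq datasets (circadian binding of BMAL1, PER1/2, CRY1/2, CLOCK and
#' NPAS2 from Koike et al.; BMAL1 from Rey et al.; REV-ERB alpha/beta from Cho,
#' Bugge and Feng et al.; ROR alpha and E4BP4 from Fang et al.), 3 circadian
#' proteomics datasets (Robles, Mauvoisin, Chiang et al.) and 2
#' protein-protein-interaction datasets (Wallach et al. core-clock
#' interactions, PINA mouse database). All datasets carry weight 1 except the
#' Rey et al. BMAL1 set, which carries weight 3, so a gene present in every
#' dataset scores 21. `expected_hits` are the published per-dataset counts of
#' master-list genes.
#'
#' @param n_genes master-list size; default 1000.
#' @return A [clock_registry()] object with 19 records.
#' @export
default_registry <- function(n_genes = 1000) {
  records <- data.frame(
    dataset_id = c("koike_bmal1", "koike_per1", "koike_per2", "koike_cry1",
                   "koike_cry2", "koike_clock", "koike_npas2", "rey_bmal1",
                   "cho_reverba", "cho_reverbb", "bugge_reverba",
                   "feng_reverbb", "fang_rora", "fang_e4bp4",
                   "robles", "mauvoisin", "chiang", "wallach", "pina"),
    source_label = c("Koike et al. BMAL1", "Koike et al. PER1",
                     "Koike et al. PER2", "Koike et al. CRY1",
                     "Koike et al. CRY2", "Koike et al. CLOCK",
                     "Koike et al. NPAS2", "Rey et al. BMAL1",
                     "Cho et al. REV-ERBa", "Cho et al. REV-ERBb",
                     "Bugge et al. REV-ERBa", "Feng et al. REV-ERBb",
                     "Fang et al. RORa", "Fang et al. E4BP4",
                     "Robles et al. liver proteome",
                     "Mauvoisin et al. liver proteome",
                     "Chiang et al. SCN proteome",
                     "Wallach et al. core-clock PPI", "PINA mouse PPI"),
    data_class = c(rep("chipseq", 14), rep("proteomics", 3), rep("ppi", 2)),
    weight = c(1, 1, 1, 1, 1, 1, 1, 3, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    tf_group = c("ebox", "none", "none", "none", "none", "ebox", "ebox",
                 "ebox", "rre", "rre", "rre", "rre", "rre", "dbox",
                 rep("none", 5)),
    expected_hits = c(359, 15, 384, 356, 318, 170, 121, 228, 412, 412,
                      636, 635, 529, 437, 34, 35, 6, 25, 33),
    stringsAsFactors = FALSE
  )
  clock_registry(records, n_genes = n_genes)
}

#' Read or write a registry config file
#'
#' Registries are exchanged as YAML: a top-level `schema_version`, `n_genes`
#' and a `datasets` list, each entry carrying `dataset_id`, `source_label`,
#' `data_class`, `weight`, `tf_group` and `expected_hits`.
#'
#' @param path file path.
#' @return `read_registry()` returns a [clock_registry()];
#'   `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0L)
    stop("registry file has no datasets: ", path)
  if (is.null(cfg$n_genes)) stop("registry file lacks n_genes: ", path)
  required <- c("dataset_id", "source_label", "data_class", "weight",
                "tf_group", "expected_hits")
  recs <- lapply(seq_along(cfg$datasets), function(i) {
    rec <- cfg$datasets[[i]]
    miss <- setdiff(required, names(rec))
    if (length(miss) > 0L)
      stop("dataset entry ", i,
           if (!is.null(rec$dataset_id)) paste0(" ('", rec$dataset_id, "')"),
           " lacks field(s): ", paste(miss, collapse = ", "))
    as.data.frame(rec[required], stringsAsFactors = FALSE)
  })
  clock_registry(do.call(rbind, recs), n_genes = cfg$n_genes)
}

#' @rdname read_registry
#' @param registry a [clock_registry()].
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "clock_registry"))
  datasets <- lapply(seq_len(nrow(registry$records)), function(i)
    as.list(registry$records[i, , drop = FALSE]))
  datasets <- lapply(datasets, lapply, function(v)
    if (is.numeric(v) && v == round(v)) as.integer(v) else v)
  yaml::write_yaml(list(schema_version = 1L,
                        n_genes = registry$n_genes,
                        datasets = datasets), path)
  invisible(path)
}

#' Read or write a binary hit matrix
#'
#' The hit table is a TSV with a header row, first column `gene_id`, and one
#' 0/1 column per registered dataset recording whether the gene is present in
#' that dataset. Columns may appear in any order in the file; they are
#' returned in registry order.
#'
#' @param path TSV file path.
#' @param registry a [clock_registry()]; the file's dataset columns must
#'   match its `dataset_id`s exactly.
#' @return `read_hit_matrix()` returns an integer matrix (genes x datasets)
#'   with gene IDs as rownames and dataset IDs as colnames.
#' @export
read_hit_matrix <- function(path, registry) {
  stopifnot(inherits(registry, "clock_registry"))
  if (!file.exists(path)) stop("hit table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("hit table must have 'gene_id' as its first column: ", path)
  ids <- registry$records$dataset_id
  missing_d <- setdiff(ids, names(tab))
  if (length(missing_d) > 0L)
    stop("hit table lacks dataset column(s): ",
         paste(missing_d, collapse = ", "))
  extra <- setdiff(names(tab)[-1], ids)
  if (length(extra) > 0L)
    stop("hit table has unknown dataset column(s): ",
         paste(extra, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("duplicated gene_id in hit table: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  m <- as.matrix(tab[, ids, drop = FALSE])
  bad <- which(!(m %in% c(0, 1)))
  if (length(bad) > 0L) {
    row <- (bad[1] - 1L) %% nrow(m) + 1L
    col <- (bad[1] - 1L) %/% nrow(m) + 1L
    stop("non-binary cell in hit table at gene '", tab$gene_id[row],
         "', dataset '", ids[col], "': ", m[bad[1]])
  }
  storage.mode(m) <- "integer"
  rownames(m) <- tab$gene_id
  m
}

#' @rdname read_hit_matrix
#' @param hits integer 0/1 matrix with gene rownames and dataset colnames.
#' @export
write_hit_matrix <- function(hits, path) {
  df <- data.frame(gene_id = rownames(hits), hits, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a score table
#'
#' The score table is a TSV with columns `gene_id`, one 0/1 hit column per
#' dataset, `total_score`, `p_value`, `significant` and `robust`. Numeric
#' columns are written with full precision so that a write/read round trip is
#' lossless.
#'
#' @param scores a `score_table` (see [total_scores()]).
#' @param path TSV file path.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(inherits(scores, "score_table"))
  df <- as.data.frame(scores)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.17g", v)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  fixed <- c("gene_id", "total_score", "p_value", "significant", "robust")
  miss <- setdiff(fixed, names(df))
  if (length(miss) > 0L)
    stop("score table lacks column(s): ", paste(miss, collapse = ", "))
  df$significant <- as.logical(df$significant)
  df$robust <- as.logical(df$robust)
  hit_cols <- setdiff(names(df), fixed)
  structure(df, hit_columns = hit_cols,
            class = c("score_table", "data.frame"))
}
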