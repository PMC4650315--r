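#' Per-gene total evidence scores
#'
#' Each gene's total score is the weighted sum of its dataset hits,
#' `sum_d weight_d * I_d(g)`: one point per evidence dataset containing the
#' gene, except for datasets carrying a larger registry weight (in the default
#' registry only the Rey et al. BMAL1 ChIP-seq set, at weight 3). With the
#' 19-dataset default registry the maximum attainable score is 21.
#'
#' @param hits 0/1 matrix, genes x datasets, columns matching the registry
#'   (as from [read_hit_matrix()] or [simulate_hit_matrix()]).
#' @param registry a [clock_registry()].
#' @return A `score_table`: a data.frame with `gene_id`, the per-dataset hit
#'   columns, `total_score`, and `p_value`/`significant`/`robust` columns
#'   initialised to `NA` (filled by [attach_pvalues()] and
#'   [robust_candidates()]).
#' @examples
#' reg <- default_registry(n_genes = 10)
#' hits <- matrix(0L, 10, 19, dimnames = list(sprintf("g%02d", 1:10),
#'                                            reg$records$dataset_id))
#' hits["g01", ] <- 1L          # present in every dataset
#' hits["g02", "rey_bmal1"] <- 1L
#' st <- total_scores(hits, reg)
#' st$total_score[1:2]          # 21 and 3
#' @export
total_scores <- function(hits, registry) {
  hits <- check_hits(hits, registry)
  s <- as.numeric(hits %*% registry$records$weight)
  structure(
    data.frame(gene_id = rownames(hits), hits,
               total_score = s, p_value = rep(NA_real_, nrow(hits)),
               significant = rep(NA, nrow(hits)),
               robust = rep(NA, nrow(hits)),
               check.names = FALSE, stringsAsFactors = FALSE,
               row.names = NULL),
    hit_columns = registry$records$dataset_id,
    class = c("score_table", "data.frame")
  )
}

#' Class-weighted evidence scores
#'
#' The class-weighted score of gene g under pre-factors (alpha, beta, gamma)
#' on the simplex is
#' `S(g) = alpha * [ChIP-seq score] + beta * [proteomics score] +
#' gamma * [PPI score]`, where each class score is the weighted hit sum over
#' that class's datasets (the Rey weight-3 set stays inside the ChIP-seq
#' class sum). Equal pre-factors (1/3, 1/3, 1/3) reproduce
#' `total_scores()/3` exactly.
#'
#' @inheritParams total_scores
#' @param w a [prefactors()] triple (alpha, beta, gamma).
#' @return Named numeric vector of S(g), one entry per gene.
#' @export
weighted_scores <- function(hits, registry, w) {
  hits <- check_hits(hits, registry)
  w <- prefactors(w[1], w[2], w[3])
  cls <- class_sums(hits, registry)
  s <- w[1] * cls[, "chipseq"] + w[2] * cls[, "proteomics"] + w[3] * cls[, "ppi"]
  names(s) <- rownames(hits)
  s
}

#' Pre-factor triple on the simplex
#'
#' Class-level weights for the ChIP-seq, proteomics and PPI evidence classes,
#' constrained to sum to one.
#'
#' @param alpha,beta,gamma class pre-factors; must sum to 1 within 1e-9.
#' @return Numeric vector `c(alpha, beta, gamma)` of class `prefactors`.
#' @export
prefactors <- function(alpha, beta, gamma) {
  w <- c(alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma))
  if (anyNA(w) || any(w < 0))
    stop("pre-factors must be non-negative numbers")
  if (abs(sum(w) - 1) > 1e-9)
    stop("pre-factors must sum to 1 (got ", format(sum(w)), ")")
  structure(w, class = "prefactors")
}

#' @export
print.score_table <- function(x, ...) {
  cat("Score table:", nrow(x), "genes\n")
  cat("  total score range:", min(x$total_score), "-", max(x$total_score), "\n")
  if (!all(is.na(x$p_value)))
    cat("  significant:", sum(x$significant, na.rm = TRUE), "genes\n")
  if (!all(is.na(x$robust)))
    cat("  robust:", sum(x$robust, na.rm = TRUE), "genes\n")
  invisible(x)
}

# validate a hit matrix against a registry; returns matrix in registry order
check_hits <- function(hits, registry) {
  stopifnot(inherits(registry, "clock_registry"))
  if (!is.matrix(hits)) hits <- as.matrix(hits)
  ids <- registry$records$dataset_id
  if (is.null(colnames(hits))) {
    if (ncol(hits) != length(ids))
      stop("hit matrix has ", ncol(hits), " columns; registry has ",
           length(ids), " datasets")
    colnames(hits) <- ids
  }
  miss <- setdiff(ids, colnames(hits))
  if (length(miss) > 0L)
    stop("hit matrix lacks dataset column(s): ", paste(miss, collapse = ", "))
  hits <- hits[, ids, drop = FALSE]
  if (!all(hits %in% c(0, 1))) stop("hit matrix entries must be 0 or 1")
  if (is.null(rownames(hits)))
    rownames(hits) <- sprintf("g%0*d", nchar(nrow(hits)), seq_len(nrow(hits)))
  hits
}

# weighted within-class hit sums: genes x {chipseq, proteomics, ppi}
class_sums <- function(hits, registry) {
  out <- matrix(0, nrow(hits), 3L,
                dimnames = list(rownames(hits),
                                c("chipseq", "proteomics", "ppi")))
  for (cl in colnames(out)) {
    idx <- registry$records$data_class == cl
    if (any(idx))
      out[, cl] <- as.numeric(hits[, idx, drop = FALSE] %*%
                                registry$records$weight[idx])
  }
  out
}
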