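#' Empirical permutation null for evidence scores
#'
#' Builds the null distribution of per-gene scores under random reassignment
#' of evidence: in each iteration every dataset's published hit count is
#' assigned uniformly at random without replacement to the master-list genes,
#' independently across datasets, and all per-gene scores from all iterations
#' are pooled. Because the three class sums (ChIP-seq, proteomics, PPI) are
#' integer-valued, the null is accumulated on their joint integer lattice and
#' collapsed exactly for whatever weighting is requested: unit dataset weights
#' (the total score) when `w` is `NULL`, or class pre-factors otherwise.
#'
#' @param registry a [clock_registry()] supplying `expected_hits` per dataset
#'   and the master-list size.
#' @param w optional [prefactors()] triple; `NULL` (default) gives the
#'   unit-weight total-score null.
#' @param n_iterations number of shuffle iterations (>= 1); each pools
#'   `n_genes` scores, so the smallest attainable tail probability is
#'   `1 / (n_iterations * n_genes)`.
#' @param seed integer seed for reproducibility (optional).
#' @return An object of class `clock_null` with elements `support` (ascending
#'   distinct score values), `pmf`, `tail_prob` (`P(score >= s)`),
#'   `n_iterations`, `n_pooled` and `method`.
#' @seealso [exact_null()] for the analytic oracle, [attach_pvalues()],
#'   [significance_threshold()].
#' @export
shuffle_null <- function(registry, w = NULL, n_iterations = 1000,
                         seed = NULL) {
  stopifnot(inherits(registry, "clock_registry"))
  if (!is.numeric(n_iterations) || n_iterations < 1)
    stop("n_iterations must be >= 1")
  n_iterations <- as.integer(n_iterations)
  if (!is.null(seed)) set.seed(seed)
  n <- registry$n_genes
  rec <- registry$records
  cls <- c("chipseq", "proteomics", "ppi")
  cmax <- vapply(cls, function(k) sum(rec$weight[rec$data_class == k]),
                 numeric(1))
  dims <- cmax + 1
  nbins <- prod(dims)
  counts <- numeric(nbins)
  d_class <- match(rec$data_class, cls)
  h <- rec$expected_hits
  wt <- rec$weight
  for (it in seq_len(n_iterations)) {
    s <- matrix(0, nrow = n, ncol = 3L)
    for (d in seq_len(nrow(rec))) {
      if (h[d] == 0) next
      idx <- sample.int(n, h[d])
      s[idx, d_class[d]] <- s[idx, d_class[d]] + wt[d]
    }
    code <- s[, 1L] + dims[1L] * (s[, 2L] + dims[2L] * s[, 3L])
    counts <- counts + tabulate(code + 1L, nbins = nbins)
  }
  lat <- collapse_lattice(counts, dims, w)
  new_clock_null(lat$support, lat$mass / sum(lat$mass),
                 n_iterations = n_iterations,
                 n_pooled = n_iterations * n, method = "shuffle")
}

#' Exact convolution null for evidence scores
#'
#' Analytic counterpart of [shuffle_null()]: under the shuffle, a single
#' gene's null score is `sum_d weight_d * Bernoulli(h_d / n_genes)` with
#' independent terms, so the exact null follows by convolving the weighted
#' Bernoulli variables within each evidence class (integer support) and
#' combining the three independent class sums under the requested weighting.
#'
#' @inheritParams shuffle_null
#' @return A `clock_null` with `method = "exact"` and `n_iterations = 0`.
#' @examples
#' nul <- exact_null(default_registry())
#' significance_threshold(nul, 0.001)  # 13
#' @export
exact_null <- function(registry, w = NULL) {
  stopifnot(inherits(registry, "clock_registry"))
  n <- registry$n_genes
  rec <- registry$records
  cls <- c("chipseq", "proteomics", "ppi")
  cmax <- vapply(cls, function(k) sum(rec$weight[rec$data_class == k]),
                 numeric(1))
  dims <- cmax + 1
  class_pmf <- lapply(seq_along(cls), function(k) {
    pmf <- 1
    for (d in which(rec$data_class == cls[k])) {
      p <- rec$expected_hits[d] / n
      wd <- rec$weight[d]
      new <- numeric(length(pmf) + wd)
      new[seq_along(pmf)] <- pmf * (1 - p)
      new[seq_along(pmf) + wd] <- new[seq_along(pmf) + wd] + pmf * p
      pmf <- new
    }
    c(pmf, rep(0, dims[k] - length(pmf)))
  })
  joint <- outer(outer(class_pmf[[1]], class_pmf[[2]]), class_pmf[[3]])
  lat <- collapse_lattice(as.numeric(joint), dims, w)
  new_clock_null(lat$support, lat$mass, n_iterations = 0L,
                 n_pooled = Inf, method = "exact")
}

#' Attach permutation p-values to a score table
#'
#' Sets each gene's p-value to the null right-tail probability at its score,
#' `P(null score >= observed)`, and flags genes significant at `level`
#' (strict `p < level`). For a shuffle null a score beyond the pooled support
#' receives the smallest attainable tail value
#' `1 / (n_iterations * n_genes)`; a shuffle null never returns 0.
#'
#' @param scores a `score_table` from [total_scores()].
#' @param null a `clock_null` built under the same registry and weighting.
#' @param level significance level for the `significant` flag
#'   (default 0.001).
#' @return The `score_table` with `p_value` and `significant` filled in.
#' @export
attach_pvalues <- function(scores, null, level = 0.001) {
  stopifnot(inherits(scores, "score_table"), inherits(null, "clock_null"))
  p <- null_pvalues(scores$total_score, null)
  scores$p_value <- p
  scores$significant <- p < level
  scores
}

#' Score significance threshold
#'
#' The smallest score whose null right-tail probability is strictly below
#' `level`. If no pooled support value qualifies, the next integer above the
#' support is returned for an exact null; for a shuffle null whose resolution
#' (`1 / n_pooled`) cannot resolve `level`, an error advises more iterations
#' or [exact_null()].
#'
#' @param null a `clock_null`.
#' @param level significance level in (0, 1).
#' @return A single score value.
#' @export
significance_threshold <- function(null, level) {
  stopifnot(inherits(null, "clock_null"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  idx <- which(null$tail_prob < level)
  if (length(idx) > 0L) return(null$support[min(idx)])
  if (null$method == "shuffle" && 1 / null$n_pooled >= level)
    stop("level ", level, " is below the resolution of this shuffle null (",
         format(1 / null$n_pooled), "); increase n_iterations or use ",
         "exact_null()")
  floor(max(null$support)) + 1
}

#' @export
print.clock_null <- function(x, ...) {
  cat("Null score distribution (", x$method, "), ",
      length(x$support), " support points",
      if (x$method == "shuffle")
        paste0(", ", x$n_iterations, " iterations (",
               format(x$n_pooled, big.mark = ","), " pooled scores)"),
      "\n", sep = "")
  cat("  support: ", format(min(x$support)), " - ", format(max(x$support)),
      "\n", sep = "")
  invisible(x)
}

# p-values for a numeric score vector against a clock_null
null_pvalues <- function(s, null) {
  sup <- null$support
  i <- findInterval(s - 1e-9, sup) + 1L   # first support value >= s (tol 1e-9)
  p <- numeric(length(s))
  inside <- i <= length(sup)
  p[inside] <- null$tail_prob[i[inside]]
  p[!inside] <- if (null$method == "shuffle") 1 / null$n_pooled else 0
  p
}

# collapse mass on the (chip, prot, ppi) integer lattice to score values
# under unit weights (w = NULL) or a pre-factor triple
collapse_lattice <- function(mass, dims, w) {
  keep <- which(mass > 0)
  idx <- keep - 1L
  i <- idx %% dims[1L]
  j <- (idx %/% dims[1L]) %% dims[2L]
  k <- idx %/% (dims[1L] * dims[2L])
  v <- if (is.null(w)) i + j + k else {
    w <- prefactors(w[1], w[2], w[3])
    w[1] * i + w[2] * j + w[3] * k
  }
  v <- round(v, 12)  # collapse floating-point ties on the lattice
  agg <- rowsum(mass[keep], group = v)
  support <- as.numeric(rownames(agg))
  ord <- order(support)
  list(support = support[ord], mass = as.numeric(agg)[ord])
}

new_clock_null <- function(support, pmf, n_iterations, n_pooled, method) {
  structure(list(support = support, pmf = pmf,
                 tail_prob = rev(cumsum(rev(pmf))),
                 n_iterations = n_iterations, n_pooled = n_pooled,
                 method = method),
            class = "clock_null")
}
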