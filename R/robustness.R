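#' Sample pre-factor triples uniformly on the constrained simplex
#'
#' Draws (alpha, beta, gamma) i.i.d. uniform on the region of the simplex
#' `{alpha + beta + gamma = 1}` with every component strictly between `lower`
#' and `upper` (defaults 0.165 and 0.5: at most 50 percent below or above the
#' equal pre-factors 1/3). Sampling is by rejection from the uniform
#' distribution on the full simplex (normalised unit-rate exponentials, i.e.
#' a flat Dirichlet), which is exactly uniform on the accepted region.
#'
#' @param n_draws number of triples to draw.
#' @param lower,upper open box bounds on every component; must satisfy
#'   `3 * lower < 1 < 3 * upper`.
#' @param seed integer seed (optional).
#' @return `n_draws` x 3 matrix with columns `alpha`, `beta`, `gamma`.
#' @export
sample_prefactors <- function(n_draws, lower = 0.165, upper = 0.5,
                              seed = NULL) {
  if (!is.numeric(n_draws) || n_draws < 1) stop("n_draws must be >= 1")
  if (lower >= upper || 3 * lower >= 1 || 3 * upper <= 1)
    stop("infeasible bounds: need lower < upper with 3*lower < 1 < 3*upper")
  if (!is.null(seed)) set.seed(seed)
  n_draws <- as.integer(n_draws)
  out <- matrix(NA_real_, 0L, 3L)
  while (nrow(out) < n_draws) {
    m <- max(2L * (n_draws - nrow(out)), 64L)
    e <- matrix(stats::rexp(3L * m), ncol = 3L)
    d <- e / rowSums(e)
    keep <- d[, 1L] > lower & d[, 1L] < upper &
            d[, 2L] > lower & d[, 2L] < upper &
            d[, 3L] > lower & d[, 3L] < upper
    out <- rbind(out, d[keep, , drop = FALSE])
  }
  out <- out[seq_len(n_draws), , drop = FALSE]
  colnames(out) <- c("alpha", "beta", "gamma")
  out
}

#' Weight-robust candidate genes
#'
#' Screens candidates for sensitivity to the relative weighting of the three
#' evidence classes: for each sampled pre-factor triple the class-weighted
#' scores S(g) are computed, a null distribution is rebuilt under the same
#' pre-factors, and genes with `p < level` are flagged; only genes significant
#' under every draw are retained.
#'
#' @inheritParams total_scores
#' @param n_draws number of pre-factor draws (default 100).
#' @param level per-draw significance level (default 0.001).
#' @param null_iterations shuffle iterations per draw (used when
#'   `null_method = "shuffle"`); each draw gets an independent seed derived
#'   from `seed`.
#' @param seed master seed for the draws and the per-draw nulls.
#' @param null_method `"shuffle"` (the randomisation procedure, default) or
#'   `"exact"` (the convolution oracle; deterministic and fast).
#' @param lower,upper bounds for [sample_prefactors()].
#' @param draws optional matrix of pre-factor triples to use instead of
#'   sampling (rows summing to 1); `n_draws` is then ignored.
#' @return An object of class `robustness_result`: list with `draws` (the
#'   pre-factor matrix), `per_draw_significant` (list of gene-ID vectors),
#'   `n_significant` (per-draw counts), `robust_genes` (the intersection)
#'   and `level`.
#' @export
robust_candidates <- function(hits, registry, n_draws = 100, level = 0.001,
                              null_iterations = 1000, seed = NULL,
                              null_method = c("shuffle", "exact"),
                              lower = 0.165, upper = 0.5, draws = NULL) {
  null_method <- match.arg(null_method)
  hits <- check_hits(hits, registry)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(draws)) {
    draws <- sample_prefactors(n_draws, lower = lower, upper = upper)
  } else {
    draws <- as.matrix(draws)
    stopifnot(ncol(draws) == 3L)
    colnames(draws) <- c("alpha", "beta", "gamma")
    n_draws <- nrow(draws)
  }
  draw_seeds <- sample.int(.Machine$integer.max, nrow(draws))
  sig <- vector("list", nrow(draws))
  for (k in seq_len(nrow(draws))) {
    w <- prefactors(draws[k, 1L], draws[k, 2L], draws[k, 3L])
    s <- weighted_scores(hits, registry, w)
    nul <- if (null_method == "shuffle")
      shuffle_null(registry, w = w, n_iterations = null_iterations,
                   seed = draw_seeds[k])
    else exact_null(registry, w = w)
    sig[[k]] <- rownames(hits)[null_pvalues(s, nul) < level]
  }
  robust <- Reduce(intersect, sig, accumulate = FALSE)
  structure(list(draws = draws, per_draw_significant = sig,
                 n_significant = lengths(sig),
                 robust_genes = robust, level = level,
                 null_method = null_method),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat("Weight-robustness screen:", nrow(x$draws), "pre-factor draws at level",
      x$level, "\n")
  cat("  significant per draw:", min(x$n_significant), "-",
      max(x$n_significant), "genes\n")
  cat("  robust (significant in every draw):", length(x$robust_genes),
      "genes\n")
  invisible(x)
}
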