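test_that("exact null matches closed-form Bernoulli tail probabilities", {
  # single dataset, weight 1, 300 hits of 1000: P(S >= 1) = 0.3
  reg1 <- toy_registry("chipseq", 1, 300, 1000)
  nul1 <- exact_null(reg1)
  expect_equal(nul1$support, c(0, 1))
  expect_equal(nul1$tail_prob, c(1, 0.3))
  # two unit datasets, 500 hits each: P(S >= 2) = 0.25
  reg2 <- toy_registry(c("chipseq", "proteomics"), c(1, 1), c(500, 500), 1000)
  nul2 <- exact_null(reg2)
  expect_equal(nul2$tail_prob[nul2$support == 2], 0.25)
  # tail_prob is non-increasing and starts at 1
  reg <- default_registry()
  nul <- exact_null(reg)
  expect_equal(nul$tail_prob[1], 1)
  expect_true(all(diff(nul$tail_prob) <= 0))
  expect_equal(sum(nul$pmf), 1, tolerance = 1e-12)
})

test_that("shuffle null agrees with the exact convolution oracle", {
  # toy case with an enumerable answer: 10 genes, two unit-weight datasets
  # with 5 hits each; a gene is hit in each with prob 1/2 independently,
  # so P(S >= 2) = 1/4
  toy <- toy_registry(c("chipseq", "ppi"), c(1, 1), c(5, 5), 10)
  sh <- shuffle_null(toy, n_iterations = 20000, seed = 101)
  expect_equal(sh$tail_prob[sh$support == 2], 0.25,
               tolerance = 3 * sqrt(0.25 * 0.75 / 20000) / 0.25)
  # richer registry (4 datasets, mixed weights, 20 genes): every support
  # point within 3 conservative Monte-Carlo standard errors of the oracle
  reg <- toy_registry(c("chipseq", "chipseq", "proteomics", "ppi"),
                      c(2, 1, 1, 1), c(6, 12, 3, 9), 20)
  n_iter <- 2e5
  sh <- shuffle_null(reg, n_iterations = n_iter, seed = 42)
  ex <- exact_null(reg)
  expect_equal(sh$support, ex$support)
  se <- sqrt(ex$tail_prob * (1 - ex$tail_prob) / n_iter)
  expect_true(all(abs(sh$tail_prob - ex$tail_prob) <= 3 * se + 1e-12))
  # identical seed, identical distribution
  sh2 <- shuffle_null(reg, n_iterations = 1000, seed = 7)
  sh3 <- shuffle_null(reg, n_iterations = 1000, seed = 7)
  expect_identical(sh2, sh3)
  expect_error(shuffle_null(reg, n_iterations = 0), "n_iterations")
})

test_that("pre-factor-weighted nulls collapse the class lattice correctly", {
  reg <- toy_registry(c("chipseq", "proteomics", "ppi"), c(1, 1, 1),
                      c(400, 300, 200), 1000)
  w <- prefactors(0.5, 0.3, 0.2)
  ex <- exact_null(reg, w = w)
  # enumerate the 8 hit patterns directly
  probs <- c(chip = 0.4, prot = 0.3, ppi = 0.2)
  vals <- c(chip = 0.5, prot = 0.3, ppi = 0.2)
  grid <- expand.grid(c(0, 1), c(0, 1), c(0, 1))
  s <- as.matrix(grid) %*% vals
  pr <- apply(grid, 1, function(b)
    prod(ifelse(b == 1, probs, 1 - probs)))
  brute <- sort(unique(round(s, 12)))
  brute_tail <- vapply(brute, function(v) sum(pr[round(s, 12) >= v]),
                       numeric(1))
  expect_equal(ex$support, brute)
  expect_equal(ex$tail_prob, brute_tail)
  # shuffle under the same pre-factors agrees
  sh <- shuffle_null(reg, w = w, n_iterations = 2000, seed = 5)
  expect_equal(sh$support, ex$support)
  expect_true(all(abs(sh$tail_prob - ex$tail_prob) <=
                  3 * sqrt(ex$tail_prob * (1 - ex$tail_prob) / 2000) + 1e-9))
})

test_that("p-values attach as right-tail probabilities", {
  reg <- default_registry()
  ex <- exact_null(reg)
  hits <- make_hits(reg, list(all = reg$records$dataset_id,
                              none = character(0)))
  st <- attach_pvalues(total_scores(hits, reg), ex)
  expect_equal(st$p_value[st$gene_id == "none"], 1)
  # maximal score: p equals the product of the 19 hit fractions
  expect_equal(st$p_value[st$gene_id == "all"],
               prod(reg$records$expected_hits / 1000))
  expect_true(st$significant[st$gene_id == "all"])
  expect_false(st$significant[st$gene_id == "none"])
  # toy two-dataset case: score 2 has p = 0.25
  toy <- toy_registry(c("chipseq", "ppi"), c(1, 1), c(5, 5), 10)
  th <- make_hits(toy, list(both = c("d01", "d02")))
  expect_equal(attach_pvalues(total_scores(th, toy),
                              exact_null(toy))$p_value, 0.25)
  # a score beyond a shuffle null's pooled support gets the resolution floor
  sh <- shuffle_null(toy_registry("chipseq", 1, 1, 10),
                     n_iterations = 50, seed = 1)
  big <- clockscreen:::null_pvalues(5, sh)
  expect_equal(big, 1 / (50 * 10))
})

test_that("significance thresholds behave across levels and methods", {
  reg <- default_registry()
  ex <- exact_null(reg)
  expect_equal(significance_threshold(ex, 0.001), 13)
  # single dataset with 1 hit of 1000: P(S >= 1) = 0.001 < 0.01
  reg1 <- toy_registry("chipseq", 1, 1, 1000)
  expect_equal(significance_threshold(exact_null(reg1), 0.01), 1)
  # null entirely at 0: first score above the support qualifies
  reg0 <- toy_registry("chipseq", 1, 0, 100)
  expect_equal(significance_threshold(exact_null(reg0), 0.5), 1)
  # monotone non-increasing in the level
  levels <- c(0.0001, 0.001, 0.01, 0.05, 0.2)
  thr <- vapply(levels, function(l) significance_threshold(ex, l), numeric(1))
  expect_true(all(diff(thr) <= 0))
  # shuffle resolution guard
  sh <- shuffle_null(reg0, n_iterations = 5, seed = 2)
  expect_error(significance_threshold(sh, 1e-6), "resolution")
  expect_error(significance_threshold(ex, 0), "level")
})
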