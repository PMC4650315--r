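test_that("TF-group scores normalise weighted group sums to [0, 1]", {
  reg <- default_registry()
  hits <- make_hits(reg, list(
    all_ebox = c("koike_bmal1", "koike_clock", "koike_npas2", "rey_bmal1"),
    rey_only = "rey_bmal1",
    percry   = c("koike_per1", "koike_per2", "koike_cry1"),
    one_rre  = "cho_reverba",
    dboxed   = "fang_e4bp4"))
  gs <- tf_group_scores(hits, reg)
  expect_equal(gs$s_e[gs$gene_id == "all_ebox"], 1)       # group maximum 6
  expect_equal(gs$s_e[gs$gene_id == "rey_only"], 0.5)     # weight 3 over 6
  expect_equal(unlist(gs[gs$gene_id == "percry", -1]),
               c(s_e = 0, s_d = 0, s_rre = 0))            # PER/CRY: no group
  expect_equal(gs$s_rre[gs$gene_id == "one_rre"], 0.2)    # 1 of group max 5
  expect_equal(gs$s_d[gs$gene_id == "dboxed"], 1)         # group maximum 1
  expect_true(all(as.matrix(gs[, -1]) >= 0 & as.matrix(gs[, -1]) <= 1))
  # a registry without any D-box ChIP-seq dataset cannot build group scores
  reg2 <- toy_registry(c("chipseq", "chipseq"), c(1, 1), c(5, 5), 10,
                       tf_groups = c("ebox", "rre"))
  expect_error(tf_group_scores(make_hits(reg2, list(g = "d01")), reg2),
               "dbox")
})

test_that("phase pooling filters on FDR and wraps to [0, 24)", {
  rec <- data.frame(
    gene_id = paste0("g", 1:6), tissue = "liver",
    phase_ct = c(3, 24.5, -1, 12, 30, 6),
    fdr = c(0.04, 0.01, 0.049, 0.06, 0.05, 0.2))
  pooled <- pool_phases(rec, fdr_cutoff = 0.05)
  expect_equal(nrow(pooled), 3L)  # 0.04, 0.01, 0.049 kept; 0.05 dropped
  expect_equal(pooled$phase_ct, c(3, 0.5, 23))
  expect_error(pool_phases(rec[, -4]), "lack column")
})

test_that("with constant regressors the fit reduces to the circular mean", {
  set.seed(5)
  ph <- (18 + rnorm(60, 0, 2)) %% 24
  dat <- data.frame(phase_ct = ph, s_e = 0, s_d = 0, s_rre = 0)
  fit <- phase_glm(phase_ct ~ s_e + s_d + s_rre, data = dat)
  expect_true(fit$converged)
  expect_true(all(fit$fixed))
  expect_equal(unname(coef(fit)[-1]), c(0, 0, 0))
  expect_equal(unname(coef(fit)["mu_ct"]), circ_mean_ct(ph),
               tolerance = 1e-6)
  th <- ph * pi / 12
  rbar <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  expect_equal(fit$kappa, vm_A_inv(rbar), tolerance = 1e-6)
  # kappa satisfies A(kappa) = mean cosine of residuals
  expect_equal(vm_A(fit$kappa), mean(cos(residuals(fit) * pi / 12)),
               tolerance = 1e-6)
  expect_error(phase_glm(phase_ct ~ s_e, data = dat[1:3, ]), "at least 5")
})

test_that("the fit matches an independent direct-search optimiser", {
  set.seed(21)
  n <- 50
  dat <- data.frame(s_e = runif(n), s_d = rbinom(n, 1, 0.3),
                    s_rre = runif(n))
  eta <- -1.5 * dat$s_e + 0.5 * dat$s_d + 0.8 * dat$s_rre
  mean_rad <- 17 * pi / 12 + 2 * atan(eta)
  dat$phase_ct <- (rvonmises(n, 0, 1.2) + mean_rad) %% (2 * pi) * 12 / pi
  fit <- phase_glm(phase_ct ~ s_e + s_d + s_rre, data = dat)
  # independent oracle: direct maximisation of the same von Mises likelihood
  th <- dat$phase_ct * pi / 12
  X <- as.matrix(dat[, c("s_e", "s_d", "s_rre")])
  nll <- function(p) {
    k <- exp(p[5])
    r <- th - p[1] - 2 * atan(drop(X %*% p[2:4]))
    n * log(2 * pi) + n * (log(besselI(k, 0, expon.scaled = TRUE)) + k) -
      k * sum(cos(r))
  }
  best <- Inf
  for (mu0 in seq(0, 2 * pi, by = pi / 4)) {
    o <- optim(c(mu0, 0, 0, 0, 0), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fit$loglik, -best, tolerance = 1e-6)
})

test_that("log-likelihood ascends along accepted iterations", {
  set.seed(33)
  n <- 200
  dat <- data.frame(s_e = runif(n), s_d = runif(n), s_rre = runif(n))
  mean_rad <- 1.2 + 2 * atan(-2 * dat$s_e + dat$s_rre)
  dat$phase_ct <- (rvonmises(n, 0, 0.8) + mean_rad) %% (2 * pi) * 12 / pi
  fit <- phase_glm(phase_ct ~ s_e + s_d + s_rre, data = dat)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) >= -1e-9))
  expect_equal(fit$loglik, fit$trace[length(fit$trace)])
})

test_that("rotating all phases shifts mu and leaves c and kappa unchanged", {
  set.seed(55)
  n <- 400
  dat <- data.frame(s_e = runif(n), s_d = rbinom(n, 1, 0.2),
                    s_rre = runif(n))
  mean_rad <- 0.8 + 2 * atan(-1.8 * dat$s_e + 0.6 * dat$s_d + 0.4 * dat$s_rre)
  dat$phase_ct <- (rvonmises(n, 0, 1.5) + mean_rad) %% (2 * pi) * 12 / pi
  fit <- phase_glm(phase_ct ~ s_e + s_d + s_rre, data = dat)
  delta <- 5.25
  dat2 <- dat
  dat2$phase_ct <- (dat$phase_ct + delta) %% 24
  fit2 <- phase_glm(phase_ct ~ s_e + s_d + s_rre, data = dat2)
  expect_equal((coef(fit2)["mu_ct"] - coef(fit)["mu_ct"]) %% 24, delta,
               ignore_attr = TRUE, tolerance = 1e-4)
  expect_equal(coef(fit2)[-1], coef(fit)[-1], tolerance = 1e-4)
  expect_equal(fit2$kappa, fit$kappa, tolerance = 1e-4)
})

test_that("predictions follow the arctan link and stay within a half cycle", {
  m <- phase_model(mu_ct = 17.97, c_e = -2.25, c_d = 0.67, c_rre = 0.41,
                   kappa = 0.58)
  # no regulation: baseline phase exactly
  expect_equal(predict(m, data.frame(s_e = 0, s_d = 0, s_rre = 0)), 17.97)
  # full E-box score: 17.97 + (12/pi)*2*atan(-2.25) ~ CT 9.2 (dusk side)
  p_e <- predict(m, data.frame(s_e = 1, s_d = 0, s_rre = 0))
  expect_equal(p_e, (17.97 + (12 / pi) * 2 * atan(-2.25)) %% 24)
  expect_equal(round(p_e, 1), 9.2)
  # D-box + RRE: wraps past midnight to ~ CT 0.2-0.3
  p_dr <- predict(m, data.frame(s_e = 0, s_d = 1, s_rre = 1))
  expect_equal(p_dr, (17.97 + (12 / pi) * 2 * atan(1.08)) %% 24)
  expect_lt(p_dr, 0.5)
  # bounded within mu +/- 12 h before wrapping, continuous in the scores
  s <- seq(0, 1, by = 0.01)
  pr <- predict(m, data.frame(s_e = s, s_d = 0, s_rre = 0))
  off <- (pr - 17.97 + 12) %% 24 - 12
  expect_true(all(abs(off) < 12))
  expect_true(all(abs(diff(off)) < 0.5))
})

test_that("Rayleigh test separates concentrated from uniform phases", {
  r1 <- rayleigh_test(rep(7.5, 10))
  expect_equal(r1$resultant_length, 1)
  expect_lt(r1$p_value, 1e-3)
  r2 <- rayleigh_test(c(0, 6, 12, 18))
  expect_equal(r2$resultant_length, 0, tolerance = 1e-12)
  expect_equal(r2$p_value, 1, tolerance = 0.05)
  expect_error(rayleigh_test(5), "at least 2")
  # Monte-Carlo option agrees with the approximation for moderate n
  set.seed(12)
  ph <- runif(30, 0, 24)
  ra <- rayleigh_test(ph)
  rm_ <- rayleigh_test(ph, method = "mc", n_mc = 20000, seed = 3)
  expect_equal(rm_$p_value, ra$p_value, tolerance = 0.05)
})

test_that("TF-combination summaries recover planted group phases", {
  reg <- default_registry()
  hits <- make_hits(reg, list(
    e1 = "koike_bmal1", e2 = "rey_bmal1",
    r1 = "cho_reverba", r2 = "fang_rora",
    ed = c("koike_clock", "fang_e4bp4"),
    none1 = "robles", none2 = character(0)))
  # combo labels
  obs0 <- data.frame(gene_id = character(0), tissue = character(0),
                     phase_ct = numeric(0))
  cs <- tf_combo_summary(hits, reg, obs0)
  expect_equal(cs$n_genes[cs$combo == "ebox"], 2L)
  expect_equal(cs$n_genes[cs$combo == "rre"], 2L)
  expect_equal(cs$n_genes[cs$combo == "ebox+dbox"], 1L)
  expect_equal(cs$n_genes[cs$combo == "none"], 2L)
  # planted phases: ebox-only genes near CT12, rre-only near CT0
  set.seed(99)
  obs <- rbind(
    data.frame(gene_id = rep(c("e1", "e2"), each = 40), tissue = "t",
               phase_ct = (rvonmises(80, 12 * pi / 12, 8)) * 12 / pi),
    data.frame(gene_id = rep(c("r1", "r2"), each = 40), tissue = "t",
               phase_ct = (rvonmises(80, 0, 8)) * 12 / pi))
  cs <- tf_combo_summary(hits, reg, obs)
  med_e <- cs$median_phase_ct[cs$combo == "ebox"]
  med_r <- cs$median_phase_ct[cs$combo == "rre"]
  expect_lt(abs(med_e - 12), 1)
  expect_lt(min(abs(med_r - 0), abs(med_r - 24)), 1)
  expect_lt(cs$rayleigh_p[cs$combo == "ebox"], 1e-6)
})

test_that("circular median minimises mean absolute circular deviation", {
  ph <- c(23, 0.5, 1, 2, 22)
  med <- circ_median_ct(ph)
  devs <- vapply(sort(unique(ph)), function(m) {
    d <- abs(ph - m); mean(pmin(d, 24 - d))
  }, numeric(1))
  expect_equal(min(devs), {
    d <- abs(ph - med); mean(pmin(d, 24 - d))
  })
  # tie broken towards the smaller CT value
  expect_equal(circ_median_ct(c(1, 11)), 1)
})

test_that("simulate() draws phases around the fitted means", {
  m <- phase_model(mu_ct = 6, c_e = 0, c_d = 0, c_rre = 0, kappa = 300)
  s <- data.frame(s_e = rep(0, 50), s_d = 0, s_rre = 0)
  sims <- simulate(m, nsim = 2, seed = 8, newdata = s)
  expect_equal(dim(sims), c(50L, 2L))
  off <- (as.matrix(sims) - 6 + 12) %% 24 - 12
  expect_true(all(abs(off) < 1))
  expect_identical(sims, simulate(m, nsim = 2, seed = 8, newdata = s))
})
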