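#' Transcription-factor-group binding scores
#'
#' Collapses the ChIP-seq columns of a hit matrix into one score per
#' cis-regulatory element group and gene: the weighted hit sum over that
#' group's datasets, normalised by the maximum attainable within the group,
#' so every score lies in [0, 1]. With the default registry the E-box group
#' (Koike BMAL1/CLOCK/NPAS2 at weight 1 each plus Rey BMAL1 at weight 3) has
#' maximum 6, the D-box group (Fang E4BP4) maximum 1 and the RRE group (Cho
#' REV-ERB alpha/beta, Bugge REV-ERB alpha, Feng REV-ERB beta, Fang ROR
#' alpha) maximum 5. ChIP-seq datasets with `tf_group = "none"` (PER/CRY)
#' contribute to no group.
#'
#' @inheritParams total_scores
#' @return data.frame with columns `gene_id`, `s_e`, `s_d`, `s_rre`.
#' @export
tf_group_scores <- function(hits, registry) {
  hits <- check_hits(hits, registry)
  rec <- registry$records
  groups <- c(ebox = "s_e", dbox = "s_d", rre = "s_rre")
  out <- data.frame(gene_id = rownames(hits), stringsAsFactors = FALSE)
  for (g in names(groups)) {
    idx <- rec$data_class == "chipseq" & rec$tf_group == g
    gmax <- sum(rec$weight[idx])
    if (gmax == 0)
      stop("TF group '", g, "' has no ChIP-seq datasets in the registry")
    out[[groups[[g]]]] <-
      as.numeric(hits[, idx, drop = FALSE] %*% rec$weight[idx]) / gmax
  }
  out
}

#' Filter and pool circadian phase observations
#'
#' Keeps phase records whose rhythmicity FDR is strictly below the cutoff;
#' each surviving gene-tissue pair becomes one pooled observation with its
#' peak phase wrapped onto [0, 24) CT hours.
#'
#' @param records data.frame with columns `gene_id`, `tissue`, `phase_ct`,
#'   `fdr` (as from [simulate_phase_table()] or a rhythmicity analysis).
#' @param fdr_cutoff rhythmicity FDR cutoff (default 0.05).
#' @return data.frame with columns `gene_id`, `tissue`, `phase_ct`.
#' @export
pool_phases <- function(records, fdr_cutoff = 0.05) {
  required <- c("gene_id", "tissue", "phase_ct", "fdr")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0L)
    stop("phase records lack column(s): ", paste(miss, collapse = ", "))
  keep <- records$fdr < fdr_cutoff
  out <- records[keep, c("gene_id", "tissue", "phase_ct")]
  out$phase_ct <- wrap_ct(out$phase_ct)
  rownames(out) <- NULL
  out
}

#' Von Mises circular regression with an arctan link
#'
#' Fits the phase-regulation model
#' `phase ~ vonMises(mu + 2 * arctan(c' S), kappa)`: the peak phase of a
#' transcript (a circular response, in CT hours) is regressed on linear
#' predictors (here TF-group binding scores) through the two-argument arctan
#' link, which maps the linear predictor into an offset of at most a half
#' cycle (+/- 12 h) around the baseline phase `mu`. Estimation maximises the
#' von Mises log-likelihood by Newton ascent with step halving on the
#' sum-of-cosines criterion (equivalent to iteratively reweighted least
#' squares for this family), with the concentration `kappa` profiled out via
#' `A(kappa) = I1/I0 = mean cosine residual`. Because the arctan-link surface
#' can be multimodal, the fit is multi-started from baseline offsets of 0,
#' +/-6 and 12 h around the circular mean and the best likelihood is kept.
#'
#' @param formula model formula; the response is the peak phase in CT hours,
#'   regressors enter the arctan term linearly (no intercept term is used
#'   inside the link: the circular intercept `mu` is always estimated).
#'   Typical usage: `phase_ct ~ s_e + s_d + s_rre`.
#' @param data data.frame holding the response and regressors, e.g. the
#'   merge of [pool_phases()] output with [tf_group_scores()].
#' @param max_iter maximum Newton iterations per start (default 200).
#' @param tol convergence tolerance on the parameter step (default 1e-8).
#' @return An object of class `phase_glm` with components `coefficients`
#'   (`mu_ct` followed by the link coefficients), `kappa`, `loglik`, `vcov`
#'   (observed-information covariance for `(mu_ct, coefficients, kappa)`),
#'   `fitted.values`, `converged`, `trace` (log-likelihood at each accepted
#'   Newton step of the winning start) and `n_obs`. Regressors that are
#'   constant in the data are unidentifiable; their coefficients are fixed at
#'   0 and reported with `NA` standard errors.
#' @seealso [predict.phase_glm()], [phase_model()], [simulate.phase_glm()]
#' @examples
#' set.seed(1)
#' s <- data.frame(s_e = runif(200), s_d = 0, s_rre = runif(200))
#' mean_ct <- wrap_ct(18 + (12 / pi) * 2 * atan(-2 * s$s_e + 0.5 * s$s_rre))
#' s$phase_ct <- rad_to_ct(rvonmises(200, ct_to_rad(mean_ct), kappa = 2))
#' fit <- phase_glm(phase_ct ~ s_e + s_d + s_rre, data = s)
#' coef(fit)
#' @export
phase_glm <- function(formula, data, max_iter = 200, tol = 1e-8) {
  mf <- stats::model.frame(formula, data)
  terms_obj <- attr(mf, "terms")
  y <- stats::model.response(mf)
  X <- stats::model.matrix(terms_obj, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  n <- length(y)
  if (n < 5) stop("phase_glm needs at least 5 observations")
  theta <- ct_to_rad(wrap_ct(y))
  const <- apply(X, 2L, function(v) diff(range(v)) < 1e-12)
  Xf <- X[, !const, drop = FALSE]
  mu_bar <- atan2(mean(sin(theta)), mean(cos(theta)))
  if (!is.finite(mu_bar)) mu_bar <- 0
  best <- NULL
  for (m0 in mu_bar + c(0, pi / 2, -pi / 2, pi)) {
    cand <- arcfit_newton(theta, Xf, m0, max_iter, tol)
    if (is.null(best) || cand$C > best$C) best <- cand
  }
  cvec <- numeric(ncol(X))
  names(cvec) <- colnames(X)
  cvec[!const] <- best$c
  rbar <- max(best$C / n, 0)
  kappa <- max(vm_A_inv(rbar), 1e-8)
  loglik <- vm_loglik_C(best$C, kappa, n)
  trace <- vapply(best$trace_C, function(C)
    vm_loglik_C(C, max(vm_A_inv(max(C / n, 0)), 1e-8), n), numeric(1))
  eta <- if (ncol(X) > 0) drop(X %*% cvec) else rep(0, n)
  fitted_ct <- rad_to_ct(best$mu + 2 * atan(eta))
  fit <- structure(list(
    coefficients = c(mu_ct = rad_to_ct_unwrapped(best$mu), cvec),
    mu_rad = best$mu %% (2 * pi),
    kappa = kappa, loglik = loglik, n_obs = n,
    converged = best$converged, iterations = best$iterations,
    trace = trace, fixed = const,
    fitted.values = fitted_ct, y_ct = wrap_ct(y), X = X,
    terms = terms_obj, call = match.call(), formula = formula
  ), class = "phase_glm")
  fit$vcov <- phase_glm_vcov(theta, Xf, best$mu, best$c, kappa, const,
                             colnames(X))
  fit
}

# mu reported on [0, 24)
rad_to_ct_unwrapped <- function(theta) (theta * 12 / pi) %% 24

# profile log-likelihood given the cosine sum C and kappa
vm_loglik_C <- function(C, kappa, n) {
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  -n * log(2 * pi) - n * log_i0 + kappa * C
}

# Newton ascent with step halving on C(mu, c) = sum cos(theta - mu - 2 atan(Xc))
arcfit_newton <- function(theta, X, mu0, max_iter, tol) {
  p <- ncol(X)
  par <- c(mu0, numeric(p))
  Cfun <- function(par) {
    eta <- if (p > 0) drop(X %*% par[-1L]) else 0
    sum(cos(theta - par[1L] - 2 * atan(eta)))
  }
  C_cur <- Cfun(par)
  trace_C <- C_cur
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- if (p > 0) drop(X %*% par[-1L]) else rep(0, length(theta))
    r <- theta - par[1L] - 2 * atan(eta)
    sr <- sin(r); cr <- cos(r)
    a <- if (p > 0) 2 * X / (1 + eta^2) else NULL   # d(2 atan eta)/dc_j
    g <- c(sum(sr), if (p > 0) colSums(sr * a))
    H <- matrix(0, p + 1L, p + 1L)
    H[1L, 1L] <- -sum(cr)
    if (p > 0) {
      H[1L, -1L] <- H[-1L, 1L] <- -colSums(cr * a)
      H[-1L, -1L] <- -crossprod(a, a * (cr + eta * sr))
    }
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    # fall back to a gradient step when the Hessian is not usable for ascent
    if (is.null(step) || sum(step * g) <= 0)
      step <- g / max(sqrt(sum(g^2)), 1)
    accepted <- FALSE
    for (half in 0:30) {
      par_new <- par + step / 2^half
      C_new <- Cfun(par_new)
      if (C_new >= C_cur) { accepted <- TRUE; break }
    }
    if (!accepted) { converged <- TRUE; break }
    moved <- max(abs(par_new - par))
    par <- par_new
    C_cur <- C_new
    trace_C <- c(trace_C, C_cur)
    if (moved < tol) { converged <- TRUE; break }
  }
  list(mu = par[1L], c = if (p > 0) par[-1L] else numeric(0),
       C = C_cur, trace_C = trace_C, converged = converged, iterations = it)
}

# observed-information covariance for (mu_ct, c_free..., kappa)
phase_glm_vcov <- function(theta, Xf, mu, cfree, kappa, const, all_names) {
  p <- ncol(Xf)
  n <- length(theta)
  nll <- function(par) {
    m <- par[1L]; k <- par[length(par)]
    if (k <= 0) return(Inf)
    eta <- if (p > 0) drop(Xf %*% par[seq_len(p) + 1L]) else 0
    log_i0 <- log(besselI(k, 0, expon.scaled = TRUE)) + k
    n * log(2 * pi) + n * log_i0 - k * sum(cos(theta - m - 2 * atan(eta)))
  }
  par0 <- c(mu, cfree, kappa)
  np <- length(par0)
  h <- pmax(abs(par0), 1) * 1e-4
  H <- matrix(NA_real_, np, np)
  for (i in seq_len(np)) for (j in i:np) {
    ei <- ej <- numeric(np); ei[i] <- h[i]; ej[j] <- h[j]
    H[i, j] <- H[j, i] <-
      (nll(par0 + ei + ej) - nll(par0 + ei - ej) -
       nll(par0 - ei + ej) + nll(par0 - ei - ej)) / (4 * h[i] * h[j])
  }
  V <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, np, np))
  # report mu on the CT-hours scale
  scale <- c(12 / pi, rep(1, np - 1L))
  V <- V * tcrossprod(scale)
  full <- matrix(NA_real_, length(all_names) + 2L, length(all_names) + 2L)
  nm <- c("mu_ct", all_names, "kappa")
  dimnames(full) <- list(nm, nm)
  free_idx <- c(1L, 1L + which(!const), length(all_names) + 2L)
  full[free_idx, free_idx] <- V
  full
}

#' Build a phase model from known coefficients
#'
#' Constructs a `phase_glm` object directly from parameter values (for
#' example published estimates), usable with [predict.phase_glm()] and
#' [simulate.phase_glm()] without refitting.
#'
#' @param mu_ct baseline (unregulated) peak phase in CT hours.
#' @param c_e,c_d,c_rre link coefficients for the E-box, D-box and RRE
#'   group scores.
#' @param kappa von Mises concentration (> 0).
#' @return A `phase_glm` object with coefficients named `s_e`, `s_d`,
#'   `s_rre`.
#' @examples
#' m <- phase_model(mu_ct = 17.97, c_e = -2.25, c_d = 0.67, c_rre = 0.41,
#'                  kappa = 0.58)
#' predict(m, data.frame(s_e = 1, s_d = 0, s_rre = 0))  # ~ CT 9.2
#' @export
phase_model <- function(mu_ct, c_e = 0, c_d = 0, c_rre = 0, kappa = 1) {
  stopifnot(kappa > 0)
  cvec <- c(s_e = c_e, s_d = c_d, s_rre = c_rre)
  structure(list(
    coefficients = c(mu_ct = wrap_ct(mu_ct), cvec),
    mu_rad = ct_to_rad(wrap_ct(mu_ct)),
    kappa = kappa, loglik = NA_real_, n_obs = 0L,
    converged = TRUE, iterations = 0L, trace = numeric(0),
    fixed = stats::setNames(rep(FALSE, 3L), names(cvec)),
    fitted.values = numeric(0), y_ct = numeric(0),
    X = matrix(numeric(0), 0L, 3L, dimnames = list(NULL, names(cvec))),
    terms = NULL, call = match.call(), formula = NULL,
    vcov = NULL
  ), class = "phase_glm")
}

#' Predict peak phases from a fitted phase model
#'
#' Returns `wrap24(mu_ct + (12 / pi) * 2 * arctan(c' s))`: the arctan term is
#' evaluated in radians and converted to hours, so a predictor can shift the
#' peak by strictly less than half a cycle in either direction.
#'
#' @param object a `phase_glm` fit or [phase_model()].
#' @param newdata data.frame of regressor values (columns matching the
#'   coefficient names); omit to predict at the training data.
#' @param type `"ct"` (hours, default) or `"radians"`.
#' @param ... unused.
#' @export
predict.phase_glm <- function(object, newdata = NULL,
                              type = c("ct", "radians"), ...) {
  type <- match.arg(type)
  cvec <- object$coefficients[-1L]
  if (is.null(newdata)) {
    X <- object$X
  } else if (!is.null(object$terms)) {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  } else {
    miss <- setdiff(names(cvec), names(newdata))
    if (length(miss) > 0L)
      stop("newdata lacks column(s): ", paste(miss, collapse = ", "))
    X <- as.matrix(newdata[, names(cvec), drop = FALSE])
  }
  eta <- if (length(cvec) > 0) drop(X %*% cvec) else rep(0, nrow(X))
  theta <- object$mu_rad + 2 * atan(eta)
  if (type == "ct") rad_to_ct(theta) else theta %% (2 * pi)
}

#' @export
print.phase_glm <- function(x, ...) {
  cat("Von Mises circular regression (arctan link)\n")
  if (!is.null(x$call)) cat("  call: ", deparse(x$call), "\n", sep = "")
  cat("  baseline phase mu: CT", format(round(x$coefficients[["mu_ct"]], 2)),
      "\n")
  cvec <- x$coefficients[-1L]
  if (length(cvec) > 0)
    cat("  link coefficients:",
        paste(names(cvec), format(round(cvec, 3)), sep = " = ",
              collapse = ", "), "\n")
  cat("  kappa:", format(round(x$kappa, 3)),
      " n =", x$n_obs,
      if (is.finite(x$loglik)) paste(" logLik =", format(round(x$loglik, 2))),
      "\n")
  if (x$n_obs > 0 && !x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
coef.phase_glm <- function(object, ...) object$coefficients

#' @export
vcov.phase_glm <- function(object, ...) object$vcov

#' @export
logLik.phase_glm <- function(object, ...) {
  structure(object$loglik,
            df = 2L + sum(!object$fixed), nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.phase_glm <- function(object, ...) object$fitted.values

#' Circular residuals of a phase fit
#'
#' Signed shortest-arc differences between observed and fitted phases,
#' in hours on (-12, 12].
#' @param object a `phase_glm` fit.
#' @param ... unused.
#' @export
residuals.phase_glm <- function(object, ...) {
  d <- (object$y_ct - object$fitted.values) %% 24
  ifelse(d > 12, d - 24, d)
}

#' @export
summary.phase_glm <- function(object, ...) {
  est <- c(object$coefficients, kappa = object$kappa)
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else
    rep(NA_real_, length(est))
  z <- est / se
  tab <- cbind(Estimate = est, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, loglik = object$loglik,
                 n_obs = object$n_obs, converged = object$converged,
                 kappa = object$kappa, call = object$call),
            class = "summary.phase_glm")
}

#' @export
print.summary.phase_glm <- function(x, ...) {
  cat("Von Mises circular regression (arctan link)\n")
  if (!is.null(x$call)) cat("call: ", deparse(x$call), "\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE,
                      na.print = "-")
  cat("n =", x$n_obs, " logLik =", format(round(x$loglik, 2)),
      if (!x$converged) " (NOT converged)", "\n")
  invisible(x)
}

#' @export
confint.phase_glm <- function(object, parm, level = 0.95, ...) {
  est <- c(object$coefficients, kappa = object$kappa)
  se <- sqrt(diag(object$vcov))
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - q * se, est + q * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2,
                                       1 - (1 - level) / 2)), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Simulate phases from a fitted phase model
#'
#' Draws von Mises phases around the fitted (or predicted) mean phases with
#' the fitted concentration.
#'
#' @param object a `phase_glm` fit or [phase_model()].
#' @param nsim number of simulated response vectors.
#' @param seed optional seed.
#' @param newdata optional regressor data.frame (defaults to training data).
#' @param ... unused.
#' @return data.frame with `nsim` columns of phases in CT hours.
#' @export
simulate.phase_glm <- function(object, nsim = 1, seed = NULL,
                               newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mean_rad <- ct_to_rad(predict(object, newdata = newdata))
  out <- as.data.frame(lapply(seq_len(nsim), function(i)
    rad_to_ct(vapply(mean_rad, function(m)
      rvonmises(1L, m, object$kappa), numeric(1)))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.phase_glm <- function(x, ...) {
  if (x$n_obs == 0) stop("nothing to plot: model has no training data")
  plot(x$fitted.values, x$y_ct, xlim = c(0, 24), ylim = c(0, 24),
       xlab = "fitted peak phase (CT h)", ylab = "observed peak phase (CT h)",
       main = "Von Mises arctan-link phase regression", ...)
  graphics::abline(0, 1, col = "grey50", lty = 2)
  invisible(x)
}

#' Phase summaries by transcription-factor combination
#'
#' Labels each gene with the presence/absence pattern of binding evidence in
#' the E-box, D-box and RRE groups (any ChIP-seq hit in the group counts) and
#' summarises the pooled phase observations within each combination: number
#' of pooled transcripts, circular median peak phase, and the Rayleigh test
#' of mean direction.
#'
#' @inheritParams total_scores
#' @param observations pooled phase observations from [pool_phases()].
#' @return data.frame with one row per TF combination (`combo`), `n_genes`,
#'   `n` (pooled observations), `median_phase_ct` and `rayleigh_p`.
#' @export
tf_combo_summary <- function(hits, registry, observations) {
  hits <- check_hits(hits, registry)
  rec <- registry$records
  present <- sapply(c("ebox", "dbox", "rre"), function(g) {
    idx <- rec$data_class == "chipseq" & rec$tf_group == g
    rowSums(hits[, idx, drop = FALSE]) > 0
  })
  combo_of <- function(row) {
    on <- c("ebox", "dbox", "rre")[row]
    if (length(on) == 0) "none" else paste(on, collapse = "+")
  }
  gene_combo <- apply(present, 1L, combo_of)
  names(gene_combo) <- rownames(hits)
  levels <- c("ebox", "dbox", "rre", "ebox+dbox", "ebox+rre", "dbox+rre",
              "ebox+dbox+rre", "none")
  obs_combo <- gene_combo[match(observations$gene_id, names(gene_combo))]
  out <- lapply(levels, function(cb) {
    ph <- observations$phase_ct[!is.na(obs_combo) & obs_combo == cb]
    data.frame(
      combo = cb,
      n_genes = sum(gene_combo == cb),
      n = length(ph),
      median_phase_ct = if (length(ph) > 0) circ_median_ct(ph) else NA_real_,
      rayleigh_p = if (length(ph) >= 2) rayleigh_test(ph)$p_value
                   else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
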