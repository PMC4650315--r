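# Circular utilities: von Mises distribution, circular mean/median, and the
# A(kappa) = I1(kappa)/I0(kappa) mapping between concentration and mean
# resultant length. Phases in this package live on circadian time (CT) hours
# in [0, 24); radians = CT * pi / 12.

#' Wrap circadian-time hours onto [0, 24)
#' @param ct numeric vector of hours.
#' @export
wrap_ct <- function(ct) ct %% 24

ct_to_rad <- function(ct) ct * pi / 12
rad_to_ct <- function(theta) wrap_ct(theta * 12 / pi)

#' Mean resultant length ratio A(kappa) and its inverse
#'
#' `vm_A(kappa)` evaluates `I1(kappa)/I0(kappa)`, the mean resultant length of
#' a von Mises distribution with concentration `kappa`; `vm_A_inv(r)` inverts
#' it (Fisher's series/rational approximation refined by Newton steps).
#'
#' @param kappa non-negative concentration.
#' @export
vm_A <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' @rdname vm_A
#' @param r mean resultant length in [0, 1).
#' @export
vm_A_inv <- function(r) {
  vapply(r, function(ri) {
    if (ri <= 0) return(0)
    if (ri >= 1) return(1e8)
    k <- if (ri < 0.53) 2 * ri + ri^3 + 5 * ri^5 / 6
         else if (ri < 0.85) -0.4 + 1.39 * ri + 0.43 / (1 - ri)
         else 1 / (ri^3 - 4 * ri^2 + 3 * ri)
    # Newton refinement on A(k) = r; A'(k) = 1 - A/k - A^2
    for (it in 1:25) {
      a <- vm_A(k)
      da <- 1 - a / k - a^2
      if (!is.finite(da) || da <= 0) break
      step <- (a - ri) / da
      k <- max(k - step, 1e-12)
      if (abs(step) < 1e-12) break
    }
    k
  }, numeric(1))
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `mu` and the result are in radians; see
#' [simulate_phase_table()] for the CT-hours interface.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0; 0 gives the uniform distribution).
#' @return Numeric vector of angles in [0, 2*pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- th[seq_len(min(length(th), n - got))]
    out[got + seq_along(take)] <- take
    got <- got + length(take)
  }
  (mu + out) %% (2 * pi)
}

#' Circular mean direction of phases in CT hours
#' @param ct phases in CT hours.
#' @return Mean direction in CT hours on [0, 24); `NA` if the resultant
#'   length is numerically zero.
#' @export
circ_mean_ct <- function(ct) {
  th <- ct_to_rad(ct)
  s <- mean(sin(th)); c <- mean(cos(th))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  rad_to_ct(atan2(s, c))
}

# mean resultant length of CT-hour phases
resultant_length <- function(ct) {
  th <- ct_to_rad(ct)
  sqrt(mean(sin(th))^2 + mean(cos(th))^2)
}

#' Circular median of phases in CT hours
#'
#' The observed phase minimising the mean absolute circular deviation
#' (shorter arc distance, in hours) to all phases; ties are broken by the
#' smaller CT value.
#'
#' @param ct phases in CT hours.
#' @export
circ_median_ct <- function(ct) {
  ct <- wrap_ct(ct)
  cand <- sort(unique(ct))
  dev <- vapply(cand, function(m) {
    d <- abs(ct - m)
    mean(pmin(d, 24 - d))
  }, numeric(1))
  cand[which(dev <= min(dev) + 1e-12)][1L]
}

#' Rayleigh test of mean direction
#'
#' Tests the null of uniform phases against a unimodal concentration around a
#' mean direction. The statistic is `Z = n * Rbar^2` with `Rbar` the mean
#' resultant length; the p-value uses the second-order approximation
#' `exp(-Z) * (1 + (2Z - Z^2) / (4n))`, clipped to [0, 1]. For small samples
#' a Monte-Carlo p-value under uniformity is available.
#'
#' @param ct phases in CT hours (n >= 2).
#' @param method `"approx"` (default) or `"mc"` (Monte-Carlo, useful for
#'   n < 10).
#' @param n_mc Monte-Carlo replicates for `method = "mc"`.
#' @param seed optional seed for `method = "mc"`.
#' @return List of class `rayleigh_test` with `mean_direction_ct`,
#'   `resultant_length`, `statistic`, `p_value`, `n` and `method`.
#' @export
rayleigh_test <- function(ct, method = c("approx", "mc"), n_mc = 10000,
                          seed = NULL) {
  method <- match.arg(method)
  n <- length(ct)
  if (n < 2) stop("rayleigh_test needs at least 2 phases")
  rbar <- resultant_length(ct)
  z <- n * rbar^2
  if (method == "approx") {
    p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n))
    p <- min(max(p, 0), 1)
  } else {
    if (!is.null(seed)) set.seed(seed)
    zs <- vapply(seq_len(n_mc), function(i) {
      u <- stats::runif(n, 0, 2 * pi)
      n * (mean(sin(u))^2 + mean(cos(u))^2)
    }, numeric(1))
    p <- (sum(zs >= z) + 1) / (n_mc + 1)
  }
  structure(list(mean_direction_ct = circ_mean_ct(ct),
                 resultant_length = rbar, statistic = z, p_value = p,
                 n = n, method = method),
            class = "rayleigh_test")
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat("Rayleigh test of mean direction (n = ", x$n, ")\n", sep = "")
  cat("  mean direction: CT", format(round(x$mean_direction_ct, 2)),
      "  Rbar =", format(round(x$resultant_length, 3)), "\n")
  cat("  Z =", format(round(x$statistic, 3)), " p =",
      format.pval(x$p_value), "\n")
  invisible(x)
}
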