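# Circular statistics for response-phase samples. Angles are degrees in
# [0, 360) at the interface and radians internally.

circ_test_row <- function(test_name, statistic, p_value, n, n2 = NA_integer_,
                          mu0 = NA_real_, method = "asymptotic",
                          p_asymptotic = NA_real_) {
  tibble::tibble(
    test_name = test_name, statistic = statistic,
    p_value = min(max(p_value, 0), 1), n = as.integer(n),
    n2 = as.integer(n2), mu0 = mu0, method = method,
    p_asymptotic = p_asymptotic
  )
}

#' Circular summary statistics
#'
#' Mean direction, mean resultant length and circular standard deviation of
#' a sample of angles in degrees.
#'
#' @param angles Numeric angles in degrees.
#' @return List of class `"circ_summary"` with `mu` (degrees in `[0, 360)`,
#'   `NA` when `rho` is 0), `rho` in `[0, 1]`, `circ_sd` (degrees,
#'   `sqrt(-2 log rho)` converted from radians; `Inf` when `rho` is 0) and
#'   `n`.
#' @export
#' @examples
#' circular_summary(c(80, 90, 100))
circular_summary <- function(angles) {
  if (length(angles) == 0) {
    vr_stop("empty phase sample", "vr_insufficient_data")
  }
  th <- deg2rad(angles)
  C <- mean(cos(th))
  S <- mean(sin(th))
  rho <- sqrt(C^2 + S^2)
  undefined <- rho < .Machine$double.eps * 8
  mu <- if (undefined) NA_real_ else rad2deg(atan2(S, C)) %% 360
  circ_sd <- if (undefined) Inf else rad2deg(sqrt(-2 * log(min(rho, 1))))
  structure(
    list(mu = mu, rho = min(rho, 1), circ_sd = circ_sd, n = length(angles),
         undefined_mean = undefined),
    class = "circ_summary"
  )
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("Circular summary (n = %d)\n", x$n))
  cat(sprintf("  mean direction mu  : %s deg\n",
              if (is.na(x$mu)) "undefined" else formatC(x$mu, digits = 4)))
  cat(sprintf("  resultant length   : %.4f\n", x$rho))
  cat(sprintf("  circular SD        : %s deg\n",
              if (is.infinite(x$circ_sd)) "Inf" else formatC(x$circ_sd, digits = 4)))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests uniformity against a unimodal alternative. The reported statistic is
#' the mean resultant length `rho`; the p-value uses the standard
#' approximation based on `z = n * rho^2`.
#'
#' @param angles Numeric angles in degrees, `n >= 4`.
#' @return One-row tibble (`test_name`, `statistic`, `p_value`, `n`, ...).
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 4) vr_stop("Rayleigh test needs n >= 4", "vr_insufficient_data")
  rho <- circular_summary(angles)$rho
  z <- n * rho^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  circ_test_row("rayleigh", rho, p, n)
}

#' V-test of uniformity against a specified mean direction
#'
#' One-tailed test of uniformity with power concentrated on a unimodal
#' alternative at `mu0`. The statistic is `V = rho * cos(mu - mu0)`; its
#' p-value comes from the normal approximation to `u = V * sqrt(2 n)`.
#'
#' @param angles Numeric angles in degrees, `n >= 4`.
#' @param mu0 Hypothesized mean direction in degrees.
#' @return One-row tibble.
#' @export
v_test <- function(angles, mu0) {
  n <- length(angles)
  if (n < 4) vr_stop("V-test needs n >= 4", "vr_insufficient_data")
  s <- circular_summary(angles)
  V <- if (s$undefined_mean) 0 else s$rho * cos(deg2rad(s$mu - mu0))
  u <- V * sqrt(2 * n)
  circ_test_row("v_test", V, pnorm(u, lower.tail = FALSE), n, mu0 = mu0)
}

#' Kuiper's test of circular uniformity
#'
#' Rotation-invariant analogue of the Kolmogorov-Smirnov test;
#' the p-value uses the standard asymptotic series with Stephens' small-sample
#' correction factor.
#'
#' @param angles Numeric angles in degrees.
#' @return One-row tibble.
#' @export
kuiper_test <- function(angles) {
  n <- length(angles)
  if (n < 4) vr_stop("Kuiper test needs n >= 4", "vr_insufficient_data")
  u <- sort((angles %% 360) / 360)
  i <- seq_len(n)
  d_plus <- max(i / n - u)
  d_minus <- max(u - (i - 1) / n)
  Vn <- d_plus + d_minus
  k <- Vn * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
  j <- 1:100
  p <- 2 * sum((4 * j^2 * k^2 - 1) * exp(-2 * j^2 * k^2))
  circ_test_row("kuiper", Vn, p, n)
}

#' Rao's spacing test of circular uniformity
#'
#' Based on the deviation of arc spacings from equal spacing; sensitive to
#' multimodal departures. The p-value is Monte Carlo, against `n_sim` uniform
#' samples of the same size.
#'
#' @param angles Numeric angles in degrees.
#' @param n_sim Number of Monte Carlo null replicates.
#' @param null_stats Optional precomputed vector of null statistics for this
#'   sample size (see [rao_null_statistics()]), reused across repeated calls.
#' @param seed Seed for the Monte Carlo draw (ignored when `null_stats` is
#'   supplied).
#' @return One-row tibble; the statistic is `U = 0.5 * sum(|T_i - 360/n|)`
#'   in degrees.
#' @export
rao_spacing_test <- function(angles, n_sim = 10000, null_stats = NULL,
                             seed = NULL) {
  n <- length(angles)
  if (n < 4) vr_stop("Rao spacing test needs n >= 4", "vr_insufficient_data")
  U <- rao_statistic(angles)
  if (is.null(null_stats)) {
    null_stats <- rao_null_statistics(n, n_sim = n_sim, seed = seed)
  }
  p <- (sum(null_stats >= U) + 1) / (length(null_stats) + 1)
  circ_test_row("rao_spacing", U, p, n, method = "monte_carlo")
}

rao_statistic <- function(angles) {
  a <- sort(angles %% 360)
  spacings <- diff(c(a, a[1] + 360))
  0.5 * sum(abs(spacings - 360 / length(a)))
}

#' Monte Carlo null distribution of the Rao spacing statistic
#'
#' @param n Sample size.
#' @param n_sim Number of uniform replicates.
#' @param seed Optional seed.
#' @return Numeric vector of `n_sim` null statistics.
#' @export
rao_null_statistics <- function(n, n_sim = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_sim), function(i) rao_statistic(runif(n, 0, 360)), 0)
}

## --- von Mises helpers -----------------------------------------------------

# A1(kappa) = I1(kappa) / I0(kappa): scaled Bessel functions for moderate
# kappa, the standard asymptotic expansion where besselI underflows.
vm_a1 <- function(kappa) {
  ifelse(kappa == 0, 0,
         ifelse(kappa > 1e4,
                1 - 1 / (2 * kappa) - 1 / (8 * kappa^2) - 1 / (8 * kappa^3),
                besselI(kappa, 1, expon.scaled = TRUE) /
                  besselI(kappa, 0, expon.scaled = TRUE)))
}

#' Maximum-likelihood fit of a von Mises distribution
#'
#' @param angles Numeric angles in degrees.
#' @return List with `mu` (degrees) and `kappa` (concentration).
#' @export
fit_von_mises <- function(angles) {
  s <- circular_summary(angles)
  rho <- s$rho
  if (rho < 1e-8) return(list(mu = 0, kappa = 0))
  kappa_hi <- 1e6
  if (rho >= vm_a1(kappa_hi)) {
    kappa <- kappa_hi
  } else {
    kappa <- uniroot(function(k) vm_a1(k) - rho, c(1e-8, kappa_hi),
                     tol = 1e-10)$root
  }
  list(mu = s$mu %||% 0, kappa = kappa)
}

# von Mises CDF on [0, 360) measured from angle 0, by trapezoidal
# integration of the density on a fixed grid; accurate to O(grid^-2).
pvonmises <- function(angles, mu, kappa, ngrid = 1024) {
  if (kappa == 0) return((angles %% 360) / 360)
  grid <- seq(0, 360, length.out = ngrid + 1)
  dens <- exp(kappa * (cos(deg2rad(grid - mu)) - 1))
  h <- 360 / ngrid
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * h))
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(grid, cdf, xout = angles %% 360, rule = 2)$y
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to the circular
#' uniform.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration parameter.
#' @return Angles in degrees in `[0, 360)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2 * (n - length(out)), 16)
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    out <- c(out, th)
  }
  (rad2deg(out[seq_len(n)]) + mu) %% 360
}

watson_u2_stat <- function(u) {
  n <- length(u)
  u <- sort(u)
  i <- seq_len(n)
  sum((u - (2 * i - 1) / (2 * n))^2) + 1 / (12 * n) - n * (mean(u) - 0.5)^2
}

#' Watson one-sample goodness-of-fit test against a fitted von Mises
#'
#' Computes the one-sample Watson `U^2` statistic for the sample transformed
#' through the CDF of a von Mises distribution fitted by maximum likelihood,
#' with the p-value obtained by parametric bootstrap (resampling from the
#' fitted distribution and refitting in every replicate, so the estimation
#' step is accounted for).
#'
#' @param angles Numeric angles in degrees, `n >= 8`.
#' @param n_boot Number of bootstrap replicates (at least 99).
#' @param seed Seed for the bootstrap.
#' @return One-row tibble with `method = "monte_carlo"`.
#' @export
watson_vm_gof <- function(angles, n_boot = 999, seed = NULL) {
  n <- length(angles)
  if (n < 8) vr_stop("Watson GOF needs n >= 8", "vr_insufficient_data")
  if (n_boot < 99) vr_stop("n_boot must be at least 99", "vr_config_error")
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_von_mises(angles)
  obs <- watson_u2_stat(pvonmises(angles, fit$mu, fit$kappa))
  boot <- vapply(seq_len(n_boot), function(i) {
    x <- rvonmises(n, fit$mu, fit$kappa)
    f <- fit_von_mises(x)
    watson_u2_stat(pvonmises(x, f$mu, f$kappa))
  }, 0)
  p <- (sum(boot >= obs) + 1) / (n_boot + 1)
  circ_test_row("watson_gof", obs, p, n, method = "monte_carlo")
}

#' Battery of circular uniformity / goodness-of-fit tests
#'
#' Runs Kuiper's test, Rao's spacing test (Monte Carlo p) and the Watson
#' von Mises goodness-of-fit test (parametric bootstrap p) on one phase
#' sample, complementing the Rayleigh test's p-value with tests sensitive to
#' non-unimodal departures.
#'
#' @param angles Numeric angles in degrees, `n >= 8`.
#' @param n_boot Bootstrap replicates for the Watson GOF test (>= 99).
#' @param n_sim_rao Monte Carlo replicates for the Rao spacing p-value.
#' @param seed Seed for both resampling procedures.
#' @return Tibble with one row per test.
#' @export
uniformity_suite <- function(angles, n_boot = 999, n_sim_rao = 10000,
                             seed = 1) {
  n <- length(angles)
  if (n < 8) vr_stop("uniformity suite needs n >= 8", "vr_insufficient_data")
  if (n_boot < 99) vr_stop("n_boot must be at least 99", "vr_config_error")
  rbind(
    kuiper_test(angles),
    rao_spacing_test(angles, n_sim = n_sim_rao, seed = derive_seed(seed, "rao")),
    watson_vm_gof(angles, n_boot = n_boot, seed = derive_seed(seed, "gof"))
  )
}

watson_two_sample_stat <- function(values, is_a, n, m) {
  # d_k = F_a - F_b evaluated at the pooled order statistics
  N <- n + m
  d <- cumsum(is_a) / n - cumsum(!is_a) / m
  n * m / N^2 * sum((d - mean(d))^2)
}

#' Watson's two-sample U-squared test
#'
#' Compares two circular samples without reference to an origin. The p-value
#' is obtained by permuting sample labels (`n_perm` replicates); the standard
#' asymptotic approximation is reported alongside in `p_asymptotic`.
#'
#' @param a,b Numeric angle samples in degrees, each `n >= 8`.
#' @param n_perm Number of label permutations (at least 99).
#' @param seed Seed for the permutation draw.
#' @return One-row tibble with `statistic` (U^2), permutation `p_value`, and
#'   `p_asymptotic`.
#' @export
watson_two_sample <- function(a, b, n_perm = 999, seed = NULL) {
  n <- length(a); m <- length(b)
  if (n < 8 || m < 8) {
    vr_stop("Watson two-sample test needs n >= 8 in both samples",
            "vr_insufficient_data")
  }
  if (n_perm < 99) vr_stop("n_perm must be at least 99", "vr_config_error")
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(a %% 360, b %% 360)
  ord <- order(pooled)
  is_a <- c(rep(TRUE, n), rep(FALSE, m))[ord]
  obs <- watson_two_sample_stat(pooled[ord], is_a, n, m)
  perm <- vapply(seq_len(n_perm), function(i) {
    watson_two_sample_stat(pooled[ord], sample(is_a), n, m)
  }, 0)
  p_perm <- (sum(perm >= obs) + 1) / (n_perm + 1)
  j <- 1:50
  p_asym <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * pi^2 * obs))
  circ_test_row("watson_two_sample", obs, p_perm, n, n2 = m,
                method = "permutation",
                p_asymptotic = min(max(p_asym, 0), 1))
}
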