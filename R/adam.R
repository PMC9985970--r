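# ADAM: adaptation and anticipation model for interpersonal timing.
#
# The adaptation module corrects the phase and period of an internal
# timekeeper in proportion to the current asynchrony; the anticipation
# module predicts the partner's next interval as a weighted sum of linear
# extrapolation and tracking of previous intervals; the joint module
# applies an anticipatory error correction pulling the planned onset toward
# the predicted partner onset.

ADAM_BOUNDS <- list(
  alpha = c(-2, 2), beta = c(-2, 2), m = c(-3, 3), gamma = c(0, 2)
)

#' ADAM parameter set
#'
#' @param alpha Phase-correction gain (dimensionless, in `[-2, 2]`); used by
#'   the adaptation-only version.
#' @param beta Period-correction gain (dimensionless, in `[-2, 2]`).
#' @param m Prediction-tracking weight in `[-3, 3]`: 1 = pure linear
#'   extrapolation of the partner's intervals, 0 = pure tracking (copy the
#'   last interval); used by the joint version.
#' @param gamma Anticipatory error-correction gain in `[0, 2]`; used by the
#'   joint version.
#' @param sigma Motor timing noise scale in seconds (standard deviation of
#'   the Gaussian term added to each planned onset).
#' @param version `"adaptation_only"` or `"joint"`.
#' @return List of class `"adam_params"`.
#' @export
adam_params <- function(alpha = 0, beta = 0, m = 0, gamma = 0, sigma = 0,
                        version = c("adaptation_only", "joint")) {
  version <- match.arg(version)
  check <- function(val, name) {
    b <- ADAM_BOUNDS[[name]]
    if (val < b[1] || val > b[2]) {
      vr_stop(sprintf("%s = %g outside bounds [%g, %g]", name, val, b[1], b[2]),
              "vr_param_error")
    }
  }
  check(alpha, "alpha"); check(beta, "beta"); check(m, "m"); check(gamma, "gamma")
  if (sigma < 0) vr_stop("sigma must be non-negative", "vr_param_error")
  structure(list(alpha = alpha, beta = beta, m = m, gamma = gamma,
                 sigma = sigma, version = version),
            class = "adam_params")
}

# Linear extrapolation of the next value from the last min(window, k)
# values of a series, by least-squares line fit.
extrapolate_next <- function(hist, window) {
  k <- min(window, length(hist))
  if (k == 0) return(NA_real_)
  h <- hist[(length(hist) - k + 1):length(hist)]
  if (k == 1) return(h)
  xs <- seq_len(k)
  slope <- sum((xs - mean(xs)) * (h - mean(h))) / sum((xs - mean(xs))^2)
  mean(h) + slope * (k + 1 - mean(xs))
}

#' Simulate a responding caller with ADAM
#'
#' Generates focal onsets in response to a fixed partner onset sequence. With
#' asynchrony `A_n = f_n - p_n` and timekeeper `T` (initialised to the mean
#' partner interval), the adaptation-only version updates
#' `T <- T - beta * A_n` and plans `f_{n+1} = f_n + T - alpha * A_n + e`;
#' the joint version predicts the partner's next interval as
#' `m * extrapolation + (1 - m) * last interval`, plans `f* = f_n + T`
#' (with the same period update), and corrects
#' `f_{n+1} = f* - gamma * (f* - (p_n + S_hat + target)) + e`, where `e` is
#' i.i.d. Gaussian with scale `sigma`.
#'
#' @param params An [adam_params()] object (its `version` selects the model).
#' @param partner_onsets Increasing numeric onsets (at least 3).
#' @param initial_asynchrony First focal onset minus first partner onset, in
#'   seconds.
#' @param seed Optional seed for the noise draws.
#' @param window Number of partner intervals in the extrapolation window.
#' @param target Target asynchrony of the anticipatory correction, in
#'   seconds (0 aims at coincidence with the predicted partner onset).
#' @return Numeric vector of focal onsets, same length as `partner_onsets`.
#' @export
adam_simulate <- function(params, partner_onsets, initial_asynchrony = 0,
                          seed = NULL, window = 3, target = 0) {
  stopifnot(inherits(params, "adam_params"))
  p <- partner_onsets
  n <- length(p)
  if (n < 3) vr_stop("need at least 3 partner onsets", "vr_insufficient_data")
  if (any(diff(p) <= 0)) {
    vr_stop("partner onsets must be strictly increasing", "vr_format_error")
  }
  if (!is.null(seed)) set.seed(seed)
  eps <- if (params$sigma > 0) rnorm(n - 1, 0, params$sigma) else numeric(n - 1)
  f <- numeric(n)
  f[1] <- p[1] + initial_asynchrony
  T_k <- mean(diff(p))
  for (t in seq_len(n - 1)) {
    A <- f[t] - p[t]
    T_k <- T_k - params$beta * A
    if (params$version == "adaptation_only") {
      f[t + 1] <- f[t] + T_k - params$alpha * A + eps[t]
    } else {
      hist <- if (t >= 2) diff(p[1:t]) else numeric(0)
      s_hat <- if (length(hist) == 0) {
        mean(diff(p))
      } else {
        params$m * extrapolate_next(hist, window) +
          (1 - params$m) * hist[length(hist)]
      }
      f_star <- f[t] + T_k
      f[t + 1] <- f_star - params$gamma * (f_star - (p[t] + s_hat + target)) +
        eps[t]
    }
  }
  f
}

#' Concatenate bout-level series for model fitting
#'
#' Joins several paired bout series into one series whose boundary mask
#' marks the first position of every bout after the first; masked positions
#' are excluded from the fitting loss, and the timekeeper state is
#' re-initialised at each bout start.
#'
#' @param series_list Non-empty list of `"timing_series"` objects (onset
#'   mode).
#' @return A single `"timing_series"` with the combined boundary mask.
#' @export
concatenate_bouts <- function(series_list) {
  if (length(series_list) == 0) {
    vr_stop("no bout series to concatenate", "vr_insufficient_data")
  }
  stopifnot(all(vapply(series_list, inherits, TRUE, "timing_series")))
  lens <- vapply(series_list, function(s) length(s$focal), 0L)
  mask <- unlist(lapply(lens, function(l) c(TRUE, rep(FALSE, l - 1))))
  mask[1] <- FALSE
  timing_series(
    focal = unlist(lapply(series_list, `[[`, "focal")),
    partner = unlist(lapply(series_list, `[[`, "partner")),
    mask = mask,
    value_mode = series_list[[1]]$value_mode,
    session_id = series_list[[1]]$session_id,
    level = "session"
  )
}

# Segment bookkeeping: start index of the bout segment containing each
# position, from the boundary mask.
segment_starts <- function(mask) {
  cummax(ifelse(mask | seq_along(mask) == 1, seq_along(mask), 0L))
}

# Precomputed per-position design for the one-step predictions. Because the
# timekeeper follows T_t = T0(segment) - beta * cumsum(A) and the partner
# interval prediction mixes two data-driven forecasts, every prediction is a
# cheap vector expression in the parameters given these columns. Rows are
# positions t that predict t+1 (t+1 not a bout start).
adam_design <- function(f, p, mask, window = 3) {
  n <- length(f)
  starts <- segment_starts(mask)
  rows <- list()
  for (s0 in unique(starts)) {
    idx <- which(starts == s0)
    len <- length(idx)
    if (len < 2) next
    pseg <- p[idx]; fseg <- f[idx]
    T0 <- mean(diff(pseg))
    S <- diff(pseg)
    A <- fseg - pseg
    cumA <- cumsum(A)
    tloc <- seq_len(len - 1)
    extrap <- vapply(tloc, function(j) {
      if (j < 2) T0 else extrapolate_next(S[seq_len(j - 1)], window)
    }, 0)
    track <- vapply(tloc, function(j) {
      if (j < 2) T0 else S[j - 1]
    }, 0)
    rows[[length(rows) + 1L]] <- list(
      f_t = fseg[tloc], p_t = pseg[tloc], f_next = fseg[tloc + 1],
      A = A[tloc], cumA = cumA[tloc], T0 = rep(T0, len - 1),
      extrap = extrap, track = track, pos_next = idx[tloc + 1]
    )
  }
  if (length(rows) == 0) {
    return(list(f_t = numeric(0), p_t = numeric(0), f_next = numeric(0),
                A = numeric(0), cumA = numeric(0), T0 = numeric(0),
                extrap = numeric(0), track = numeric(0),
                pos_next = integer(0)))
  }
  out <- lapply(names(rows[[1]]), function(nm) {
    unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  })
  names(out) <- names(rows[[1]])
  out
}

adam_predict_design <- function(par, version, d, target = 0) {
  T_t <- d$T0 - par[["beta"]] * d$cumA
  if (version == "adaptation_only") {
    d$f_t + T_t - par[["alpha"]] * d$A
  } else {
    f_star <- d$f_t + T_t
    s_hat <- par[["m"]] * d$extrap + (1 - par[["m"]]) * d$track
    f_star - par[["gamma"]] * (f_star - (d$p_t + s_hat + target))
  }
}

# One-step-ahead ADAM predictions of focal onsets given observed data.
# Returns pred (length n, NA where undefined) and the valid residual
# positions (2..n, excluding bout starts).
adam_onestep <- function(par, version, f, p, mask, window = 3, target = 0) {
  d <- adam_design(f, p, mask, window)
  pred <- rep(NA_real_, length(f))
  pred[d$pos_next] <- adam_predict_design(par, version, d, target)
  list(pred = pred, valid = d$pos_next)
}

adam_sse <- function(par, version, f, p, mask, window = 3, target = 0) {
  os <- adam_onestep(par, version, f, p, mask, window, target)
  sum((f[os$valid] - os$pred[os$valid])^2)
}

adam_param_names <- function(version) {
  if (version == "adaptation_only") c("alpha", "beta") else c("beta", "m", "gamma")
}

#' Fit ADAM to a paired timing series
#'
#' Estimates the model parameters by minimising the summed squared
#' one-step-ahead prediction error of the focal onsets over the bounded
#' parameter space. The adaptation-only version's predictions are linear in
#' `(alpha, beta)`, so its least-squares solution is computed exactly (with
#' a bounded refinement only when the unconstrained optimum leaves the box);
#' the joint version uses bounded quasi-Newton optimisation from
#' Latin-hypercube starts and returns the best local solution. Fits are
#' deterministic given the seed.
#'
#' @param series A `"timing_series"` in onset mode with at least 10 unmasked
#'   prediction terms.
#' @param version `"adaptation_only"` or `"joint"`.
#' @param multi_start Number of optimisation starts for the joint version.
#' @param seed Seed controlling the start placement.
#' @param window Extrapolation window of the anticipation module.
#' @param target Target asynchrony of the anticipatory correction, seconds.
#' @return List of class `"adam_fit"`: `estimates` (named vector),
#'   `sigma_hat`, `sse`, `n_terms`, `version`, `flags` (filled by
#'   [adam_permutation_test()]).
#' @export
fit_adam <- function(series, version = c("adaptation_only", "joint"),
                     multi_start = 16, seed = 1, window = 3, target = 0) {
  version <- match.arg(version)
  stopifnot(inherits(series, "timing_series"))
  d <- adam_design(series$focal, series$partner, series$mask, window)
  n_terms <- length(d$pos_next)
  if (n_terms < 10) {
    vr_stop(sprintf("only %d prediction terms; need at least 10", n_terms),
            "vr_insufficient_data")
  }
  pnames <- adam_param_names(version)
  lower <- vapply(pnames, function(nm) ADAM_BOUNDS[[nm]][1], 0)
  upper <- vapply(pnames, function(nm) ADAM_BOUNDS[[nm]][2], 0)
  obj <- function(theta) {
    par <- setNames(rep(0, 4), c("alpha", "beta", "m", "gamma"))
    par[pnames] <- theta
    sum((d$f_next - adam_predict_design(par, version, d, target))^2)
  }

  if (version == "adaptation_only") {
    est <- fit_adaptation_ols(d)
    if (!is.null(est) && all(est >= lower) && all(est <= upper)) {
      theta <- est
      sse <- obj(theta)
    } else {
      theta <- NULL
    }
  } else {
    theta <- NULL
  }

  if (is.null(theta)) {
    set.seed(derive_seed(seed, paste0("fit_", version)))
    starts <- lhs::randomLHS(multi_start, length(pnames))
    starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
    best <- NULL
    for (i in seq_len(multi_start)) {
      res <- tryCatch(
        optim(starts[i, ], obj, method = "L-BFGS-B", lower = lower,
              upper = upper, control = list(factr = 1e2, maxit = 500)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best)) vr_stop("all optimisation starts failed",
                               "vr_optim_error")
    theta <- best$par
    sse <- best$value
  }
  names(theta) <- pnames
  structure(
    list(estimates = theta, sigma_hat = sqrt(sse / n_terms), sse = sse,
         n_terms = n_terms, version = version, window = window,
         target = target, multi_start = multi_start, seed = seed,
         flags = NULL),
    class = "adam_fit"
  )
}

# Exact least squares for the adaptation-only version: with per-segment
# timekeeper reset, the residual at t is
#   f[t+1] - f[t] - T0_seg = -alpha * A_t - beta * cumsum_seg(A)_t + e.
fit_adaptation_ols <- function(d) {
  y <- d$f_next - d$f_t - d$T0
  X <- cbind(-d$A, -d$cumA)
  if (nrow(X) < 2 || qr(X)$rank < 2) return(NULL)
  as.numeric(qr.solve(X, y))
}

#' @export
print.adam_fit <- function(x, ...) {
  cat(sprintf("ADAM fit (%s), %d prediction terms\n", x$version, x$n_terms))
  for (nm in names(x$estimates)) {
    flag <- if (!is.null(x$flags)) sprintf(" [%s]", x$flags[[nm]]) else ""
    cat(sprintf("  %-6s = %8.4f%s\n", nm, x$estimates[[nm]], flag))
  }
  cat(sprintf("  sigma  = %8.4f s\n  sse    = %.6g\n", x$sigma_hat, x$sse))
  invisible(x)
}

# Permute the order of partner intervals within each bout segment and
# rebuild the partner onsets from each segment's first onset.
permute_partner_intervals <- function(series) {
  p <- series$partner
  starts <- segment_starts(series$mask)
  for (s0 in unique(starts)) {
    idx <- which(starts == s0)
    if (length(idx) < 3) next
    S <- diff(p[idx])
    p[idx] <- p[idx[1]] + cumsum(c(0, sample(S)))
  }
  timing_series(series$focal, p, mask = series$mask,
                value_mode = series$value_mode, session_id = series$session_id,
                bout_id = series$bout_id, level = series$level)
}

#' Permutation significance envelope for ADAM estimates
#'
#' Refits the model to `n_perm` datasets in which the order of the partner's
#' intervals is randomly permuted within each bout (preserving the marginal
#' interval distribution while destroying temporal contingency), and flags
#' each observed estimate against the resulting envelope: `two_tailed` when
#' outside the 2.5th-97.5th percentile band, `one_tailed` when outside the
#' 5th-95th band in the direction of the estimate's sign, otherwise `ns`.
#'
#' @param series A `"timing_series"` (onset mode).
#' @param version Model version, as in [fit_adam()].
#' @param n_perm Number of permutation refits (at least 100).
#' @param seed Seed for permutations and refit starts.
#' @param multi_start Starts per refit (the observed fit uses
#'   [fit_adam()]'s default of 16).
#' @inheritParams fit_adam
#' @return List of class `"adam_permutation"`: `fit` (with `flags` filled),
#'   `envelope` (tibble of per-parameter percentiles 2.5, 5, 25, 50, 75, 95,
#'   97.5), `perm_estimates` (matrix), `n_perm`, `seed`.
#' @export
adam_permutation_test <- function(series, version = c("adaptation_only", "joint"),
                                  n_perm = 1000, seed = 1, multi_start = 4,
                                  window = 3, target = 0) {
  version <- match.arg(version)
  if (n_perm < 100) vr_stop("n_perm must be at least 100", "vr_config_error")
  fit <- fit_adam(series, version, seed = seed, window = window,
                  target = target)
  pnames <- names(fit$estimates)
  set.seed(derive_seed(seed, "perm"))
  perm_seeds <- sample.int(2^31 - 2, n_perm)
  est_mat <- matrix(NA_real_, n_perm, length(pnames),
                    dimnames = list(NULL, pnames))
  for (i in seq_len(n_perm)) {
    set.seed(perm_seeds[i])
    perm <- permute_partner_intervals(series)
    pf <- tryCatch(
      fit_adam(perm, version, multi_start = multi_start,
               seed = perm_seeds[i], window = window, target = target),
      vr_error = function(e) NULL)
    if (!is.null(pf)) est_mat[i, ] <- pf$estimates
  }
  probs <- c(0.025, 0.05, 0.25, 0.5, 0.75, 0.95, 0.975)
  qs <- apply(est_mat, 2, quantile, probs = probs, na.rm = TRUE)
  envelope <- tibble::tibble(parameter = pnames)
  for (k in seq_along(probs)) {
    envelope[[sprintf("p%g", probs[k] * 100)]] <- qs[k, ]
  }
  flags <- vapply(pnames, function(nm) {
    est <- fit$estimates[[nm]]
    q <- qs[, nm]
    if (est < q[1] || est > q[7]) return("two_tailed")
    if ((est > 0 && est > q[6]) || (est < 0 && est < q[2])) return("one_tailed")
    "ns"
  }, "")
  fit$flags <- flags
  structure(
    list(fit = fit, envelope = envelope, perm_estimates = est_mat,
         n_perm = n_perm, seed = seed),
    class = "adam_permutation"
  )
}

#' Parameter-recovery study
#'
#' Simulates responding callers at known parameter values over a grid of
#' series lengths, refits the model to every replicate, and reports the
#' per-cell bias and root-mean-square error of each estimated parameter.
#' Used to verify that estimates are not compromised by sequence length or
#' by the bout-concatenation procedure.
#'
#' @param param_grid List of [adam_params()] objects (may be empty).
#' @param lengths Integer vector of partner-sequence lengths.
#' @param n_rep Replicates per cell.
#' @param seed Master seed.
#' @param period Partner period in seconds for the isochronous stimulus.
#' @param initial_asynchrony Initial asynchrony passed to the simulator.
#' @return Tibble with one row per (cell, length, parameter): `truth`,
#'   `bias`, `rmse`, `n_rep`.
#' @export
adam_recovery_study <- function(param_grid, lengths, n_rep = 20, seed = 1,
                                period = 2, initial_asynchrony = 0.5) {
  rows <- list()
  cell <- 0L
  for (params in param_grid) {
    cell <- cell + 1L
    pnames <- adam_param_names(params$version)
    truth <- unlist(params[pnames])
    for (L in lengths) {
      partner <- seq(0, by = period, length.out = L)
      errs <- matrix(NA_real_, n_rep, length(pnames),
                     dimnames = list(NULL, pnames))
      for (r in seq_len(n_rep)) {
        s <- derive_seed(seed, sprintf("rec_%d_%d_%d", cell, L, r))
        focal <- adam_simulate(params, partner,
                               initial_asynchrony = initial_asynchrony,
                               seed = s)
        series <- timing_series(focal, partner, value_mode = "onsets")
        fit <- tryCatch(fit_adam(series, params$version, seed = s),
                        vr_error = function(e) NULL)
        if (!is.null(fit)) errs[r, ] <- fit$estimates[pnames] - truth
      }
      for (nm in pnames) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cell = cell, length = as.integer(L), parameter = nm,
          truth = truth[[nm]], bias = mean(errs[, nm], na.rm = TRUE),
          rmse = sqrt(mean(errs[, nm]^2, na.rm = TRUE)),
          n_rep = as.integer(n_rep))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(cell = integer(0), length = integer(0),
                          parameter = character(0), truth = numeric(0),
                          bias = numeric(0), rmse = numeric(0),
                          n_rep = integer(0)))
  }
  do.call(rbind, rows)
}
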