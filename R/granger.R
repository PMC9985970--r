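# Granger causality between paired call-timing series.

#' Construct a paired focal/partner timing series
#'
#' @param focal,partner Equal-length numeric vectors of aligned values
#'   (onsets or IOIs).
#' @param mask Logical vector of the same length; `TRUE` marks positions
#'   whose predecessor lies in a different bout (regression rows whose lag
#'   window spans a masked position are dropped).
#' @param value_mode `"onsets"` or `"iois"`.
#' @param session_id,bout_id,level Bookkeeping labels.
#' @return List of class `"timing_series"`.
#' @export
timing_series <- function(focal, partner, mask = NULL,
                          value_mode = c("onsets", "iois"),
                          session_id = NA_character_, bout_id = NA_integer_,
                          level = c("bout", "session")) {
  value_mode <- match.arg(value_mode)
  level <- match.arg(level)
  if (length(focal) != length(partner)) {
    vr_stop("focal and partner series must have equal length", "vr_format_error")
  }
  if (is.null(mask)) mask <- rep(FALSE, length(focal))
  if (length(mask) != length(focal)) {
    vr_stop("mask length must match series length", "vr_format_error")
  }
  structure(
    list(focal = focal, partner = partner, mask = mask,
         value_mode = value_mode, session_id = session_id, bout_id = bout_id,
         level = level),
    class = "timing_series"
  )
}

#' Build paired timing series from an annotated session
#'
#' Within each bout, the n-th focal call is matched to the n-th partner call
#' (the longer sequence is trimmed), giving aligned value vectors in onset or
#' IOI mode. At the bout level, bouts with fewer than `min_pairs` paired
#' calls are excluded (recorded in the `"excluded"` attribute); at the
#' session level all bouts of a session are concatenated with the boundary
#' mask set at bout joins.
#'
#' @param calls Call annotation tibble with `bout_id` (see [segment_bouts()]).
#' @param focal_id,partner_id Caller identities.
#' @param value_mode `"onsets"` (default) or `"iois"`.
#' @param level `"session"` or `"bout"`.
#' @param min_pairs Minimum paired calls for a bout-level series.
#' @return List of `"timing_series"` objects; excluded bout-level series are
#'   listed in the attribute `"excluded"` (tibble of `bout_id`, `reason`).
#' @export
build_paired_series <- function(calls, focal_id, partner_id,
                                value_mode = c("onsets", "iois"),
                                level = c("session", "bout"),
                                min_pairs = 5) {
  value_mode <- match.arg(value_mode)
  level <- match.arg(level)
  if (!"bout_id" %in% names(calls)) {
    vr_stop("calls must carry a bout_id column; run segment_bouts() first",
            "vr_format_error")
  }
  calls <- calls[!is.na(calls$bout_id), , drop = FALSE]
  out <- list()
  excluded <- list()
  for (sid in unique(calls$session_id)) {
    sess <- calls[calls$session_id == sid, , drop = FALSE]
    seg_f <- list(); seg_p <- list(); seg_b <- integer(0)
    for (b in unique(sess$bout_id)) {
      bout <- sess[sess$bout_id == b, , drop = FALSE]
      f_on <- sort(bout$onset_s[bout$individual_id == focal_id])
      p_on <- sort(bout$onset_s[bout$individual_id == partner_id])
      k <- min(length(f_on), length(p_on))
      if (k == 0) next
      f_on <- f_on[seq_len(k)]; p_on <- p_on[seq_len(k)]
      if (value_mode == "iois") {
        if (k < 2) next
        fv <- diff(f_on); pv <- diff(p_on)
      } else {
        fv <- f_on; pv <- p_on
      }
      if (level == "bout") {
        if (k < min_pairs) {
          excluded[[length(excluded) + 1L]] <- tibble::tibble(
            session_id = sid, bout_id = b,
            reason = sprintf("fewer than %d paired calls", min_pairs))
          next
        }
        out[[length(out) + 1L]] <- timing_series(
          fv, pv, value_mode = value_mode, session_id = sid, bout_id = b,
          level = "bout")
      } else {
        seg_f[[length(seg_f) + 1L]] <- fv
        seg_p[[length(seg_p) + 1L]] <- pv
        seg_b <- c(seg_b, b)
      }
    }
    if (level == "session" && length(seg_f) > 0) {
      lens <- vapply(seg_f, length, 0L)
      mask <- unlist(lapply(lens, function(l) c(TRUE, rep(FALSE, l - 1))))
      mask[1] <- FALSE
      out[[length(out) + 1L]] <- timing_series(
        unlist(seg_f), unlist(seg_p), mask = mask, value_mode = value_mode,
        session_id = sid, level = "session")
    }
  }
  attr(out, "excluded") <- if (length(excluded) > 0) {
    do.call(rbind, excluded)
  } else {
    tibble::tibble(session_id = character(0), bout_id = integer(0),
                   reason = character(0))
  }
  out
}

# Rows of the lagged design at time t use positions t-lag .. t; a row is
# valid only when no bout join falls inside that window.
granger_design <- function(y, x, mask, lag) {
  n <- length(y)
  t_idx <- (lag + 1):n
  valid <- vapply(t_idx, function(t) !any(mask[(t - lag + 1):t]), TRUE)
  ylags <- sapply(seq_len(lag), function(k) y[t_idx - k])
  xlags <- sapply(seq_len(lag), function(k) x[t_idx - k])
  list(y = y[t_idx][valid],
       ylags = matrix(ylags, ncol = lag)[valid, , drop = FALSE],
       xlags = matrix(xlags, ncol = lag)[valid, , drop = FALSE])
}

#' Granger causality test on a paired timing series
#'
#' Fits, by ordinary least squares, a restricted autoregression of the
#' target series on its own `lag` previous values and an unrestricted model
#' adding the predictor series' `lag` previous values, and F-tests the joint
#' exclusion of the predictor lags. Regression rows whose lag window crosses
#' a bout boundary are dropped.
#'
#' @param series A `"timing_series"`.
#' @param lag Number of lags (1-5 in the standard scan).
#' @param direction `"partner_to_focal"` (does the partner's past predict the
#'   focal series?) or `"focal_to_partner"`.
#' @param min_obs_per_lag Minimum valid rows per lag (rule of thumb 4).
#' @return One-row tibble: `direction`, `lag`, `F`, `p_value`,
#'   `n_effective`, `level`, `session_id`, `bout_id`.
#' @export
granger_test <- function(series, lag,
                         direction = c("partner_to_focal", "focal_to_partner"),
                         min_obs_per_lag = 4) {
  direction <- match.arg(direction)
  if (direction == "partner_to_focal") {
    y <- series$focal; x <- series$partner
  } else {
    y <- series$partner; x <- series$focal
  }
  if (lag < 1) vr_stop("lag must be at least 1", "vr_config_error")
  if (length(y) <= lag) {
    vr_stop("series shorter than lag order", "vr_insufficient_data")
  }
  d <- granger_design(y, x, series$mask, lag)
  n_eff <- length(d$y)
  if (n_eff < lag * min_obs_per_lag) {
    vr_stop(sprintf("only %d effective observations for lag %d", n_eff, lag),
            "vr_insufficient_data")
  }
  if (sd(d$y) == 0 || any(apply(d$xlags, 2, sd) == 0)) {
    vr_stop("constant series: Granger regression is degenerate",
            "vr_degenerate")
  }
  X_r <- cbind(1, d$ylags)
  X_u <- cbind(X_r, d$xlags)
  fit_r <- stats::lm.fit(X_r, d$y)
  fit_u <- stats::lm.fit(X_u, d$y)
  if (fit_u$rank < ncol(X_u)) {
    vr_stop("singular design in unrestricted model", "vr_degenerate")
  }
  rss_r <- sum(fit_r$residuals^2)
  rss_u <- sum(fit_u$residuals^2)
  df2 <- n_eff - ncol(X_u)
  if (df2 < 1) vr_stop("not enough observations for the F test",
                       "vr_insufficient_data")
  if (rss_u <= .Machine$double.eps * max(1, rss_r)) {
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- ((rss_r - rss_u) / lag) / (rss_u / df2)
    p <- pf(Fstat, lag, df2, lower.tail = FALSE)
  }
  tibble::tibble(direction = direction, lag = as.integer(lag), F = Fstat,
                 p_value = p, n_effective = as.integer(n_eff),
                 level = series$level, session_id = series$session_id,
                 bout_id = series$bout_id, excluded_reason = NA_character_)
}

#' Scan Granger causality over lags and directions
#'
#' Runs [granger_test()] for every lag in `lags` and every requested
#' direction. Cells that fail their preconditions (too short, degenerate) are
#' returned with an `excluded_reason` instead of being dropped.
#'
#' @inheritParams granger_test
#' @param lags Integer vector of lag orders.
#' @param directions Directions to test; defaults to both (a two-way
#'   analysis). For one-way playback designs use
#'   `directions = "partner_to_focal"`.
#' @return Tibble with one row per direction x lag.
#' @export
granger_scan <- function(series, lags = 1:5,
                         directions = c("partner_to_focal", "focal_to_partner"),
                         min_obs_per_lag = 4) {
  rows <- list()
  for (dir in directions) {
    for (lag in lags) {
      row <- tryCatch(
        granger_test(series, lag, dir, min_obs_per_lag = min_obs_per_lag),
        vr_error = function(e) {
          tibble::tibble(direction = dir, lag = as.integer(lag), F = NA_real_,
                         p_value = NA_real_, n_effective = NA_integer_,
                         level = series$level, session_id = series$session_id,
                         bout_id = series$bout_id,
                         excluded_reason = conditionMessage(e))
        })
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
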