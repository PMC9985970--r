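# Categorical rhythm analysis: IOI ratios, small-integer-ratio binning,
# simulated null distributions, KS and Wilcoxon tests.

#' IOI ratios of adjacent intervals
#'
#' For each pair of adjacent inter-onset intervals `t_k`, `t_{k+1}` the ratio
#' is `r_k = t_k / (t_k + t_{k+1})`, so isochrony maps to 0.5 and
#' `r(t1, t2) + r(t2, t1) = 1`.
#'
#' @param iois Numeric vector of positive inter-onset intervals.
#' @return Numeric vector of length `length(iois) - 1` (empty when fewer
#'   than two IOIs are supplied), each value strictly in `(0, 1)`.
#' @export
#' @examples
#' compute_ratios(c(1, 1, 1))  # 0.5 0.5
#' compute_ratios(c(2, 1))     # 2/3
compute_ratios <- function(iois) {
  if (any(iois <= 0)) vr_stop("IOIs must be positive", "vr_format_error")
  n <- length(iois)
  if (n < 2) return(numeric(0))
  iois[-n] / (iois[-n] + iois[-1])
}

#' IOI ratios per bout for one caller or a pooled interaction
#'
#' Computes within-bout IOI ratios from a segmented annotation table. The
#' IOIs entering the ratios depend on `ioi_mode`: `"own"` uses only the focal
#' individual's onsets inside each bout (covering both the solitary contexts
#' and the disregard-the-partner analysis of interactive contexts), while
#' `"pooled"` uses all onsets in the bout regardless of caller (the
#' responding-to-partner analysis).
#'
#' @param calls Call annotation tibble with `bout_id` (see [segment_bouts()]).
#' @param ioi_mode `"own"` or `"pooled"`.
#' @param focal_id Individual whose calls define the IOIs in `"own"` mode.
#' @return Tibble with columns `bout_id` and `ratio`.
#' @export
compute_bout_ratios <- function(calls, ioi_mode = c("own", "pooled"),
                                focal_id = NULL) {
  ioi_mode <- match.arg(ioi_mode)
  if (!"bout_id" %in% names(calls)) {
    vr_stop("calls must carry a bout_id column; run segment_bouts() first",
            "vr_format_error")
  }
  if (ioi_mode == "own") {
    if (is.null(focal_id)) vr_stop("focal_id required in 'own' mode",
                                   "vr_config_error")
    calls <- calls[calls$individual_id == focal_id, , drop = FALSE]
  }
  calls <- calls[!is.na(calls$bout_id), , drop = FALSE]
  out <- lapply(split(calls$onset_s, calls$bout_id), function(on) {
    on <- sort(on)
    if (length(on) < 3) return(numeric(0))
    compute_ratios(diff(on))
  })
  tibble::tibble(
    bout_id = as.integer(rep(names(out), vapply(out, length, 0L))),
    ratio = unlist(out, use.names = FALSE)
  )
}

#' Small-integer-ratio bin geometry
#'
#' Builds the on-/off-integer binning used to look for categorical rhythms
#' at small integer ratios. Each SIR `a:b` sits at the ratio value
#' `a / (a + b)`; cell boundaries fall at midpoints between adjacent SIR
#' values (the outermost cells extended symmetrically), and within each cell
#' the on-integer bin is centred on the SIR value with width `on_fraction`
#' times the cell width, the remainder forming two flanking off-integer bins.
#'
#' @param sirs Character vector of `a:b` ratios, ordered by value.
#' @param on_fraction Fraction of each cell covered by the on-integer bin.
#' @return List of class `"sir_binning"` with a `bins` tibble (`label`,
#'   `value`, `cell_lo`, `cell_hi`, `on_lo`, `on_hi`) and `on_fraction`.
#' @export
build_sir_bins <- function(sirs = c("1:4", "1:3", "1:2", "1:1",
                                    "2:1", "3:1", "4:1"),
                           on_fraction = 0.5) {
  if (on_fraction <= 0 || on_fraction > 1) {
    vr_stop("on_fraction must be in (0, 1]", "vr_config_error")
  }
  parts <- strsplit(sirs, ":", fixed = TRUE)
  aa <- as.numeric(vapply(parts, `[[`, "", 1L))
  bb <- as.numeric(vapply(parts, `[[`, "", 2L))
  values <- aa / (aa + bb)
  if (is.unsorted(values, strictly = TRUE)) {
    vr_stop("sirs must be sorted by ratio value", "vr_config_error")
  }
  k <- length(values)
  mids <- (values[-k] + values[-1]) / 2
  cell_lo <- c(values[1] - (mids[1] - values[1]), mids)
  cell_hi <- c(mids, values[k] + (values[k] - mids[k - 1]))
  # the on-bin spans on_fraction of the cell on either side of the SIR
  # value; midpoint cells are not symmetric about their value, so a
  # proportional span (rather than a fixed half-width) keeps the bin inside
  # the cell, preserves total width on_fraction x cell width, and collapses
  # the off-bins exactly at on_fraction = 1
  on_lo <- values - on_fraction * (values - cell_lo)
  on_hi <- values + on_fraction * (cell_hi - values)
  structure(
    list(
      bins = tibble::tibble(label = sirs, value = values,
                            cell_lo = cell_lo, cell_hi = cell_hi,
                            on_lo = on_lo, on_hi = on_hi),
      on_fraction = on_fraction
    ),
    class = "sir_binning"
  )
}

#' Simulated null distribution of IOI ratios
#'
#' Generates the ratio distribution expected in the absence of rhythmic
#' categories: pairs of IOIs are drawn i.i.d. from a continuous law spanning
#' the observed IOI range (`"uniform"`, the default, draws from
#' `U(min(iois), max(iois))`; `"bootstrap"` resamples the empirical IOIs)
#' and the ratio of each pair is formed. The resulting ECDF is interpolated
#' so the null is continuous and fully specified, as a one-sample KS test
#' requires.
#'
#' @param iois Observed IOIs defining the generating range.
#' @param n_sim Number of simulated ratio pairs (at least 10^4).
#' @param seed Seed for the simulation.
#' @param method `"uniform"` or `"bootstrap"`.
#' @return List of class `"null_ratio_dist"` with `cdf` (a vectorized
#'   function), `range`, `n_sim`, `seed`, `method`.
#' @export
simulate_null_ratios <- function(iois, n_sim = 1e5, seed = 1,
                                 method = c("uniform", "bootstrap")) {
  method <- match.arg(method)
  if (n_sim < 1e4) vr_stop("n_sim must be at least 10^4", "vr_config_error")
  a <- min(iois); b <- max(iois)
  if (!is.finite(a) || a <= 0) vr_stop("IOIs must be positive", "vr_format_error")
  if (a == b) vr_stop("degenerate IOI range (min == max)", "vr_config_error")
  set.seed(seed)
  if (method == "uniform") {
    t1 <- runif(n_sim, a, b); t2 <- runif(n_sim, a, b)
  } else {
    t1 <- sample(iois, n_sim, replace = TRUE)
    t2 <- sample(iois, n_sim, replace = TRUE)
  }
  r <- sort(t1 / (t1 + t2))
  probs <- (seq_len(n_sim) - 0.5) / n_sim
  cdf <- approxfun(r, probs, yleft = 0, yright = 1, ties = "ordered")
  structure(
    list(cdf = cdf, range = c(a, b), n_sim = n_sim, seed = seed,
         method = method),
    class = "null_ratio_dist"
  )
}

#' One-sample KS test of empirical ratios against a simulated null
#'
#' @param ratios Numeric vector of empirical IOI ratios (at least 10, the
#'   well-sampled criterion).
#' @param null A `"null_ratio_dist"` from [simulate_null_ratios()].
#' @return One-row tibble with `statistic` (D), `p_value`, `n`.
#' @export
ks_against_null <- function(ratios, null) {
  if (length(ratios) < 10) {
    vr_stop("need at least 10 ratios for the KS test", "vr_insufficient_data")
  }
  res <- suppressWarnings(ks.test(ratios, null$cdf))
  tibble::tibble(test_name = "ks_one_sample",
                 statistic = unname(res$statistic),
                 p_value = res$p.value, n = length(ratios))
}

#' Paired Wilcoxon test for a peak at one small integer ratio
#'
#' For each bout, the density of ratios inside the on-integer bin of the
#' chosen SIR (count normalized by bin width) is paired with the density over
#' the two flanking off-integer bins; a two-sided paired Wilcoxon signed-rank
#' test asks whether on-integer density exceeds off-integer density across
#' bouts.
#'
#' @param bout_ratios Tibble with `bout_id` and `ratio` columns (see
#'   [compute_bout_ratios()]); at least 6 bouts with a ratio each.
#' @param binning A `"sir_binning"` from [build_sir_bins()].
#' @param sir Label of the ratio to test, e.g. `"1:1"`.
#' @return One-row tibble with the Wilcoxon `statistic` (V), `p_value`,
#'   `n` (bouts) and a `degenerate` flag set when all paired differences are
#'   zero.
#' @export
sir_peak_test <- function(bout_ratios, binning, sir = "1:1") {
  bins <- binning$bins
  row <- bins[bins$label == sir, , drop = FALSE]
  if (nrow(row) != 1) vr_stop(sprintf("unknown SIR label: %s", sir),
                              "vr_config_error")
  groups <- split(bout_ratios$ratio, bout_ratios$bout_id)
  groups <- groups[vapply(groups, length, 0L) >= 1]
  if (length(groups) < 6) {
    vr_stop("need at least 6 bouts with ratios", "vr_insufficient_data")
  }
  on_w <- row$on_hi - row$on_lo
  off_w <- (row$on_lo - row$cell_lo) + (row$cell_hi - row$on_hi)
  on_d <- vapply(groups, function(r) {
    sum(r > row$on_lo & r <= row$on_hi) / on_w
  }, 0)
  off_d <- vapply(groups, function(r) {
    cnt <- sum((r > row$cell_lo & r <= row$on_lo) |
                 (r > row$on_hi & r <= row$cell_hi))
    if (off_w == 0) 0 else cnt / off_w
  }, 0)
  if (all(on_d == off_d)) {
    return(tibble::tibble(test_name = "sir_peak_wilcoxon", sir = sir,
                          statistic = NA_real_, p_value = NA_real_,
                          n = length(groups), degenerate = TRUE))
  }
  res <- suppressWarnings(wilcox.test(on_d, off_d, paired = TRUE))
  tibble::tibble(test_name = "sir_peak_wilcoxon", sir = sir,
                 statistic = unname(res$statistic), p_value = res$p.value,
                 n = length(groups), degenerate = FALSE)
}

#' Two-sample KS comparison of ratio distributions
#'
#' Compares the IOI-ratio distributions of one individual across two
#' behavioural contexts (or of two individuals).
#'
#' @param a,b Numeric ratio vectors, each with at least 10 values.
#' @return One-row tibble with `statistic` (D), `p_value`, `n`, `n2`.
#' @export
compare_ratio_distributions <- function(a, b) {
  if (length(a) < 10 || length(b) < 10) {
    vr_stop("need at least 10 ratios in each sample", "vr_insufficient_data")
  }
  res <- suppressWarnings(ks.test(a, b))
  tibble::tibble(test_name = "ks_two_sample", statistic = unname(res$statistic),
                 p_value = res$p.value, n = length(a), n2 = length(b))
}

#' Plot-ready export of a ratio distribution against its null
#'
#' Evaluates the empirical and null ratio densities on a common grid,
#' together with the SIR bin edges, for external plotting.
#'
#' @param ratios Numeric vector of empirical ratios.
#' @param null A `"null_ratio_dist"`.
#' @param binning A `"sir_binning"`.
#' @param n_grid Grid resolution.
#' @return List with tibbles `density` (`ratio`, `empirical`, `null`) and
#'   `bins` (the binning geometry).
#' @export
ratio_density_export <- function(ratios, null, binning, n_grid = 512) {
  grid <- seq(0, 1, length.out = n_grid)
  emp <- stats::density(ratios, from = 0, to = 1, n = n_grid)$y
  h <- grid[2] - grid[1]
  null_cdf <- null$cdf(grid)
  null_dens <- c(diff(null_cdf) / h, 0)
  list(
    density = tibble::tibble(ratio = grid, empirical = emp, null = null_dens),
    bins = binning$bins
  )
}
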