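test_that("IOI ratios follow r = t_k / (t_k + t_{k+1})", {
  expect_equal(compute_ratios(c(1, 1, 1)), c(0.5, 0.5))
  expect_equal(compute_ratios(c(2, 1)), 2 / 3)
  expect_equal(compute_ratios(c(1, 3)), 0.25)
  expect_equal(compute_ratios(2), numeric(0))
  expect_error(compute_ratios(c(1, -1)), class = "vr_format_error")
})

test_that("ratio complement and tempo invariance hold", {
  set.seed(41)
  t1 <- runif(50, 0.1, 5); t2 <- runif(50, 0.1, 5)
  expect_equal(t1 / (t1 + t2) + t2 / (t2 + t1), rep(1, 50))
  # isochronous sequences give 0.5 at any tempo
  for (tempo in c(0.3, 1, 7)) {
    expect_equal(compute_ratios(rep(tempo, 6)), rep(0.5, 5))
  }
})

test_that("per-bout ratios restrict to the focal caller in 'own' mode", {
  duet <- make_duet(seq(0, by = 2, length.out = 8))
  duet$bout_id <- 1L
  own <- compute_bout_ratios(duet, "own", focal_id = "F")
  expect_equal(own$ratio, rep(0.5, 6))  # responder inherits isochrony
  pooled <- compute_bout_ratios(duet, "pooled")
  expect_gt(nrow(pooled), nrow(own))
  expect_error(compute_bout_ratios(duet, "own"), class = "vr_config_error")
})

test_that("SIR binning places cells and on-bins at midpoint geometry", {
  b <- build_sir_bins()
  expect_equal(b$bins$value, c(0.2, 0.25, 1 / 3, 0.5, 2 / 3, 0.75, 0.8))
  r <- b$bins[b$bins$label == "1:1", ]
  expect_equal(r$cell_lo, 5 / 12)
  expect_equal(r$cell_hi, 7 / 12)
  expect_equal(r$on_lo, 0.5 - 1 / 24)
  expect_equal(r$on_hi, 0.5 + 1 / 24)

  # partition: cells tile the covered span, on/off widths sum to cell width
  expect_equal(b$bins$cell_lo[-1], b$bins$cell_hi[-7])
  on_w <- b$bins$on_hi - b$bins$on_lo
  off_w <- (b$bins$on_lo - b$bins$cell_lo) + (b$bins$cell_hi - b$bins$on_hi)
  expect_equal(on_w + off_w, b$bins$cell_hi - b$bins$cell_lo)

  # on_fraction -> 1 collapses the off-bins
  b1 <- build_sir_bins(on_fraction = 1)
  expect_equal(b1$bins$on_lo, b1$bins$cell_lo)
  expect_equal(b1$bins$on_hi, b1$bins$cell_hi)
})

test_that("simulated null ratio ECDF is symmetric, supported on the ratio
           bounds and matches the analytic CDF for unit-uniform IOIs", {
  null <- simulate_null_ratios(c(1, 3), n_sim = 2e4, seed = 7)
  g <- seq(0.05, 0.95, by = 0.01)
  expect_lt(max(abs(null$cdf(g) + null$cdf(1 - g) - 1)), 0.01)
  # support bound for U(a, b): ratios live in [a/(a+b), b/(a+b)]
  expect_equal(null$cdf(1 / 4 - 1e-9), 0)
  expect_equal(null$cdf(3 / 4 + 1e-9), 1)

  # near-U(0,1) generator against the analytic law
  null01 <- simulate_null_ratios(c(1e-9, 1), n_sim = 5e4, seed = 8)
  analytic <- function(r) ifelse(r <= 0.5, r / (2 * (1 - r)),
                                 1 - (1 - r) / (2 * r))
  expect_lt(max(abs(null01$cdf(g) - analytic(g))), 0.015)

  expect_error(simulate_null_ratios(c(2, 2)), class = "vr_config_error")
  expect_error(simulate_null_ratios(c(1, 2), n_sim = 100),
               class = "vr_config_error")
})

test_that("one-sample KS against the null has its D at the analytic median
           for degenerate isochronous ratios", {
  null01 <- simulate_null_ratios(c(1e-9, 1), n_sim = 5e4, seed = 9)
  res <- ks_against_null(rep(0.5, 20), null01)
  expect_equal(res$statistic, 0.5, tolerance = 0.01)
  expect_lt(res$p_value, 0.01)
  expect_error(ks_against_null(rep(0.5, 5), null01),
               class = "vr_insufficient_data")
})

test_that("SIR peak test flags concentration at 1:1 and needs 6 bouts", {
  binning <- build_sir_bins()
  conc <- tibble::tibble(bout_id = rep(1:10, each = 3),
                         ratio = rep(0.5, 30))
  res <- sir_peak_test(conc, binning, "1:1")
  expect_lt(res$p_value, 0.05)
  expect_false(res$degenerate)

  few <- tibble::tibble(bout_id = rep(1:5, each = 3), ratio = rep(0.5, 15))
  expect_error(sir_peak_test(few, binning, "1:1"),
               class = "vr_insufficient_data")

  # ratios outside the 1:1 cell entirely -> all paired differences zero
  off <- tibble::tibble(bout_id = rep(1:8, each = 2), ratio = rep(0.21, 16))
  expect_true(sir_peak_test(off, binning, "1:1")$degenerate)
})

test_that("two-sample ratio comparison separates distinct peaks and is inert
           on identical samples", {
  set.seed(43)
  a <- rnorm(30, 0.5, 0.01)
  b <- rnorm(30, 0.75, 0.01)
  expect_lt(compare_ratio_distributions(a, b)$p_value, 0.001)
  same <- compare_ratio_distributions(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_ratio_distributions(a[1:5], b),
               class = "vr_insufficient_data")
})

test_that("density export grids empirical and null densities with bin edges", {
  set.seed(47)
  null <- simulate_null_ratios(c(1, 2), n_sim = 1e4, seed = 3)
  out <- ratio_density_export(runif(50, 0.3, 0.7), null, build_sir_bins(),
                              n_grid = 128)
  expect_equal(nrow(out$density), 128)
  expect_equal(names(out$density), c("ratio", "empirical", "null"))
  expect_equal(nrow(out$bins), 7)
})
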