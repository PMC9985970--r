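iso_partner <- function(n, period = 2) seq(0, by = period, length.out = n)

test_that("parameter bounds are enforced at construction", {
  expect_s3_class(adam_params(alpha = -1.5, beta = 2, m = -3, gamma = 2),
                  "adam_params")
  expect_error(adam_params(alpha = 2.5), class = "vr_param_error")
  expect_error(adam_params(gamma = -0.1), class = "vr_param_error")
  expect_error(adam_params(sigma = -1), class = "vr_param_error")
})

test_that("noiseless adaptation follows the closed-form asynchrony recurrence", {
  p <- iso_partner(20)

  # alpha = 1 cancels the asynchrony after one step
  f1 <- adam_simulate(adam_params(alpha = 1), p, initial_asynchrony = 0.4)
  expect_equal((f1 - p)[-1], rep(0, 19))

  # zero gains: the initial asynchrony persists
  f0 <- adam_simulate(adam_params(), p, initial_asynchrony = 0.4)
  expect_equal(f0 - p, rep(0.4, 20))

  # geometric decay A_{n+1} = (1 - alpha) A_n, to machine precision
  f <- adam_simulate(adam_params(alpha = 0.5), p, initial_asynchrony = 0.4)
  expect_equal(f - p, 0.4 * 0.5^(0:19))

  expect_error(adam_simulate(adam_params(), p[1:2]),
               class = "vr_insufficient_data")
})

test_that("the joint model nests period-only adaptation at gamma = 0 and
           pure tracking at m = 0", {
  set.seed(83)
  p <- cumsum(c(0, runif(30, 1.5, 2.5)))
  fj <- adam_simulate(adam_params(beta = 0.3, m = 0.5, gamma = 0,
                                  version = "joint"), p, 0.3)
  fa <- adam_simulate(adam_params(alpha = 0, beta = 0.3), p, 0.3)
  expect_equal(fj, fa)

  # with m = 0 the predicted interval is the last partner interval
  f_track <- adam_simulate(adam_params(beta = 0, m = 0, gamma = 1,
                                       version = "joint"), p, 0.3)
  S <- diff(p)
  expect_equal(f_track[3:31], p[2:30] + S[1:29])
})

test_that("concatenated bouts carry one masked join per boundary and fit as
           well as an unbroken series", {
  p1 <- iso_partner(6); p2 <- iso_partner(8)
  s <- concatenate_bouts(list(timing_series(p1 + 0.1, p1),
                              timing_series(p2 + 0.1, p2)))
  expect_length(s$focal, 14)
  expect_equal(which(s$mask), 7L)
  expect_error(concatenate_bouts(list()), class = "vr_insufficient_data")

  pars <- adam_params(alpha = 0.4, beta = 0.1)
  pA <- iso_partner(15); pB <- iso_partner(15) + 100
  fA <- adam_simulate(pars, pA, 0.3)
  fB <- adam_simulate(pars, pB, 0.3)
  concat_fit <- fit_adam(concatenate_bouts(list(timing_series(fA, pA),
                                                timing_series(fB, pB))),
                         "adaptation_only")
  whole <- fit_adam(timing_series(adam_simulate(pars, iso_partner(30), 0.3),
                                  iso_partner(30)), "adaptation_only")
  expect_lt(abs(concat_fit$sse - whole$sse), 1e-8)
  expect_equal(unname(concat_fit$estimates), c(0.4, 0.1), tolerance = 1e-6)
})

test_that("noiseless fits recover generating parameters within 1e-4", {
  set.seed(89)
  p <- cumsum(c(0, runif(59, 1.5, 2.5)))
  f <- adam_simulate(adam_params(alpha = 0.5, beta = 0.2), p, 0.5)
  fit <- fit_adam(timing_series(f, p), "adaptation_only")
  expect_equal(unname(fit$estimates), c(0.5, 0.2), tolerance = 1e-4)

  fj <- adam_simulate(adam_params(beta = 0.15, m = 0.6, gamma = 0.5,
                                  version = "joint"), p, 0.5)
  fitj <- fit_adam(timing_series(fj, p), "joint")
  expect_equal(unname(fitj$estimates), c(0.15, 0.6, 0.5), tolerance = 1e-4)
})

test_that("the analytic adaptation fit agrees with the generic bounded
           optimiser", {
  set.seed(97)
  p <- cumsum(c(0, runif(49, 1.5, 2.5)))
  f <- adam_simulate(adam_params(alpha = 0.6, beta = 0.1, sigma = 0.1), p,
                     0.5, seed = 5)
  d <- vocalrhythm:::adam_design(f, p, rep(FALSE, 50))
  ols <- vocalrhythm:::fit_adaptation_ols(d)
  obj <- function(theta) {
    par <- c(alpha = theta[1], beta = theta[2], m = 0, gamma = 0)
    sum((d$f_next - vocalrhythm:::adam_predict_design(
      par, "adaptation_only", d))^2)
  }
  opt <- optim(c(0, 0), obj, method = "L-BFGS-B", lower = c(-2, -2),
               upper = c(2, 2), control = list(factr = 1e1))
  expect_equal(ols, unname(opt$par), tolerance = 1e-5)
})

test_that("fits are reproducible and insufficient data is refused", {
  set.seed(101)
  p <- cumsum(c(0, runif(39, 1.5, 2.5)))
  f <- adam_simulate(adam_params(beta = 0.2, m = 0.4, gamma = 0.3,
                                 version = "joint", sigma = 0.05), p, 0.4,
                     seed = 11)
  s <- timing_series(f, p)
  fit1 <- fit_adam(s, "joint", seed = 7)
  fit2 <- fit_adam(s, "joint", seed = 7)
  expect_identical(fit1$estimates, fit2$estimates)

  short <- timing_series(f[1:8], p[1:8])
  expect_error(fit_adam(short, "adaptation_only"),
               class = "vr_insufficient_data")
})

test_that("permutation envelopes flag strong coupling and refuse tiny
           replicate counts", {
  set.seed(103)
  p <- cumsum(c(0, runif(59, 1.5, 2.5)))
  f <- adam_simulate(adam_params(alpha = 0.8, sigma = 0.1), p, 0.5, seed = 3)
  s <- timing_series(f, p)
  expect_error(adam_permutation_test(s, "adaptation_only", n_perm = 50),
               class = "vr_config_error")
  pt <- adam_permutation_test(s, "adaptation_only", n_perm = 200, seed = 5)
  expect_equal(pt$fit$flags[["alpha"]], "two_tailed")
  expect_true(all(diff(unlist(pt$envelope[1, -1])) >= 0))  # ordered percentiles
})

test_that("recovery study reports near-zero bias without noise and returns
           an empty table for an empty grid", {
  expect_equal(nrow(adam_recovery_study(list(), c(30))), 0)
  tab <- adam_recovery_study(list(adam_params(alpha = 0.4, beta = 0.1)),
                             lengths = c(30, 60), n_rep = 3, seed = 2)
  expect_equal(nrow(tab), 4)  # 2 lengths x 2 parameters
  expect_true(all(abs(tab$bias) < 1e-6))
  expect_true(all(tab$rmse < 1e-6))
})
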