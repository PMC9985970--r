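test_that("config validation rejects impossible settings", {
  expect_error(sim_config(context = "chorus"), class = "vr_config_error")
  expect_error(sim_config(bout_size = c(2, 10)), class = "vr_config_error")
  expect_error(sim_config(inter_bout_gap = 2, partner_period = 2),
               class = "vr_config_error")
})

test_that("partner sequences honour tempo, jitter and reproducibility", {
  cfg <- sim_config(context = "one_way", partner_jitter = 0, seed = 5)
  p <- gen_partner_sequence(cfg)
  # jitter 0: within-bout IOIs all equal the period
  for (b in unique(p$true_bout)) {
    on <- sort(p$onset_s[p$true_bout == b])
    expect_equal(diff(on), rep(cfg$partner_period, length(on) - 1))
  }
  expect_true(all(p$role == "playback"))

  # same seed, same output
  expect_identical(gen_partner_sequence(cfg), p)

  # session sizes within the configured range
  n_by_session <- table(p$session_id)
  expect_true(all(n_by_session >= 34 & n_by_session <= 121))
})

test_that("segmenting a generated partner stream recovers the configured
           bouts", {
  cfg <- sim_config(context = "one_way", partner_jitter = 0.05, seed = 7)
  p <- gen_partner_sequence(cfg)
  seg <- segment_bouts(p)
  got <- seg$bout_id[!is.na(seg$bout_id)]
  expect_equal(length(unique(got)), length(unique(p$true_bout)))
  # and membership matches the generating bouts exactly
  expect_equal(as.vector(tapply(seg$true_bout, seg$bout_id, function(x)
    length(unique(x)))), rep(1, length(unique(got))))
})

test_that("a noiseless quarter-phase responder places every phase at 90
           degrees", {
  cfg <- sim_config(context = "one_way", partner_jitter = 0, seed = 11,
                    responder_params = list(fraction = 0.25, noise = 0))
  p <- gen_partner_sequence(cfg)
  f <- gen_responder(p, cfg)
  both <- rbind(p, f); both$true_bout <- NULL
  seg <- segment_bouts(both, ici_scope = "per_individual")
  ph <- response_phases(seg, cfg$focal_id, cfg$partner_id)
  expect_gt(nrow(ph), 10)
  expect_equal(ph$angle_deg, rep(90, nrow(ph)))
})

test_that("a uniform-random responder produces uniform response phases", {
  rej <- 0
  for (i in 1:20) {
    cfg <- sim_config(context = "one_way", partner_jitter = 0, seed = 100 + i,
                      responder_model = "uniform_random",
                      pairs_per_session = c(60, 80))
    p <- gen_partner_sequence(cfg)
    f <- gen_responder(p, cfg)
    both <- rbind(p, f); both$true_bout <- NULL
    seg <- segment_bouts(both, ici_scope = "per_individual")
    ph <- response_phases(seg, cfg$focal_id, cfg$partner_id)
    if (rayleigh_test(ph$angle_deg)$p_value < 0.05) rej <- rej + 1
  }
  expect_lte(rej, 4)  # about the nominal rate, far from systematic rejection
})

test_that("an ADAM responder is detected by lag-1 Granger causality", {
  hits <- 0
  for (i in 1:10) {
    cfg <- sim_config(context = "one_way", partner_jitter = 0.15,
                      seed = 200 + i, pairs_per_session = c(60, 61),
                      bout_size = c(15, 20),
                      responder_model = "adam",
                      responder_params = list(
                        adam = adam_params(alpha = 0.8, sigma = 0.05)))
    p <- gen_partner_sequence(cfg)
    f <- gen_responder(p, cfg)
    both <- rbind(p, f); both$true_bout <- NULL
    seg <- segment_bouts(both, ici_scope = "per_individual")
    series <- build_paired_series(seg, cfg$focal_id, cfg$partner_id,
                                  level = "session")
    res <- granger_test(series[[1]], 1, "partner_to_focal")
    if (res$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("coupled pairs are reproducible, interleaved and degenerate only
           when warned", {
  cfg <- sim_config(context = "two_way", partner_id = "A", focal_id = "B",
                    seed = 13)
  pars <- adam_params(alpha = 0.5, beta = 0.1, sigma = 0.08)
  x <- gen_coupled_pair(pars, pars, cfg)
  expect_identical(gen_coupled_pair(pars, pars, cfg), x)
  expect_setequal(unique(x$individual_id), c("A", "B"))
  expect_warning(gen_coupled_pair(adam_params(), adam_params(), cfg),
                 "degenerate")
})

test_that("one-way coupling is detected in the adapting direction only", {
  cfg <- sim_config(context = "two_way", partner_id = "A", focal_id = "B",
                    pairs_per_session = c(80, 100), seed = 17)
  # B adapts to A; A ignores B
  x <- gen_coupled_pair(adam_params(sigma = 0.15),
                        adam_params(alpha = 0.7, sigma = 0.05), cfg)
  seg <- segment_bouts(x, ici_scope = "per_individual")
  series <- build_paired_series(seg, "B", "A", level = "session")
  tab <- granger_scan(series[[1]], lags = 1)
  p_a_to_b <- tab$p_value[tab$direction == "partner_to_focal"]
  p_b_to_a <- tab$p_value[tab$direction == "focal_to_partner"]
  expect_lt(p_a_to_b, 0.01)
  expect_gt(p_b_to_a, 0.01)
})

test_that("gen_dataset writes a readable four-context file with a faithful
           manifest", {
  path <- withr::local_tempfile(fileext = ".csv")
  configs <- default_study_configs(3)
  out <- gen_dataset(configs, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".manifest.json")))
  back <- read_call_annotations(path)
  expect_setequal(unique(back$context),
                  c("alone", "silent_partner", "one_way", "two_way"))
  manifest <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(manifest$configs$one_way$seed, configs$one_way$seed)
  expect_equal(manifest$coupling$a$alpha, 0.5)
})
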