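test_that("interval metrics follow the onset/offset definitions", {
  m <- interval_metrics(make_calls(c(0, 2, 5), durations = c(0.5, 0.6, 0.5)))
  expect_equal(m$iois, c(2, 3))
  expect_equal(m$icis, c(1.5, 2.4))
  expect_equal(m$durations, c(0.5, 0.6, 0.5))
  expect_equal(m$iois, m$icis + m$durations[-3])

  m2 <- interval_metrics(make_calls(c(0, 1), durations = 0.4))
  expect_equal(m2$iois, 1)
  expect_equal(m2$icis, 0.6)

  expect_error(interval_metrics(make_calls(0)), class = "vr_insufficient_data")
  expect_error(interval_metrics(make_calls(c(0, 0), durations = 0.4)),
               "nonpositive", class = "vr_format_error")
})

test_that("bout segmentation splits at gaps over 1.5x the median ICI and
           discards short runs", {
  # two clean bouts of three
  b <- segment_bouts(make_calls(c(0, 1, 2, 10, 11, 12)))
  expect_equal(b$bout_id, c(1L, 1L, 1L, 2L, 2L, 2L))

  # leading run of two is discarded, not returned
  b2 <- segment_bouts(make_calls(c(0, 1, 8, 9, 10)))
  expect_equal(b2$bout_id, c(NA, NA, 1L, 1L, 1L))

  # equal gaps never exceed 1.5x their own median: one bout
  b3 <- segment_bouts(make_calls(seq(0, 18, by = 2)))
  expect_equal(unique(b3$bout_id), 1L)

  expect_error(segment_bouts(make_calls(numeric(0))),
               class = "vr_insufficient_data")
})

test_that("returned bouts satisfy the gap rule on re-scan", {
  set.seed(5)
  for (rep in 1:10) {
    onsets <- sort(runif(60, 0, 300))
    onsets <- onsets[c(TRUE, diff(onsets) > 0.45)]  # enforce positive ICIs
    calls <- make_calls(onsets, durations = 0.4)
    seg <- segment_bouts(calls)
    thr <- attr(seg, "bout_threshold")[["s1"]]
    for (b in unique(na.omit(seg$bout_id))) {
      bout <- seg[!is.na(seg$bout_id) & seg$bout_id == b, ]
      expect_gte(nrow(bout), 3)
      if (nrow(bout) > 1) {
        icis <- bout$onset_s[-1] - bout$offset_s[-nrow(bout)]
        expect_true(all(icis <= thr))
      }
    }
  }
})

test_that("vocal interactions use the two most recent partner onsets", {
  duet <- make_duet(c(0, 2, 4))
  duet$bout_id <- 1L
  ix <- extract_interactions(duet, "F", "P")
  expect_equal(nrow(ix), 2)
  expect_equal(ix$partner_first_onset, c(0, 2))
  expect_equal(ix$partner_second_onset, c(2, 4))
  expect_equal(ix$focal_onset, c(2.5, 4.5))

  # a focal call before two partner calls contributes nothing
  early <- rbind(make_calls(0.2, individual = "F"),
                 make_calls(c(1, 2), individual = "P", role = "partner"))
  early$bout_id <- 1L
  expect_equal(nrow(extract_interactions(early, "F", "P")), 0)
})

test_that("response phase is the response IOI over the partner IOI x 360,
           wrapped with winding", {
  ix <- tibble::tibble(bout_id = 1L, partner_first_onset = c(0, 0, 0),
                       partner_second_onset = 2,
                       focal_onset = c(2.5, 3.0, 4.6))
  ph <- response_phase(ix)
  expect_equal(ph$angle_deg, c(90, 180, 108))
  expect_equal(ph$winding, c(0L, 0L, 1L))

  # wrap off: responses later than one period are discarded
  ph2 <- response_phase(ix, wrap = FALSE)
  expect_equal(ph2$angle_deg, c(90, 180, NA))

  bad <- tibble::tibble(bout_id = 1L, partner_first_onset = 2,
                        partner_second_onset = 2, focal_onset = 3)
  expect_error(response_phase(bad), class = "vr_format_error")
})

test_that("response phase is invariant to rescaling all onsets", {
  set.seed(9)
  p <- cumsum(runif(10, 1, 3))
  ix <- tibble::tibble(bout_id = 1L, partner_first_onset = p[1:8],
                       partner_second_onset = p[2:9],
                       focal_onset = p[2:9] + runif(8, 0.1, 4))
  ph1 <- response_phase(ix)
  for (c_scale in c(0.25, 3, 17)) {
    ix2 <- ix
    ix2[2:4] <- ix[2:4] * c_scale
    ph2 <- response_phase(ix2)
    expect_equal(ph2$angle_deg, ph1$angle_deg, tolerance = 1e-9)
    expect_equal(ph2$winding, ph1$winding)
  }
})

test_that("a quarter-period responder yields 90-degree phases and mean 90", {
  duet <- make_duet(seq(0, by = 2, length.out = 20), fraction = 0.25)
  seg <- segment_bouts(duet, ici_scope = "per_individual")
  ph <- response_phases(seg, "F", "P")
  expect_gt(nrow(ph), 0)
  expect_equal(ph$angle_deg, rep(90, nrow(ph)))
  expect_equal(circular_summary(ph$angle_deg)$mu, 90)
})

test_that("self-referential phases mirror the interactive formula on own IOIs", {
  expect_equal(self_referential_phases(c(0, 2, 4)),
               tibble::tibble(angle_deg = 0, winding = 1L))
  expect_equal(self_referential_phases(c(0, 2, 3))$angle_deg, 180)
  expect_equal(self_referential_phases(c(0, 1, 4)),
               tibble::tibble(angle_deg = 0, winding = 3L))
  expect_equal(nrow(self_referential_phases(c(0, 2))), 0)
})
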