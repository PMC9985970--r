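# Synthetic call-sequence generators with known coupling structure, used to
# validate the full analysis pipeline without any field recordings.

#' Configuration for a synthetic call dataset
#'
#' Describes one behavioural context worth of synthetic sessions: how many
#' sessions, how many paired calls per session, how the calls group into
#' bouts, the partner's tempo and jitter, and how the focal animal responds.
#'
#' @param context One of `"alone"`, `"silent_partner"`, `"one_way"`,
#'   `"two_way"`.
#' @param n_sessions Number of recording sessions to generate.
#' @param pairs_per_session Integer range of calls per caller and session;
#'   the default 34-121 matches the span of paired calls per session in the
#'   study design this generator emulates.
#' @param bout_size Integer range of calls per bout (default 5-20).
#' @param partner_period Partner inter-onset interval in seconds.
#' @param partner_jitter Multiplicative jitter on partner intervals
#'   (standard deviation as a fraction of the period; truncated so intervals
#'   stay positive).
#' @param call_duration Range of call durations in seconds.
#' @param responder_model `"quarter_phase"`, `"adam"` or `"uniform_random"`.
#' @param responder_params List of responder settings: `fraction` and
#'   `noise` (seconds) for `quarter_phase`; an [adam_params()] object under
#'   `adam` plus optional `initial_asynchrony`; none for `uniform_random`.
#' @param inter_bout_gap Silent gap between bouts in seconds; must exceed
#'   1.5 times the partner period so that the bout segmentation rule
#'   recovers the generated bouts.
#' @param focal_id,partner_id Individual identifiers written to the
#'   annotations.
#' @param seed Seed; mandatory for reproducibility.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(context = "two_way", n_sessions = 1,
                       pairs_per_session = c(34, 121),
                       bout_size = c(5, 20), partner_period = 2,
                       partner_jitter = 0.05, call_duration = c(0.3, 1.0),
                       responder_model = c("quarter_phase", "adam",
                                           "uniform_random"),
                       responder_params = list(fraction = 0.25, noise = 0),
                       inter_bout_gap = 10, focal_id = "focal1",
                       partner_id = "partner1", seed = 1) {
  responder_model <- match.arg(responder_model)
  if (!context %in% CONTEXTS) {
    vr_stop(sprintf("unknown context: %s", context), "vr_config_error")
  }
  stopifnot(length(pairs_per_session) == 2, length(bout_size) == 2,
            length(call_duration) == 2)
  if (pairs_per_session[1] > pairs_per_session[2] || pairs_per_session[1] < 1 ||
      bout_size[1] > bout_size[2] || bout_size[1] < 3 ||
      call_duration[1] > call_duration[2] || call_duration[1] <= 0) {
    vr_stop("ranges must be positive and ordered", "vr_config_error")
  }
  if (partner_period <= 0 || partner_jitter < 0) {
    vr_stop("partner period must be positive and jitter non-negative",
            "vr_config_error")
  }
  if (inter_bout_gap <= 1.5 * partner_period) {
    vr_stop("inter_bout_gap must exceed 1.5 x partner_period, or generated
bouts would not survive the segmentation rule", "vr_config_error")
  }
  if (is.null(seed)) vr_stop("seed is mandatory", "vr_config_error")
  structure(
    list(context = context, n_sessions = n_sessions,
         pairs_per_session = as.integer(pairs_per_session),
         bout_size = as.integer(bout_size), partner_period = partner_period,
         partner_jitter = partner_jitter, call_duration = call_duration,
         responder_model = responder_model,
         responder_params = responder_params,
         inter_bout_gap = inter_bout_gap, focal_id = focal_id,
         partner_id = partner_id, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Positive multiplicative jitter factors: truncated normal around 1.
jitter_factors <- function(n, sd) {
  if (sd == 0) return(rep(1, n))
  pmax(rnorm(n, 1, sd), 0.1)
}

# Draw bout sizes until their sum reaches the session target.
draw_bout_sizes <- function(target, range) {
  sizes <- integer(0)
  while (sum(sizes) < target) {
    sizes <- c(sizes, sample(range[1]:range[2], 1))
  }
  excess <- sum(sizes) - target
  if (excess > 0 && sizes[length(sizes)] - excess >= range[1]) {
    sizes[length(sizes)] <- sizes[length(sizes)] - excess
  }
  sizes
}

#' Generate a bout-structured partner (or solitary) call sequence
#'
#' Produces the stimulus stream of a synthetic session: onsets grouped into
#' bouts of the configured size, with intervals equal to the partner period
#' times a multiplicative jitter factor, and inter-bout gaps long enough to
#' survive the segmentation rule. In the non-interactive contexts the same
#' machinery generates the focal animal's own solitary calling.
#'
#' @param config A [sim_config()].
#' @return Call annotation tibble (role `"playback"` in the one-way context,
#'   `"partner"` otherwise; the caller is `config$partner_id`). The true
#'   bout index of every call is recorded in the `true_bout` column.
#' @export
gen_partner_sequence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "partner"))
  role <- if (config$context == "one_way") "playback" else "partner"
  rows <- list()
  for (s in seq_len(config$n_sessions)) {
    n_calls <- sample(config$pairs_per_session[1]:config$pairs_per_session[2], 1)
    sizes <- draw_bout_sizes(n_calls, config$bout_size)
    t0 <- 0
    for (b in seq_along(sizes)) {
      iois <- config$partner_period *
        jitter_factors(sizes[b] - 1, config$partner_jitter)
      onsets <- t0 + cumsum(c(0, iois))
      durations <- runif(sizes[b], config$call_duration[1],
                         config$call_duration[2])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        session_id = sprintf("session%02d", s), context = config$context,
        individual_id = config$partner_id, role = role,
        onset_s = onsets, offset_s = onsets + durations,
        true_bout = b
      )
      t0 <- max(onsets) + config$inter_bout_gap
    }
  }
  do.call(rbind, rows)
}

#' Generate focal responses to a partner sequence
#'
#' Adds a responding caller to a partner stream, bout by bout.
#' `"quarter_phase"` places each response at a fixed fraction of the current
#' partner interval after the partner onset (plus optional Gaussian noise in
#' seconds) — the regime in which responses cluster at 90 degrees;
#' `"adam"` simulates an [adam_params()]-governed agent with
#' [adam_simulate()]; `"uniform_random"` scatters one response uniformly
#' over each partner interval.
#'
#' @param partner_calls Annotations from [gen_partner_sequence()] (must
#'   carry `true_bout`).
#' @param config The same [sim_config()] used for the partner stream.
#' @return Call annotation tibble for the focal individual.
#' @export
gen_responder <- function(partner_calls, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!"true_bout" %in% names(partner_calls) || nrow(partner_calls) == 0) {
    vr_stop("partner_calls must come from gen_partner_sequence()",
            "vr_config_error")
  }
  set.seed(derive_seed(config$seed, "responder"))
  rp <- config$responder_params
  rows <- list()
  for (sid in unique(partner_calls$session_id)) {
    sess <- partner_calls[partner_calls$session_id == sid, , drop = FALSE]
    for (b in unique(sess$true_bout)) {
      p <- sort(sess$onset_s[sess$true_bout == b])
      if (length(p) < 3) next
      iois <- diff(p)
      f <- switch(config$responder_model,
        quarter_phase = {
          frac <- rp$fraction %||% 0.25
          noise <- rp$noise %||% 0
          cur <- c(iois, iois[length(iois)])
          p + frac * cur + rnorm(length(p), 0, noise)
        },
        uniform_random = {
          hi <- c(p[-1], p[length(p)] + median(iois))
          runif(length(p), p, hi)
        },
        adam = {
          params <- rp$adam
          if (!inherits(params, "adam_params")) {
            vr_stop("responder_params$adam must be an adam_params object",
                    "vr_config_error")
          }
          init <- rp$initial_asynchrony %||% (0.25 * median(iois))
          adam_simulate(params, p, initial_asynchrony = init,
                        seed = sample.int(2^31 - 2, 1))
        }
      )
      durations <- runif(length(f), config$call_duration[1],
                         config$call_duration[2])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        session_id = sid, context = config$context,
        individual_id = config$focal_id, role = "focal",
        onset_s = f, offset_s = f + durations, true_bout = b
      )
    }
  }
  out <- do.call(rbind, rows)
  # keep onsets non-negative (noise could push the first response below 0)
  if (min(out$onset_s) < 0) {
    shift <- -min(out$onset_s)
    out$onset_s <- out$onset_s + shift
    out$offset_s <- out$offset_s + shift
  }
  out
}

#' Generate a mutually coupled calling pair
#'
#' Two timekeeper agents call in alternation, each correcting the phase and
#' period of its own timekeeper toward a half-period offset from the other's
#' latest call: agent A leads each cycle, agent B targets A's onset plus half
#' a period, and A in turn targets B's previous onset plus half a period.
#' With both gain sets at zero the two streams are independent isochronous
#' sequences (a warning is issued when both are also noiseless, since the
#' output is then fully degenerate).
#'
#' @param params_a,params_b [adam_params()] objects for agents A and B
#'   (alpha = phase gain, beta = period gain, sigma = noise scale).
#' @param config A [sim_config()] (context should be `"two_way"`); the
#'   partner/focal ids name agents A and B respectively.
#' @return Call annotation tibble containing both agents' calls, with the
#'   generating bout index in `true_bout`.
#' @export
gen_coupled_pair <- function(params_a, params_b, config) {
  stopifnot(inherits(params_a, "adam_params"), inherits(params_b, "adam_params"),
            inherits(config, "sim_config"))
  gains_a <- abs(params_a$alpha) + abs(params_a$beta)
  gains_b <- abs(params_b$alpha) + abs(params_b$beta)
  if (gains_a == 0 && gains_b == 0 && params_a$sigma == 0 &&
      params_b$sigma == 0) {
    warning("both agents have zero gains and zero noise: output is degenerate")
  }
  set.seed(derive_seed(config$seed, "coupled"))
  period <- config$partner_period
  half <- period / 2
  id_a <- config$partner_id; id_b <- config$focal_id
  rows <- list()
  for (s in seq_len(config$n_sessions)) {
    n_cycles <- sample(config$pairs_per_session[1]:config$pairs_per_session[2], 1)
    sizes <- draw_bout_sizes(n_cycles, config$bout_size)
    t0 <- 0
    for (bt in seq_along(sizes)) {
      k <- sizes[bt]
      a <- numeric(k); b <- numeric(k)
      T_a <- period; T_b <- period
      a[1] <- t0
      b[1] <- t0 + half
      for (i in 2:k) {
        # A corrects toward half a period after B's previous call
        err_a <- a[i - 1] - (b[i - 1] - half)
        T_a <- T_a - params_a$beta * err_a
        a[i] <- a[i - 1] + T_a - params_a$alpha * err_a +
          rnorm(1, 0, params_a$sigma)
        # B corrects toward half a period after A's current call
        err_b <- b[i - 1] - (a[i - 1] + half)
        T_b <- T_b - params_b$beta * err_b
        b[i] <- b[i - 1] + T_b - params_b$alpha * err_b +
          rnorm(1, 0, params_b$sigma)
      }
      dur_a <- runif(k, config$call_duration[1], config$call_duration[2])
      dur_b <- runif(k, config$call_duration[1], config$call_duration[2])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        session_id = sprintf("session%02d", s), context = config$context,
        individual_id = rep(c(id_a, id_b), each = k),
        role = rep(c("partner", "focal"), each = k),
        onset_s = c(a, b), offset_s = c(a + dur_a, b + dur_b),
        true_bout = bt
      )
      t0 <- max(c(a, b)) + config$inter_bout_gap
    }
  }
  out <- do.call(rbind, rows)
  if (min(out$onset_s) < 0) {
    shift <- -min(out$onset_s)
    out$onset_s <- out$onset_s + shift
    out$offset_s <- out$offset_s + shift
  }
  sort_annotations(out)
}

#' Default four-context study configuration
#'
#' One configuration per behavioural context, mirroring the structure of the
#' emulated study: a solitary caller, a caller with a silent partner, a
#' caller responding to a periodic playback (one-way), and a mutually
#' coupled pair (two-way).
#'
#' @param seed Master seed; per-context seeds are derived from it.
#' @return Named list of [sim_config()] objects.
#' @export
default_study_configs <- function(seed = 1) {
  list(
    alone = sim_config(
      context = "alone", partner_jitter = 0.25, partner_id = "I",
      focal_id = "I", seed = derive_seed(seed, "alone")),
    silent_partner = sim_config(
      context = "silent_partner", partner_jitter = 0.25, partner_id = "A",
      focal_id = "A", seed = derive_seed(seed, "silent")),
    one_way = sim_config(
      context = "one_way", responder_model = "quarter_phase",
      responder_params = list(fraction = 0.25, noise = 0.05),
      partner_id = "PB", focal_id = "I", seed = derive_seed(seed, "oneway")),
    two_way = sim_config(
      context = "two_way", partner_id = "A", focal_id = "B",
      seed = derive_seed(seed, "twoway"))
  )
}

#' Generate a full multi-context dataset on disk
#'
#' Builds annotations for every configured context (solitary streams for
#' `alone`/`silent_partner`, partner + responder for `one_way`, a coupled
#' pair for `two_way`), writes them as one canonical CSV, and writes a JSON
#' manifest recording seeds and the true generating parameters so that
#' recovery and detection rates can be scored against ground truth.
#'
#' @param configs Named list of [sim_config()] objects (see
#'   [default_study_configs()]).
#' @param path Output CSV path.
#' @param manifest_path Output JSON path (default: `path` with a
#'   `.manifest.json` suffix).
#' @param coupling Named list of [adam_params()] for the two-way pair
#'   (`a`, `b`); defaults to moderate symmetric phase correction.
#' @return Invisibly, a list with the combined `calls` tibble and the
#'   `manifest` list.
#' @export
gen_dataset <- function(configs, path,
                        manifest_path = paste0(path, ".manifest.json"),
                        coupling = list(
                          a = adam_params(alpha = 0.5, beta = 0.1, sigma = 0.08),
                          b = adam_params(alpha = 0.5, beta = 0.1, sigma = 0.08))) {
  if (length(configs) == 0) vr_stop("need at least one config", "vr_config_error")
  all_calls <- list()
  for (cfg in configs) {
    calls <- switch(cfg$context,
      alone = ,
      silent_partner = {
        solo <- gen_partner_sequence(cfg)
        solo$role <- "focal"
        solo$individual_id <- cfg$focal_id
        solo
      },
      one_way = {
        partner <- gen_partner_sequence(cfg)
        rbind(partner, gen_responder(partner, cfg))
      },
      two_way = gen_coupled_pair(coupling$a, coupling$b, cfg)
    )
    all_calls[[cfg$context]] <- calls
  }
  combined <- do.call(rbind, all_calls)
  combined$true_bout <- NULL
  combined <- sort_annotations(combined)
  write_call_annotations(combined, path)
  manifest <- list(
    contexts = names(configs),
    seeds = lapply(configs, `[[`, "seed"),
    configs = lapply(configs, function(cfg) unclass(cfg)),
    coupling = lapply(coupling, function(p) unclass(p))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(calls = combined, manifest = manifest))
}
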