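#' Interval metrics for an ordered call sequence
#'
#' Computes the three elementary timing measures from a sequence of calls
#' sorted by onset: inter-onset intervals (IOI, onset-to-onset), inter-call
#' intervals (ICI, the silent gap from one call's offset to the next call's
#' onset) and call durations. By construction `ioi[n] = ici[n] + duration[n]`.
#'
#' @param calls A call annotation tibble with at least two rows, sorted by
#'   onset, or a list with numeric `onset_s` and `offset_s`.
#' @return A list of class `"interval_set"` with numeric vectors `iois`,
#'   `icis` (both length `n - 1`) and `durations` (length `n`).
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   session_id = "s", context = "alone", individual_id = "I", role = "focal",
#'   onset_s = c(0, 2, 5), offset_s = c(0.5, 2.6, 5.5)
#' )
#' interval_metrics(calls)
interval_metrics <- function(calls) {
  onset <- calls$onset_s
  offset <- calls$offset_s
  if (length(onset) < 2) {
    vr_stop("need at least 2 calls to compute intervals", "vr_insufficient_data")
  }
  if (is.unsorted(onset)) {
    vr_stop("calls must be sorted by onset", "vr_format_error")
  }
  iois <- diff(onset)
  if (any(iois <= 0)) {
    vr_stop("nonpositive inter-onset interval (duplicate onsets?)",
            "vr_format_error")
  }
  durations <- offset - onset
  icis <- onset[-1] - offset[-length(offset)]
  structure(
    list(iois = iois, icis = icis, durations = durations),
    class = "interval_set"
  )
}

#' Segment calls into bouts by the inter-call-interval gap rule
#'
#' A bout is a run of at least `min_calls` consecutive calls (pooled over all
#' callers in the session) whose internal silent gaps do not exceed
#' `multiplier` times the median ICI; the sequence is split wherever an ICI
#' exceeds that threshold, and runs shorter than `min_calls` are discarded.
#'
#' The threshold median is taken over the pooled onset-sorted sequence by
#' default (`ici_scope = "pooled"`); with `ici_scope = "per_individual"` the
#' median is taken over within-individual gaps instead, which ignores the
#' short gaps created by interleaved callers.
#'
#' @param calls Call annotation tibble (one or more sessions).
#' @param multiplier Gap threshold as a multiple of the median ICI.
#' @param min_calls Minimum number of calls per bout.
#' @param ici_scope Which gaps enter the threshold median, see Details.
#' @return The input tibble, sorted, with an integer `bout_id` column
#'   (`NA` for calls not assigned to any bout). The per-session thresholds
#'   are attached as attribute `"bout_threshold"`.
#' @export
segment_bouts <- function(calls, multiplier = 1.5, min_calls = 3,
                          ici_scope = c("pooled", "per_individual")) {
  ici_scope <- match.arg(ici_scope)
  validate_annotations(calls)
  if (nrow(calls) == 0) {
    vr_stop("no calls to segment", "vr_insufficient_data")
  }
  calls <- sort_annotations(calls)
  calls$bout_id <- NA_integer_
  thresholds <- c()
  next_id <- 1L
  for (sid in unique(calls$session_id)) {
    idx <- which(calls$session_id == sid)
    sess <- calls[idx, , drop = FALSE]
    n <- nrow(sess)
    if (n < 2) next
    icis <- sess$onset_s[-1] - sess$offset_s[-n]
    med <- if (ici_scope == "pooled") {
      median(icis)
    } else {
      per_ind <- unlist(lapply(split(sess, sess$individual_id), function(s) {
        if (nrow(s) < 2) return(numeric(0))
        s$onset_s[-1] - s$offset_s[-nrow(s)]
      }))
      if (length(per_ind) == 0) median(icis) else median(per_ind)
    }
    threshold <- multiplier * med
    thresholds[sid] <- threshold
    run <- cumsum(c(0, as.integer(icis > threshold)))
    ids <- rep(NA_integer_, n)
    for (r in unique(run)) {
      members <- which(run == r)
      if (length(members) >= min_calls) {
        ids[members] <- next_id
        next_id <- next_id + 1L
      }
    }
    calls$bout_id[idx] <- ids
  }
  attr(calls, "bout_threshold") <- thresholds
  calls
}

#' Extract vocal interactions from a bout
#'
#' A vocal interaction is a triplet of calls within one bout: two partner
#' calls followed by a focal response. Each focal call preceded (within its
#' bout) by at least two partner calls yields one interaction, built from the
#' two most recent partner onsets before the focal onset; focal calls falling
#' between the two partner calls do not disqualify later triplets.
#'
#' @param calls Call annotation tibble carrying a `bout_id` column (see
#'   [segment_bouts()]); calls with `NA` bout are ignored.
#' @param focal_id Identifier of the responding individual.
#' @param partner_id Identifier of the partner (or playback) individual.
#' @return Tibble with one row per interaction: `bout_id`,
#'   `partner_first_onset`, `partner_second_onset`, `focal_onset`.
#' @export
extract_interactions <- function(calls, focal_id, partner_id) {
  if (!"bout_id" %in% names(calls)) {
    vr_stop("calls must carry a bout_id column; run segment_bouts() first",
            "vr_format_error")
  }
  calls <- calls[!is.na(calls$bout_id), , drop = FALSE]
  out <- list()
  for (b in unique(calls$bout_id)) {
    bout <- calls[calls$bout_id == b, , drop = FALSE]
    p_on <- sort(bout$onset_s[bout$individual_id == partner_id])
    f_on <- sort(bout$onset_s[bout$individual_id == focal_id])
    if (length(p_on) < 2 || length(f_on) == 0) next
    for (f in f_on) {
      prior <- p_on[p_on < f]
      if (length(prior) < 2) next
      k <- length(prior)
      out[[length(out) + 1L]] <- tibble::tibble(
        bout_id = b,
        partner_first_onset = prior[k - 1],
        partner_second_onset = prior[k],
        focal_onset = f
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(bout_id = integer(0), partner_first_onset = numeric(0),
                          partner_second_onset = numeric(0),
                          focal_onset = numeric(0)))
  }
  do.call(rbind, out)
}

#' Response phase of focal calls relative to the partner's period
#'
#' The response phase expresses the focal response latency as a fraction of
#' the partner's preceding inter-onset interval, scaled to degrees:
#' `(focal_onset - partner_second_onset) / (partner_second_onset -
#' partner_first_onset) * 360`. Responses later than one full partner period
#' are wrapped onto the circle by default, recording the number of elapsed
#' whole periods in `winding`; with `wrap = FALSE` such responses are marked
#' `NA` (discarded) instead.
#'
#' @param interactions Interaction tibble from [extract_interactions()].
#' @param wrap Wrap phases beyond 360 degrees onto the circle?
#' @return Tibble with columns `bout_id`, `angle_deg` in `[0, 360)` and
#'   integer `winding`.
#' @export
#' @examples
#' x <- tibble::tibble(bout_id = 1L, partner_first_onset = 0,
#'                     partner_second_onset = 2, focal_onset = 2.5)
#' response_phase(x)  # 90 degrees
response_phase <- function(interactions, wrap = TRUE) {
  p1 <- interactions$partner_first_onset
  p2 <- interactions$partner_second_onset
  f <- interactions$focal_onset
  ioi <- p2 - p1
  if (any(ioi <= 0)) {
    vr_stop("partner inter-onset interval must be positive", "vr_format_error")
  }
  raw <- (f - p2) / ioi * 360
  if (wrap) {
    angle <- raw %% 360
    winding <- as.integer(floor(raw / 360))
  } else {
    keep <- raw <= 360
    angle <- ifelse(keep, raw %% 360, NA_real_)
    winding <- ifelse(keep, as.integer(floor(raw / 360)), NA_integer_)
  }
  tibble::tibble(bout_id = interactions$bout_id, angle_deg = angle,
                 winding = winding)
}

#' Self-referential phases for non-interactive contexts
#'
#' When no partner is calling there is no external reference interval, so
#' each call's phase is taken relative to the caller's own previous
#' inter-onset interval: for call `n >= 3`,
#' `angle = IOI[n-1] / IOI[n-2] * 360`, wrapped onto the circle with the
#' winding recorded. This mirrors the interactive response-phase formula with
#' the caller as its own reference.
#'
#' @param onsets Numeric onsets of one individual's calls within one bout,
#'   sorted increasing.
#' @return Tibble with `angle_deg` and `winding`; empty when fewer than three
#'   calls are supplied.
#' @export
self_referential_phases <- function(onsets) {
  if (length(onsets) < 3) {
    return(tibble::tibble(angle_deg = numeric(0), winding = integer(0)))
  }
  iois <- diff(onsets)
  if (any(iois <= 0)) {
    vr_stop("onsets must be strictly increasing", "vr_format_error")
  }
  raw <- iois[-1] / iois[-length(iois)] * 360
  tibble::tibble(angle_deg = raw %% 360, winding = as.integer(floor(raw / 360)))
}

#' Response-phase sample for one focal/partner pairing
#'
#' Convenience wrapper chaining [segment_bouts()] (if needed),
#' [extract_interactions()] and [response_phase()] across all bouts of a
#' session table, returning one pooled phase sample.
#'
#' @inheritParams extract_interactions
#' @inheritParams response_phase
#' @param calls Call annotation tibble; segmented on the fly when no
#'   `bout_id` column is present.
#' @return Tibble with `bout_id`, `angle_deg`, `winding`.
#' @export
response_phases <- function(calls, focal_id, partner_id, wrap = TRUE) {
  if (!"bout_id" %in% names(calls)) calls <- segment_bouts(calls)
  inter <- extract_interactions(calls, focal_id, partner_id)
  if (nrow(inter) == 0) {
    return(tibble::tibble(bout_id = integer(0), angle_deg = numeric(0),
                          winding = integer(0)))
  }
  response_phase(inter, wrap = wrap)
}
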