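# Fixture builders shared across test files.

make_calls <- function(onsets, durations = 0.4, individual = "I",
                       role = "focal", session = "s1", context = "alone") {
  tibble::tibble(
    session_id = session, context = context,
    individual_id = rep_len(individual, length(onsets)),
    role = rep_len(role, length(onsets)),
    onset_s = onsets, offset_s = onsets + rep_len(durations, length(onsets))
  )
}

# One bout of interleaved playback + focal calls where the focal responds at
# `fraction` of the (fixed or varying) partner period.
make_duet <- function(partner_onsets, fraction = 0.25, duration = 0.2,
                      context = "one_way") {
  p <- make_calls(partner_onsets, duration, individual = "P",
                  role = "playback", context = context)
  iois <- diff(partner_onsets)
  cur <- c(iois, iois[length(iois)])
  f <- make_calls(partner_onsets + fraction * cur, duration,
                  individual = "F", role = "focal", context = context)
  rbind(p, f)
}

canonical_csv_lines <- function() {
  c("session_id,context,individual_id,role,onset_s,offset_s",
    "s1,two_way,A,focal,0.0,0.4",
    "s1,two_way,B,partner,1.0,1.5",
    "s1,two_way,A,focal,2.0,2.4")
}
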