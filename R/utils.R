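# Internal helpers shared across modules.

vr_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "vr_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @importFrom stats median rnorm runif quantile approxfun pnorm pf sd
#' @importFrom stats ks.test wilcox.test uniroot optim complete.cases setNames
NULL

CONTEXTS <- c("alone", "silent_partner", "one_way", "two_way")
ROLES <- c("focal", "partner", "playback")

# One RNG seed per named stage, derived reproducibly from a master seed and
# kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
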