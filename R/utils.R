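# Internal helpers shared across modules.

# Round half away from zero (round() is round-half-even).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Classed errors so callers can distinguish contract violations.
stop_slicecov <- function(message, class) {
  abort(message, class = c(class, "slicecov_error"))
}

# Stable 32-bit string hash (polynomial rolling hash); used to fan a global
# seed out into per-stage / per-case sub-seeds so adding cases does not
# reshuffle the noise drawn for existing ones.
stable_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible sub-seed from a global seed and labels
#'
#' Combines a global integer seed with one or more string labels (stage
#' name, case id, ROI kind, ...) into a deterministic 32-bit seed. The
#' mapping is a fixed polynomial hash, so the sub-seed for a given case
#' never depends on how many other cases exist.
#'
#' @param seed Integer global seed.
#' @param ... Character labels identifying the consumer of the sub-seed.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' sub_seed(7, "noise", "case_012", "tumor")
sub_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  as.integer((as.numeric(seed) + stable_hash(labels)) %% 2147483647)
}
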