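# Internal helpers shared across modules.

# TRUE for each element of a list-column whose character set intersects `terms`.
has_any_term <- function(sets, terms) {
  if (length(terms) == 1L) {
    term <- terms
    vapply(sets, function(s) term %in% s, logical(1L), USE.NAMES = FALSE)
  } else {
    vapply(sets, function(s) any(s %in% terms), logical(1L), USE.NAMES = FALSE)
  }
}

# Coerce strings to numeric; anything unparseable becomes NA without a warning.
quiet_numeric <- function(x) {
  suppressWarnings(as.numeric(x))
}

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x) | x < 0 | x > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1].", what))
  }
  invisible(x)
}

# Split one seed into a reproducible stream of sub-seeds (kept below 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 77777L * seq_len(n)) %% 2147483587L
}
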