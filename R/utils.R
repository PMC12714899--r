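# Internal helpers shared across modules.

# Classed error so callers (and the CLI wrapper) can branch on failure kind
# without string matching.
tgt_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "tgt_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Per-animal seed derivation: a simple affine counter scheme, independent of
# animal order, kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, index) {
  m <- 2147483647
  as.integer((as.numeric(seed) %% m + 999983 * as.numeric(index)) %% m)
}
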