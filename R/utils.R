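.wn_sep <- "\x01"

# Path/node-id ordering is byte-wise (radix) so results do not depend on the
# session locale. Sequences of ids are compared element-wise; joining with a
# separator byte below all printable characters preserves that order on the
# concatenated strings (prefixes sort first).
path_key <- function(ids) paste(ids, collapse = .wn_sep)

radix_order <- function(...) order(..., method = "radix")

radix_sort <- function(x) x[radix_order(x)]

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 31-bit seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 19997L + as.integer(stream) * 7919L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
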