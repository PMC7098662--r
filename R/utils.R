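# internal helpers shared across modules

# run `code` under a fixed RNG state without disturbing the caller's stream
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# derive a per-stage sub-seed from a master seed; stays below 2^31
sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- rlang::`%||%`

# deterministic ascending rank with explicit tie-breakers; each ...
# vector is consulted in order, final tie-break is lexicographic on `ids`
rank_with_ties <- function(x, ids, ...) {
  extra <- list(...)
  ord <- do.call(order, c(list(x), extra, list(ids)))
  r <- integer(length(x))
  r[ord] <- seq_along(x)
  r
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name,
                  format(min), format(max)))
  }
  invisible(x)
}
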