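# Internal helpers shared across modules.

# Deterministically derive a child seed from a master seed and an offset.
# Kept well below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 46337) * 46337 + (as.numeric(offset) %% 46337)
  as.integer(s %% 2147483647)
}

# Evaluate `code` under a local RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
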