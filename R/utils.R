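# Internal helpers: deterministic RNG substreams and small numeric utilities.

# Mix a base seed with integer indices into a substream seed in [0, 2^31 - 1].
# A fixed LCG-style mix keeps every (fraction, field, layer) stream independent
# of how many other streams are drawn, so adding fractions never perturbs
# earlier ones. All arithmetic stays below 2^53 so doubles are exact.
substream_seed <- function(base, ...) {
  idx <- c(...)
  h <- as.numeric(base) %% 2147483647
  for (k in seq_along(idx)) {
    h <- (h * 69069 + (as.numeric(idx[k]) + 1) * 104729 + k * 7919) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_substream <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

hypot <- function(dx, dy) sqrt(dx^2 + dy^2)

stop_lfqa <- function(message, class) {
  abort(message, class = c(class, "lfqa_error"))
}

# Spot identity within a fraction / plan.
spot_key_cols <- c("field_id", "layer_index", "spot_index")

assert_scalar_number <- function(x, name, min = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > min else x >= min)
  if (!ok) {
    stop_lfqa(
      sprintf("`%s` must be a single finite number %s %s", name,
              if (strict) ">" else ">=", format(min)),
      "lfqa_invalid_argument"
    )
  }
  invisible(x)
}
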