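# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a fixed RNG state when `seed` is given; otherwise use the
# current RNG stream. Keeps every generator deterministic given its seed
# without clobbering the caller's RNG.
with_seed_or_current <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

stop_invalid <- function(msg, class = "recurcna_invalid_argument") {
  abort(msg, class = c(class, "recurcna_error"))
}

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single number", name))
  }
  if (integer && x != round(x)) {
    stop_invalid(sprintf("`%s` must be an integer", name))
  }
  if (x < min || x > max) {
    stop_invalid(sprintf("`%s` must be in [%s, %s], got %s", name, min, max, x))
  }
  invisible(x)
}

check_prob <- function(x, name) check_number(x, name, min = 0, max = 1)

# Derive a reproducible child seed from a parent seed and a stream label,
# staying inside 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
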