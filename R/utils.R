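# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_flag <- function(cond, ...) {
  if (!isTRUE(cond)) stop_input(...)
}

# Positive scalar / count validators used by the config constructors.
check_count <- function(x, name, min = 1L) {
  check_flag(length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x >= min,
             "configuration error: '%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_positive <- function(x, name) {
  check_flag(length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0,
             "configuration error: '%s' must be a single positive number", name)
  as.numeric(x)
}

check_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) && x <= hi
  check_flag(ok, "configuration error: '%s' must be in %s%g, %g]",
             name, if (lo_open) "(" else "[", lo, hi)
  as.numeric(x)
}

# Derive a per-stage seed from the top-level run seed and a stage name, so
# stages can be rerun in isolation reproducibly.  Plain 32-bit arithmetic on
# the stage name's character codes; result always in [1, 2^31 - 2].
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 69069 + h * 2654435761) %% (2^31 - 2) + 1)
}

# Fixed-format numeric printing for text artifacts, so that file checksums
# are stable across platforms (10 significant digits).
format_num <- function(x) formatC(x, digits = 10, format = "g")

new_tag <- function(x, class) {
  class(x) <- class
  x
}
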