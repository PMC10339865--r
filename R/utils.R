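# Internal validation and logging helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# Stage messages go to stderr via message(); callers can suppressMessages().
log_msg <- function(fmt, ...) message(sprintf(fmt, ...))

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Run `code` under a deterministic RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
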