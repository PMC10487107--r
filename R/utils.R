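## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_format <- function(...) stop(sprintf(...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, positive = FALSE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) &&
    (if (positive) x >= 1 else x >= 0)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## deterministic child seeds, kept below 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort_format("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", "))
}
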