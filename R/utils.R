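# Internal validation helpers. All user-facing errors are classed so tests
# and the pipeline can dispatch on them.

abort_config <- function(msg, field = NULL) {
  rlang::abort(msg, class = "onsetprs_config_error", field = field)
}

abort_input <- function(msg, class = "onsetprs_input_error") {
  rlang::abort(msg, class = class)
}

check_prob <- function(x, name, allow_zero = TRUE, allow_one = TRUE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    abort_config(sprintf("`%s` must be a probability in the valid range", name),
                 field = name)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    abort_config(sprintf("`%s` must be an integer count >= %d", name, min),
                 field = name)
  }
  invisible(as.integer(x))
}

check_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    abort_input(sprintf("%s is missing required column(s): %s", what,
                        paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# floor() that tolerates tiny negative fuzz from interpolation arithmetic
age_year <- function(age) as.integer(floor(age + 1e-9))
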