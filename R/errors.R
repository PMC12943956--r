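# Classed conditions used across the package; the command-line wrapper maps
# them to exit codes (validation 2, data 3, degenerate baseline 4).

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "rehabdtw_validation_error", ...)
}

abort_data <- function(message, ...) {
  rlang::abort(message, class = "rehabdtw_data_error", ...)
}

abort_degenerate <- function(message, ...) {
  rlang::abort(message, class = "rehabdtw_degenerate_baseline_error", ...)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort_validation(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort_validation(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort_validation(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  if (x > max) {
    abort_validation(sprintf("`%s` must be <= %s.", name, format(max)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort_validation(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}
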