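# Internal argument checking helpers. Kept deliberately small; user-facing
# errors should name the offending argument or record.

stopf <- function(fmt, ..., class = "depnet_error") {
  abort(sprintf(fmt, ...), class = class)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = TRUE, allow_equal_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number", name,
          class = "depnet_argument_error")
  }
  lo_ok <- if (allow_equal_lower) x >= lower else x > lower
  hi_ok <- if (allow_equal_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stopf("`%s` = %s is outside the allowed range %s%s, %s%s", name,
          format(x), if (allow_equal_lower) "[" else "(", format(lower),
          format(upper), if (allow_equal_upper) "]" else ")",
          class = "depnet_argument_error")
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be TRUE or FALSE", name, class = "depnet_argument_error")
  }
  invisible(x)
}

check_string <- function(x, name, allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) ||
      (!allow_empty && !nzchar(x))) {
    stopf("`%s` must be a single non-empty string", name,
          class = "depnet_argument_error")
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("`seed` must be supplied as a single integer",
          class = "depnet_argument_error")
  }
  invisible(as.integer(seed))
}

# Seeded evaluation that restores the caller's RNG state afterwards, so
# package functions are reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  seed <- check_seed(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
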