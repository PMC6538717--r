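# Internal input validation. All user-facing validation failures signal a
# condition of class "spicpms_validation_error" so callers can trap them.

spicpms_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "spicpms_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

validation_error <- function(message) {
  spicpms_error(message, "spicpms_validation_error", call = sys.call(-2))
}

# scalar numeric in (lower, upper) / [lower, upper] depending on *_open
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         lower_open = FALSE, upper_open = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    validation_error(sprintf("`%s` must be a single finite number", name))
  }
  if (integer && x != floor(x)) {
    validation_error(sprintf("`%s` must be an integer", name))
  }
  low_ok <- if (lower_open) x > lower else x >= lower
  up_ok <- if (upper_open) x < upper else x <= upper
  if (!low_ok || !up_ok) {
    validation_error(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (lower_open) "(" else "[", lower, upper,
      if (upper_open) ")" else "]"
    ))
  }
  invisible(x)
}

check_numeric_vector <- function(x, name, lower = -Inf, min_length = 1L) {
  if (!is.numeric(x) || length(x) < min_length || anyNA(x) ||
      any(!is.finite(x))) {
    validation_error(sprintf(
      "`%s` must be a finite numeric vector of length >= %d", name, min_length
    ))
  }
  if (any(x < lower)) {
    validation_error(sprintf("`%s` must be >= %g throughout", name, lower))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL draws from the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  check_number(seed, "seed", integer = TRUE)
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
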