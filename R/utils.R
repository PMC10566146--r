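#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rnorm runif rbinom rpois setNames
NULL

# Condition helpers: every package error carries a subclass so callers (and
# the command-line launcher) can distinguish configuration mistakes from
# runtime failures.
abort_config <- function(msg, class = NULL, ...) {
  abort(msg, class = c(class, "dispersr_error_config", "dispersr_error"), ...)
}

abort_runtime <- function(msg, class = NULL, ...) {
  abort(msg, class = c(class, "dispersr_error_runtime", "dispersr_error"), ...)
}

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE,
                         allow_min = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || (!allow_min && x == min) || x > max) {
    abort_config(sprintf(
      "`%s` must be in %s%s, %s]; got %s.",
      name, if (allow_min) "[" else "(", format(min), format(max), format(x)
    ))
  }
  if (integer && x != as.integer(x)) {
    abort_config(sprintf("`%s` must be a whole number; got %s.", name, format(x)))
  }
  invisible(x)
}

# Derive a fresh sub-seed from a parent seed for an independent RNG stream.
# Keeps values < 2^31 so they remain valid R integers.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 11 * k) %% 2147480989)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
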