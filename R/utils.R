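#' @importFrom rlang abort warn .data
#' @importFrom stats coef lm pf pt sd var setNames quantile rnorm runif rbinom
#' @importFrom utils head tail
NULL

# condition helper: all package errors carry a subclass so callers (and the
# test suite) can distinguish labeling vs geometry vs correspondence failures
stop_cs <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("cardioshape_error_", class),
                                  "cardioshape_error"), ...)
}

warn_cs <- function(message, class = "generic") {
  rlang::warn(message, class = paste0("cardioshape_warning_", class))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed for a named random substream, kept within 32-bit
# integer range so set.seed() accepts it on any platform.
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is_scalar_number(x)) {
    stop_cs(sprintf("`%s` must be a single finite number", name), "domain")
  }
  if (positive && x <= 0) {
    stop_cs(sprintf("`%s` must be positive (got %g)", name, x), "domain")
  }
  invisible(x)
}
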