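`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

#' Derive a named sub-seed from a top-level seed
#'
#' One top-level seed fans out to deterministic, distinct sub-seeds for
#' each named stage (simulation, fold assignment, inner CV, ...), so a
#' single integer reproduces an entire experiment.
#'
#' @param seed Integer top-level seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "folds")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  u <- utf8ToInt(label)
  h <- sum(u * seq_along(u))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 7919) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Verbosity-gated logging to stderr. Level: 0 silent, 1 info, 2 debug.
log_msg <- function(..., level = 1L) {
  if (getOption("osteogrs.verbose", 1L) >= level) {
    message("[osteogrs] ", ...)
  }
  invisible(NULL)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

# round-half-away-from-zero at `digits` decimals (base round() is
# round-half-even, which does not match report-style percent formatting)
round_half_away <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
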