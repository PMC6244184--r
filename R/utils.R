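# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Stage-level randomness (injection plan, concentrations, measurement noise)
#' is drawn from named sub-streams so that each stage is independently
#' reproducible from one master seed.
#'
#' @param seed Master seed (integer).
#' @param name Sub-stream name, e.g. `"plan"`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1048573
  as.integer((abs(as.numeric(seed)) %% 1e6) * 1048573 + h) %% 2147483646L + 1L
}

# Stops with a formatted message; keeps call out of the condition.
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

# Sample RSD in percent (n - 1 denominator). NA when fewer than two finite
# values; NaN-protected: a zero mean yields NA with a warning upstream.
rsd_percent <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m == 0) return(NA_real_)
  100 * stats::sd(x) / m
}
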