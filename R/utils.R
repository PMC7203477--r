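#' Derive a child seed from a master seed
#'
#' Every source of randomness in the package is addressable: per-fold,
#' per-iteration and per-stage seeds are derived from a single master seed by
#' a counter scheme, so any individual model or pair set can be regenerated
#' in isolation.  The result is always a valid 32-bit R seed.
#'
#' @param seed Master integer seed.
#' @param ... Integer counters (fold index, iteration index, stage code ...).
#' @return An integer seed in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, ...) {
  ctr <- c(seed, ...)
  h <- 0
  for (x in ctr) {
    h <- (h * 69069 + (as.numeric(x) %% 2^31) + 1) %% 2147483647
  }
  as.integer(h)
}

# Run code under a local RNG state when seed is non-NULL; otherwise use the
# ambient RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(msg) abort(msg, class = "ptcnet_invalid_argument")
stop_capacity <- function(msg) abort(msg, class = "ptcnet_capacity_error")
stop_format <- function(msg) abort(msg, class = "ptcnet_format_error")
stop_config <- function(msg) abort(msg, class = "ptcnet_configuration_error")
stop_shape <- function(msg) abort(msg, class = "ptcnet_shape_error")
stop_degenerate <- function(msg) abort(msg, class = "ptcnet_degenerate_error")
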