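#' Global numeric tolerance
#'
#' Flux values and flux differences with magnitude below this tolerance are
#' treated as zero throughout the flux analyses (steady-state residuals,
#' bound violations, fitness screens).
#'
#' @return The tolerance, `1e-4`.
#' @export
flux_tolerance <- function() 1e-4

# Derive a reproducible 32-bit substream seed from a master seed and an index,
# so that enlarging an ensemble never reshuffles earlier draws.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 + i * 16807) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
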