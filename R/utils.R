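#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message, without the call
#' @noRd
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check a scalar is a single finite number
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Polynomial rolling hash of a character scalar, returned as hex.
#' Used only for provenance stamps in run reports (no crypto intent).
#' Mod 2^31 - 1 keeps all arithmetic exact in doubles.
#' @noRd
content_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 257 + b + 1) %% m
  sprintf("%08x", h)
}

#' Deterministic seed derived from a base seed and a stream label.
#' Keeps derived seeds within 32-bit integer range.
#' @noRd
derive_seed <- function(seed, stream) {
  stopifnot(is_number(seed))
  offs <- sum(utf8ToInt(stream)) %% 1000
  as.integer((abs(seed) * 1009 + offs) %% 2147483647)
}
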