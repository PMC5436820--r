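# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a named-field error message
#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Rolling polynomial hash of a character scalar, as 8 hex digits
#'
#' Used to stamp output files with a configuration fingerprint so a report
#' can be traced to the exact inputs that produced it. Not cryptographic;
#' arithmetic stays below 2^53 so the result is exact in doubles.
#' @noRd
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Derive a 32-bit sub-seed from a base seed and an index
#'
#' Keeps per-month RNG streams reproducible under partial simulation:
#' month k always sees the same stream regardless of which other months
#' are generated.
#' @noRd
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) * 48271 + index * 16807) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

month_key <- function(date) format(as.Date(date), "%Y-%m")
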