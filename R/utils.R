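# shared helpers: rounding, seeds, pair keys

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; tabulated percentages here follow
#' the conventional half-up rule (0.125 -> 0.13 at two decimals).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# proportion -> percent at `digits` decimals, half-up
as_pct <- function(x, digits = 2) round_half_up(100 * x, digits)

# derive a per-stream 32-bit seed from a base seed; keeps streams
# insertion-order independent and below 2^31
derive_seed <- function(seed, i) {
  s <- as.numeric(seed) %% 2147483647
  # s * 48271 stays below 2^53, so the modular arithmetic is exact
  as.integer((s * 48271 + as.numeric(i) * 1009) %% 2147483647)
}

# canonical single-string key for a record pair
pair_key <- function(id_a, id_b) paste(id_a, id_b, sep = "\r")

# empty matched-pair table
empty_pairs <- function(score = FALSE) {
  out <- data.table(record_id_a = character(0), record_id_b = character(0))
  if (score) out[, score := numeric(0)]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
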