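# Internal numeric and seeding helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed design tables in the
#' response-surface literature round half away from zero (91.2 -> 91,
#' -4.35 -> -4.4). A small epsilon guards against binary representation of
#' decimal halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# Round to 2 significant figures but never finer than whole units: the
# convention that reproduces printed steepest-ascent increments
# (296 stays 296, 91.2 -> 91, -4.35 -> -4.4, 0.117 -> 0.12).
round_increment <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi == 0) return(xi)
    int_digits <- floor(log10(abs(xi))) + 1
    round_half_up(xi, max(0L, 2L - int_digits))
  }, numeric(1))
}

#' Derive a reproducible substream seed
#'
#' Maps a master seed plus a purpose label and replicate index to a
#' deterministic 31-bit seed, so that (for example) changing predictor
#' settings never perturbs the genotype simulation stream.
#'
#' @param master integer master seed.
#' @param purpose character label of the stream.
#' @param index replicate index within the stream.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
seed_stream <- function(master, purpose = "default", index = 1L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  x <- (abs(master) %% 2147483647) + 0
  # two rounds of a Lehmer-style mix keep distinct (purpose, index) apart
  x <- (x * 48271 + h * 16807 + index * 69621) %% 2147483647
  x <- (x * 48271 + 12345) %% 2147483647
  as.integer(x + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
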