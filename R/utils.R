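#' Round half away from zero
#'
#' Reported percentages use commercial rounding (0.005 -> 0.01, -0.005 ->
#' -0.01) rather than base R's round-half-to-even, so printed tables
#' reproduce exactly.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (may be 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(0.865, 2)   # 0.87
#' round(0.865, 2)             # 0.86 under banker's rounding
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp so values stored just below .5 (binary representation)
  # still round up, matching decimal half-away semantics
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

stop_ctx <- function(..., call. = FALSE) stop(..., call. = call.)

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "seedscape")
  if (!nzchar(p)) stop_ctx("packaged data file not found: ", file)
  p
}
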