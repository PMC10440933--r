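#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the
#' convention used when printing island carrier percentages (e.g. 88.9
#' prints as 89, 85.7 as 86).  Base `round()` rounds ties to even, which
#' would disagree at exact halves.
#'
#' @param x Numeric vector.
#' @return Numeric vector of rounded values.
#' @examples
#' round_half_up(100 * 16 / 18) # 89
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Segment length in kilobases
#'
#' Length of a 1-based inclusive interval in kb:
#' `(end - start + 1) / 1000`.  This is the arithmetic that relates the
#' Bp1/Bp2 columns of a segment table to its Kb column.
#'
#' @param start_bp,end_bp Integer vectors of 1-based inclusive bounds.
#' @return Numeric vector of lengths in kb.
#' @export
segment_length_kb <- function(start_bp, end_bp) {
  stopifnot(all(end_bp >= start_bp))
  (end_bp - start_bp + 1) / 1000
}

# internal: stop with a prefixed message
abort_rohscan <- function(...) {
  stop(paste0(...), call. = FALSE)
}
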