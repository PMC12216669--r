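# internal helpers shared across modules

#' Round half away from zero
#'
#' Report tables use commercial rounding (0.5 rounds away from zero) rather
#' than the IEEE banker's rounding of [base::round()], so that printed
#' three-decimal values match conventional statistical-yearbook tables.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical form of a county name used as join key: case-folded, trimmed,
# apostrophes/whitespace stripped, Unicode-normalized where iconv allows
norm_county <- function(x) {
  x <- trimws(x)
  x <- gsub("[’'` ]", "", x)
  tolower(x)
}

stop_esh <- function(..., call. = FALSE) stop(..., call. = call.)

is_finite_num <- function(x) is.numeric(x) & is.finite(x)
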