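#' @keywords internal
"_PACKAGE"

#' Round half-up
#'
#' Percentages in quality tables are conventionally rounded half-up (so
#' 92.435 prints as 92.44), whereas base [round()] rounds half-to-even.
#' A small epsilon guards against values sitting just below .5 after
#' binary-float division.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sgn <- sign(x)
  sgn * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# percentage of a count pair, half-up to `digits`; NA when denominator is 0
pct_of <- function(num, den, digits = 2) {
  if (is.na(den) || den == 0) return(NA_real_)
  round_half_up(100 * num / den, digits)
}

# stable, locale-independent ordering for paths and ids
sort_c <- function(x) {
  if (length(x) == 0) return(x)
  x[order(x, method = "radix")]
}

is_missing_value <- function(x, sentinels = c("", "na", "n/a", "null")) {
  is.na(x) | tolower(trimws(as.character(x))) %in% sentinels
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
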