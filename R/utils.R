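#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (the convention
#' used when reporting percentages in tabulated report characteristics),
#' unlike [base::round()] which rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @examples
#' round_half_up(0.5)      # 1
#' round_half_up(2.25, 1)  # 2.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p * sign(x)
}

#' Convert YYYYMMDD integers to Date
#'
#' Invalid or unparseable values become `NA` silently; callers that need to
#' log coercion counts compare `NA` counts before and after.
#'
#' @param x integer or character vector of dates in `YYYYMMDD` form.
#' @return a `Date` vector.
#' @export
ymd_int_to_date <- function(x) {
  d <- as.Date(as.character(x), format = "%Y%m%d")
  # reject things like 20241301 that as.Date tolerates on some platforms,
  # and short strings such as 2024 (year only, present in raw FAERS)
  d[nchar(as.character(x)) != 8L & !is.na(x)] <- as.Date(NA)
  d
}

#' Convert Date to YYYYMMDD integer
#' @param d a `Date` vector.
#' @return integer vector in `YYYYMMDD` form.
#' @export
date_to_ymd_int <- function(d) {
  as.integer(format(d, "%Y%m%d"))
}

# normalize a term or drug-name string for matching
norm_string <- function(x) {
  toupper(trimws(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
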