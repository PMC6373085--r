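#' @importFrom rlang %||% .data abort warn inform
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
NULL

#' Round half-up
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used when percentages are printed in data-quality reports (so 47.15 renders
#' as 47.2, not banker's-rounded 47.1).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(47.15, 2.5, -2.5), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a percentage as printed in report tables
#'
#' Computes `100 * numerator / denominator` and rounds half-up to one decimal.
#' Returns `NA` when the denominator is zero: an undefined measure is never
#' rendered as 0% or 100%.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage, or `NA_real_` for a zero denominator.
#' @examples
#' pct(14619, 31000) # 47.2
#' @export
pct <- function(numerator, denominator, digits = 1) {
  ifelse(denominator > 0,
         round_half_up(100 * numerator / denominator, digits),
         NA_real_)
}

# Raw (unrounded) percentage with zero-denominator -> NA.
pct_raw <- function(numerator, denominator) {
  ifelse(denominator > 0, 100 * numerator / denominator, NA_real_)
}

# Completed years between two dates, vectorized (age-at-date convention).
years_between <- function(from, to) {
  from <- as.Date(from)
  to <- as.Date(to)
  yrs <- lubridate::year(to) - lubridate::year(from)
  before_birthday <-
    (lubridate::month(to) < lubridate::month(from)) |
    (lubridate::month(to) == lubridate::month(from) &
       lubridate::mday(to) < lubridate::mday(from))
  yrs - as.integer(before_birthday)
}

# Render a p-value the way the report tables print it.
format_p <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "<0.001",
    TRUE ~ sprintf("%.3f", p)
  )
}

assert_date <- function(x, what) {
  if (!inherits(x, "Date")) {
    x <- tryCatch(as.Date(x), error = function(e) NA)
  }
  if (any(is.na(x))) {
    abort(sprintf("`%s` must be a parseable date (ISO-8601).", what))
  }
  x
}
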