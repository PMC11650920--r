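## 365-day calendar (no leap days); month boundaries at the standard
## day-of-year cut points.

.MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.MONTH_STARTS <- cumsum(c(1L, .MONTH_LENGTHS[-12L]))

#' Month index for a day of the year
#'
#' Maps a day of the 365-day model year (1--365, no leap days) to its
#' calendar month (1--12).
#'
#' @param day Integer vector of day-of-year values in 1--365.
#' @return Integer vector of month indices in 1--12.
#' @examples
#' month_of_day(c(1, 91, 365))
#' @export
month_of_day <- function(day) {
  if (any(!is.finite(day)) || any(day < 1) || any(day > 365))
    stop("`day` must be in 1..365", call. = FALSE)
  findInterval(as.integer(day), .MONTH_STARTS)
}

#' Day of year for a (month, day) date
#'
#' @param month Month 1--12.
#' @param day Day of month.
#' @return Day of the 365-day year.
#' @examples
#' day_of_year(4, 1) # April 1 pre-breeding census
#' @export
day_of_year <- function(month, day) {
  month <- as.integer(month); day <- as.integer(day)
  if (month < 1L || month > 12L) stop("`month` must be in 1..12", call. = FALSE)
  if (day < 1L || day > .MONTH_LENGTHS[month])
    stop("`day` is not a valid day of month ", month, call. = FALSE)
  .MONTH_STARTS[month] + day - 1L
}
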