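#' Assign biological seasons to dates
#'
#' The study year is split into *Fall/Winter* (1 October - 15 March) and
#' *Summer* (1 June - 30 September).  The period 16 March - 31 May, roughly
#' the reproductive season when movement behaviour changes (males range
#' widely, reproductive females concentrate around den trees), is excluded
#' from all analyses.
#'
#' @param dates a `Date` vector (or anything `as.Date()` accepts).
#' @return character vector with values `"FallWinter"`, `"Summer"` or
#'   `"Excluded"`.
#' @examples
#' assign_season(as.Date(c("2009-03-15", "2009-04-20", "2009-06-01")))
#' @export
assign_season <- function(dates) {
  d <- as_date(dates)
  m <- as.integer(format(d, "%m"))
  day <- as.integer(format(d, "%d"))
  out <- rep("Excluded", length(d))
  out[m %in% c(10L, 11L, 12L, 1L, 2L) | (m == 3L & day <= 15L)] <- "FallWinter"
  out[m %in% 6:9] <- "Summer"
  out
}

#' Count days of a window falling in a season
#'
#' @param start,end inclusive `Date` endpoints.
#' @param season `"FallWinter"`, `"Summer"`, or `"Any"` (any non-excluded
#'   day).
#' @return integer number of days.
#' @keywords internal
season_days <- function(start, end, season = "Any") {
  start <- as_date(start); end <- as_date(end)
  if (start > end) return(0L)
  s <- assign_season(seq(start, end, by = "day"))
  if (season == "Any") sum(s != "Excluded") else sum(s == season)
}

season_levels <- c("FallWinter", "Summer")

# period membership used for home-range estimation: Annual keeps every
# relocation in the year window; seasonal periods keep matching seasons only
period_filter <- function(dates, period) {
  if (period == "Annual") rep(TRUE, length(dates))
  else assign_season(dates) == period
}
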