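# Internal helpers shared across modules.

# Survey strata and the management stocks they belong to.  The two northern
# survey strata are pooled into the Washington Northern Inland Waters stock.
SC_STRATA <- c("SouthernPugetSound", "HoodCanal",
               "NorthernPugetSound", "SanJuans_StraitJDF")

SC_STOCK_OF_STRATUM <- c(
  SouthernPugetSound = "SouthernPugetSound",
  HoodCanal          = "HoodCanal",
  NorthernPugetSound = "WANorthernInlandWaters",
  SanJuans_StraitJDF = "WANorthernInlandWaters"
)

SC_EFFORT_TYPES <- c("transect", "connector", "transit")
SC_SEASONS <- c("spring", "summer", "autumn", "winter")

# Classed error so callers/tests can match on condition class rather than on
# message wording.
sc_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sealcount_error", "error")))
}

sc_warn <- function(msg) warning(msg, call. = FALSE)

#' Week of the year from a date
#'
#' Weeks are fixed seven-day bins of the day of year: week `k` spans days
#' `7(k-1)+1` through `7k`, so January 1-7 is always week 1 regardless of
#' weekday.  Days 365 and 366 fall into week 53.
#'
#' @param date a `Date` vector (or something coercible by [as.Date()]).
#' @return integer week numbers in `1..53`.
#' @export
#' @examples
#' week_of_year(as.Date(c("2016-01-01", "2016-01-08", "2016-12-31")))
week_of_year <- function(date) {
  date <- as.Date(date)
  yday <- as.integer(strftime(date, "%j"))
  as.integer((yday - 1L) %/% 7L) + 1L
}

# First calendar day of a fixed seven-day week bin in a given year.
week_start_date <- function(week, year) {
  as.Date(sprintf("%d-01-01", year)) + (week - 1L) * 7L
}

# Seasons a week number can fall in (by the months its days touch).  Used to
# map tag weeks onto survey seasons.
season_of_week <- function(week, year) {
  days <- week_start_date(week, year) + 0:6
  # majority month of the bin decides the season
  seas <- assign_season(days)
  names(sort(table(seas), decreasing = TRUE))[1L]
}

sc_stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    sc_abort(sprintf("`%s` must be a single number in [%s, %s]",
                     name, format(lower), format(upper)),
             "sc_invalid_argument")
  invisible(x)
}
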