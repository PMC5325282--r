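#' Seasonal interval conventions
#'
#' Survival is modelled over 3-month seasonal intervals: Winter (Dec--Feb),
#' Spring (Mar--May), Summer (Jun--Aug) and Fall (Sep--Nov).  December is
#' assigned to the Winter interval labelled by the January year, so
#' Dec 1994 -- Feb 1995 is "Winter 1995"; this keeps the interval sequence
#' contiguous.  Within a labelled year the chronological order is
#' Winter, Spring, Summer, Fall.
#'
#' @name seasons
NULL

#' Season labels in chronological order within a labelled year
#' @export
SEASONS <- c("Winter", "Spring", "Summer", "Fall")

#' Recognised life stages, from fledging to territory tenure
#' @export
STAGES <- c("juvenile", "subadult1", "subadult2", "subadult3",
            "floater", "breeder")

#' Season of a calendar month
#'
#' @param month Integer month (1--12).
#' @return One of `"Winter"`, `"Spring"`, `"Summer"`, `"Fall"`.
#' @examples
#' season_of(12) # "Winter"
#' season_of(6)  # "Summer"
#' @export
season_of <- function(month) {
  if (any(is.na(month)) || any(month < 1L) || any(month > 12L) ||
      any(month != as.integer(month)))
    stop("`month` must be an integer in 1..12", call. = FALSE)
  c("Winter", "Winter", "Spring", "Spring", "Spring",
    "Summer", "Summer", "Summer", "Fall", "Fall", "Fall", "Winter")[month]
}

#' Interval-labelling year of a calendar date
#'
#' December belongs to the following year's Winter interval.
#'
#' @param year Calendar year.
#' @param month Integer month (1--12).
#' @return The year labelling the seasonal interval containing the date.
#' @export
season_year <- function(year, month) {
  ifelse(month == 12L, year + 1L, year)
}

#' Ordinal index of a seasonal interval on a study timeline
#'
#' @param year Interval-labelling year (see [season_year()]).
#' @param season Season label.
#' @param origin_year Year whose Winter interval has index 0.
#' @return 0-based integer index; strictly increasing with time.
#' @export
interval_index <- function(year, season, origin_year) {
  s <- match(season, SEASONS)
  if (any(is.na(s))) stop("unknown season label", call. = FALSE)
  as.integer((year - origin_year) * 4L + s - 1L)
}

#' Year and season of an ordinal interval index
#'
#' Inverse of [interval_index()].
#'
#' @param index 0-based interval index.
#' @param origin_year Year whose Winter interval has index 0.
#' @return Data frame with columns `year` and `season`.
#' @export
interval_at <- function(index, origin_year) {
  data.frame(year = origin_year + index %/% 4L,
             season = SEASONS[index %% 4L + 1L],
             stringsAsFactors = FALSE)
}
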