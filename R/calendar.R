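#' No-take-zone opening calendar
#'
#' A calendar of the inclusive date intervals during which the periodic
#' no-take zone (NTZ) is open to lobster fishing. Outside every interval
#' the NTZ is closed.
#'
#' @param open_start,open_end vectors of interval start/end dates
#'   (anything `as.Date()` accepts). Intervals are inclusive at both ends,
#'   must not overlap, and must be supplied in chronological order.
#' @return An object of class `ntz_calendar`: a data.frame with columns
#'   `open_start` and `open_end`.
#' @examples
#' cal <- ntz_calendar(c("2015-07-01"), c("2015-09-30"))
#' ntz_status(cal, "2015-07-15")
#' @export
ntz_calendar <- function(open_start = character(), open_end = character()) {
  open_start <- as.Date(open_start)
  open_end <- as.Date(open_end)
  if (length(open_start) != length(open_end))
    stop_field("open_end", "start and end vectors differ in length")
  if (any(is.na(open_start)) || any(is.na(open_end)))
    stop_field("open_start", "unparseable date")
  if (any(open_end < open_start))
    stop_field("open_end", "interval ends before it starts")
  if (length(open_start) > 1L) {
    if (is.unsorted(open_start, strictly = TRUE))
      stop_field("open_start", "intervals not in chronological order")
    if (any(open_start[-1L] <= open_end[-length(open_end)]))
      stop_field("open_start", "intervals overlap")
  }
  structure(data.frame(open_start = open_start, open_end = open_end),
            class = c("ntz_calendar", "data.frame"))
}

#' Default NTZ calendar for the Sainte Luce fishery
#'
#' Openings: 2014 August-September; 2015 July-September; 2016 April-May
#' and August-September (all inclusive).
#' @return An [ntz_calendar()].
#' @export
default_ntz_calendar <- function() {
  ntz_calendar(
    open_start = c("2014-08-01", "2015-07-01", "2016-04-01", "2016-08-01"),
    open_end   = c("2014-09-30", "2015-09-30", "2016-05-31", "2016-09-30")
  )
}

#' NTZ open/closed status on a date
#'
#' @param calendar an [ntz_calendar()].
#' @param date date vector.
#' @return Character vector, `"open"` or `"closed"`, one per date.
#' @export
ntz_status <- function(calendar, date) {
  stopifnot(inherits(calendar, "ntz_calendar"))
  date <- as.Date(date)
  if (any(is.na(date))) stop_field("date", "unparseable date")
  out <- rep("closed", length(date))
  for (i in seq_len(nrow(calendar))) {
    out[date >= calendar$open_start[i] & date <= calendar$open_end[i]] <- "open"
  }
  out
}

#' Beach price schedule
#'
#' Step-function schedule of the price fishers receive at first sale,
#' in Malagasy ariary (MGA) per kg. Each price applies from its
#' `effective_from` date until the next one.
#'
#' @param effective_from strictly increasing dates.
#' @param price_mga_per_kg positive prices (MGA per kg).
#' @return An object of class `price_schedule`.
#' @export
price_schedule <- function(effective_from, price_mga_per_kg) {
  effective_from <- as.Date(effective_from)
  if (any(is.na(effective_from))) stop_field("effective_from", "unparseable date")
  if (length(effective_from) != length(price_mga_per_kg))
    stop_field("price_mga_per_kg", "lengths differ")
  if (length(effective_from) == 0L)
    stop_field("effective_from", "schedule is empty")
  if (is.unsorted(effective_from, strictly = TRUE))
    stop_field("effective_from", "dates not strictly increasing")
  if (any(!is.finite(price_mga_per_kg)) || any(price_mga_per_kg <= 0))
    stop_field("price_mga_per_kg", "prices must be positive")
  structure(data.frame(effective_from = effective_from,
                       price_mga_per_kg = as.numeric(price_mga_per_kg)),
            class = c("price_schedule", "data.frame"))
}

#' Default 2015-season price schedule
#'
#' 15,000 MGA per kg up to June 2015, 20,000 MGA per kg from 1 July 2015
#' (the step negotiated at the NTZ opening).
#' @return A [price_schedule()].
#' @export
default_price_schedule <- function() {
  price_schedule(c("2015-01-01", "2015-07-01"), c(15000, 20000))
}

#' Price in force on a date
#'
#' @param schedule a [price_schedule()].
#' @param date date vector; must be on/after the first effective date.
#' @return Numeric vector of prices (MGA per kg).
#' @export
price_at <- function(schedule, date) {
  stopifnot(inherits(schedule, "price_schedule"))
  date <- as.Date(date)
  if (any(is.na(date))) stop_field("date", "unparseable date")
  idx <- findInterval(as.numeric(date), as.numeric(schedule$effective_from))
  if (any(idx == 0L))
    stop_field("date", "before the first effective_from in the schedule")
  schedule$price_mga_per_kg[idx]
}
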