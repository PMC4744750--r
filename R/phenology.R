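#' Count-weighted mean flight date
#'
#' The timing of a flight period at one site in one year is measured as the
#' count-weighted mean day of the transect counts,
#' \eqn{\sum_d c_d d / \sum_d c_d}, an estimate of the date of mean abundance
#' in the adult flight period. Days are numbered from 1 April (day 1).
#'
#' @param day integer days of the visits.
#' @param count non-negative counts on those days.
#' @param window optional day range `c(first, last)` restricting the
#'   computation to one generation (e.g. a spring brood); defaults to the full
#'   season.
#' @return the weighted mean date, or `NA_real_` when no positive count falls
#'   inside the window (a sentinel, not an error, so batch processing
#'   continues).
#' @export
weighted_mean_flight_date <- function(day, count, window = c(1L, 182L)) {
  stopifnot(length(day) == length(count))
  if (any(count < 0, na.rm = TRUE)) stop("counts must be >= 0", call. = FALSE)
  keep <- !is.na(day) & !is.na(count) & day >= window[1] & day <= window[2]
  day <- day[keep]; count <- count[keep]
  tot <- sum(count)
  if (!length(count) || tot <= 0) return(NA_real_)
  sum(count * day) / tot
}

#' Per-species generation window
#'
#' Returns the day range over which mean flight dates are computed for a
#' species, restricting multivoltine species to their first brood or
#' adult-overwintering species to the post-hibernation summer generation.
#' Without configuration the full standard season (days 1-182 from 1 April)
#' is used.
#'
#' @param config optional named list mapping species ids to length-2 day
#'   ranges.
#' @param species_id species to look up.
#' @return integer vector `c(first_day, last_day)`.
#' @export
generation_window <- function(config = NULL, species_id = NULL) {
  win <- c(1L, 182L)
  if (!is.null(config) && !is.null(species_id) &&
      species_id %in% names(config)) {
    win <- as.integer(config[[species_id]])
  }
  if (length(win) != 2L || any(is.na(win)) || win[1] > win[2]) {
    stop("generation window must be a valid day range c(first, last)",
         call. = FALSE)
  }
  win
}

#' Compute flight records from transect counts
#'
#' Collapses a transect count table to one flight record per
#' site-by-year-by-species combination: the count-weighted mean flight date
#' plus the sampling metadata used by the sufficiency filter.
#'
#' @param counts data frame with columns `site_id`, `species_id`, `year`,
#'   `day`, `count`.
#' @param window_config optional per-species generation windows, as accepted
#'   by [generation_window()].
#' @return data frame with columns `site_id`, `species_id`, `year`,
#'   `mean_flight_date`, `total_count`, `n_positive_visits`, `n_visits`,
#'   `span_days`. Site-years with no positive count are dropped.
#' @export
flight_records <- function(counts, window_config = NULL) {
  need <- c("site_id", "species_id", "year", "day", "count")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!nrow(counts)) return(empty_flight_records())
  key <- interaction(counts$site_id, counts$species_id, counts$year,
                     drop = TRUE, lex.order = TRUE)
  pieces <- split(counts, key)
  rows <- lapply(pieces, function(d) {
    win <- generation_window(window_config, d$species_id[1])
    inwin <- d[d$day >= win[1] & d$day <= win[2], , drop = FALSE]
    pos <- inwin[inwin$count > 0, , drop = FALSE]
    mfd <- weighted_mean_flight_date(inwin$day, inwin$count, win)
    if (is.na(mfd)) return(NULL)
    data.frame(
      site_id = d$site_id[1], species_id = d$species_id[1], year = d$year[1],
      mean_flight_date = mfd,
      total_count = sum(pos$count),
      n_positive_visits = nrow(pos),
      n_visits = nrow(inwin),
      span_days = max(pos$day) - min(pos$day),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_flight_records())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_flight_records <- function() {
  data.frame(site_id = character(), species_id = character(), year = integer(),
             mean_flight_date = numeric(), total_count = numeric(),
             n_positive_visits = integer(), n_visits = integer(),
             span_days = numeric(), stringsAsFactors = FALSE)
}

#' Filter flight records for sampling sufficiency
#'
#' Keeps flight records with enough positive visits spread over enough of the
#' season to support a stable weighted mean date: a configurable, explicit
#' stand-in for annual-abundance-index sufficiency rules used with transect
#' monitoring data.
#'
#' @param records a flight-record data frame from [flight_records()].
#' @param min_positive_visits minimum number of visits with a positive count.
#' @param min_span_days minimum span (last minus first positive day), days.
#' @param quiet suppress the kept/dropped log message.
#' @return the filtered data frame.
#' @export
sufficiency_filter <- function(records, min_positive_visits = 3L,
                               min_span_days = 7L, quiet = FALSE) {
  stopifnot(min_positive_visits >= 0, min_span_days >= 0)
  keep <- records$n_positive_visits >= min_positive_visits &
    records$span_days >= min_span_days
  if (!quiet) {
    message(sprintf(
      "sufficiency_filter: kept %d / %d records (min_positive_visits = %d, min_span_days = %d)",
      sum(keep), length(keep), as.integer(min_positive_visits),
      as.integer(min_span_days)
    ))
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
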