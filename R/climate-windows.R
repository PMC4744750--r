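#' Three-month running-mean temperatures
#'
#' For each grid cell and year, computes the mean temperature of every month
#' together with its preceding and following month, labelling each window by
#' its centre month. January windows borrow the previous year's December and
#' December windows borrow the next year's January; windows whose edge months
#' are missing are absent from the output rather than zero-filled.
#'
#' @param temperatures data frame with columns `cell_e`, `cell_n`, `year`,
#'   `month`, `mean_temp_c` (the dialect written by [make_landscape()]).
#' @return data frame `cell_e`, `cell_n`, `year`, `center_month`, `mean_temp`.
#' @export
three_month_running_mean <- function(temperatures) {
  need <- c("cell_e", "cell_n", "year", "month", "mean_temp_c")
  if (!all(need %in% names(temperatures))) {
    stop("temperatures must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cell <- paste(temperatures$cell_e, temperatures$cell_n, sep = "_")
  lin <- temperatures$year * 12L + (temperatures$month - 1L)  # linear month index
  key <- paste(cell, lin, sep = "#")
  if (anyDuplicated(key)) {
    stop("duplicate cell-year-month rows in temperature table", call. = FALSE)
  }
  lookup <- setNames(temperatures$mean_temp_c, key)
  prev <- lookup[paste(cell, lin - 1L, sep = "#")]
  nxt <- lookup[paste(cell, lin + 1L, sep = "#")]
  ok <- !is.na(prev) & !is.na(nxt)
  out <- data.frame(
    cell_e = temperatures$cell_e[ok],
    cell_n = temperatures$cell_n[ok],
    year = temperatures$year[ok],
    center_month = temperatures$month[ok],
    mean_temp = (prev[ok] + temperatures$mean_temp_c[ok] + nxt[ok]) / 3,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$cell_e, out$cell_n, out$year, out$center_month), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign projected coordinates to grid cells
#'
#' Half-open floor-division cell indexing: a coordinate exactly on a boundary
#' belongs to the higher cell.
#'
#' @param coord_m non-negative projected coordinate(s), metres.
#' @param cell_size_m cell side, metres (default 5 km).
#' @return integer cell index (or indices).
#' @export
assign_site_to_cell <- function(coord_m, cell_size_m = 5000) {
  if (any(coord_m < 0, na.rm = TRUE)) {
    stop("coordinates must be >= 0 on the projected grid", call. = FALSE)
  }
  if (cell_size_m <= 0) stop("cell_size_m must be positive", call. = FALSE)
  as.integer(floor(coord_m / cell_size_m))
}

#' Select the most predictive three-month temperature window
#'
#' Fits, for each of the 12 centre months, an ordinary least-squares
#' regression of the national annual mean flight date on the national annual
#' window temperature, and selects the window with the strongest relationship
#' (largest |t|, or largest |coefficient| under the alternative criterion).
#' The national annual mean flight date is the unweighted mean over sites
#' holding a record that year; the national annual window temperature is the
#' unweighted mean over the distinct grid cells of those sites.
#'
#' @param records flight records (one species) from [flight_records()].
#' @param window_temps window temperatures from [three_month_running_mean()].
#' @param sites site table with `site_id`, `easting_m`, `northing_m`.
#' @param criterion `"t_value"` (default) or `"coefficient"`.
#' @param cell_size_m temperature grid cell size, metres.
#' @return an object of class `window_selection`: a list with
#'   `selected_center_month`, `criterion`, and `diagnostics`, a 12-row data
#'   frame (`center_month`, `n_years`, `coefficient`, `se`, `t_value`) with
#'   `NA` rows for windows that could not be fitted. Ties in the criterion
#'   break toward the earlier centre month.
#' @export
select_window <- function(records, window_temps, sites,
                          criterion = c("t_value", "coefficient"),
                          cell_size_m = 5000) {
  criterion <- match.arg(criterion)
  if (!nrow(records)) stop("no flight records supplied", call. = FALSE)

  # national annual mean flight date
  nat_date <- aggregate(mean_flight_date ~ year, data = records, FUN = mean)

  site_cells <- data.frame(
    site_id = sites$site_id,
    cell_e = assign_site_to_cell(sites$easting_m, cell_size_m),
    cell_n = assign_site_to_cell(sites$northing_m, cell_size_m),
    stringsAsFactors = FALSE
  )
  rec_cells <- merge(unique(records[, c("site_id", "year")]), site_cells,
                     by = "site_id")
  rec_cells <- unique(rec_cells[, c("year", "cell_e", "cell_n")])

  diagnostics <- data.frame(center_month = 1:12, n_years = 0L,
                            coefficient = NA_real_, se = NA_real_,
                            t_value = NA_real_)
  for (m in 1:12) {
    wt <- window_temps[window_temps$center_month == m, , drop = FALSE]
    if (!nrow(wt)) next
    cellyear <- merge(rec_cells, wt, by = c("year", "cell_e", "cell_n"))
    if (!nrow(cellyear)) next
    nat_temp <- aggregate(mean_temp ~ year, data = cellyear, FUN = mean)
    d <- merge(nat_date, nat_temp, by = "year")
    diagnostics$n_years[m] <- nrow(d)
    if (nrow(d) < 3) next
    if (var(d$mean_temp) <= 0) {
      warning(sprintf("window %d has zero temperature variance; excluded", m),
              call. = FALSE)
      next
    }
    fit <- lm(mean_flight_date ~ mean_temp, data = d)
    sm <- summary(fit)$coefficients
    slope <- sm["mean_temp", "Estimate"]
    se <- sm["mean_temp", "Std. Error"]
    diagnostics$coefficient[m] <- slope
    diagnostics$se[m] <- se
    diagnostics$t_value[m] <- if (se > 0) slope / se else sign(slope) * Inf
  }
  usable <- which(!is.na(diagnostics$coefficient))
  if (!length(usable)) {
    stop("fewer than 3 usable years in every window", call. = FALSE)
  }
  score <- abs(if (criterion == "t_value") diagnostics$t_value
               else diagnostics$coefficient)
  best <- usable[which.max(score[usable])]  # which.max takes the first (earlier month) on ties
  structure(list(
    selected_center_month = as.integer(best),
    criterion = criterion,
    diagnostics = diagnostics
  ), class = "window_selection")
}

#' @export
print.window_selection <- function(x, ...) {
  cat(sprintf("Window selection (criterion: %s)\n", x$criterion))
  cat(sprintf("Selected centre month: %d\n", x$selected_center_month))
  print(x$diagnostics, digits = 4)
  invisible(x)
}
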