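#' Read and write the pipeline's CSV dialects
#'
#' All tables travel as UTF-8 comma-separated files with a header row:
#' counts (`site_id,species_id,year,day,count`), sites
#' (`site_id,easting_m,northing_m`), monthly temperatures
#' (`cell_e,cell_n,year,month,mean_temp_c`), flight records and species
#' summaries as written by [run_pipeline()]. Trees are newick with branch
#' lengths.
#'
#' @param path file path.
#' @return a data frame (readers) or the path, invisibly (writers).
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_counts_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "species_id", "year", "day", "count")
  if (!all(need %in% names(d))) {
    stop("counts CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  d
}

#' @rdname pipeline_io
#' @export
read_sites_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "easting_m", "northing_m")
  if (!all(need %in% names(d))) {
    stop("sites CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  d
}

#' @rdname pipeline_io
#' @export
read_temperatures_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_e", "cell_n", "year", "month", "mean_temp_c")
  if (!all(need %in% names(d))) {
    stop("temperatures CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  d
}

#' @rdname pipeline_io
#' @param x data frame to write.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_trees_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "phylo")) tr <- list(tr)
  for (t in tr) {
    if (is.null(t$edge.length)) {
      stop("newick trees must carry branch lengths", call. = FALSE)
    }
  }
  tr
}

#' Day-of-season to calendar date conversion
#'
#' The package's day unit starts at 1 April (day 1); these helpers convert at
#' the I/O boundary only.
#'
#' @param day day of season (1 = 1 April).
#' @param year calendar year.
#' @return a `Date` (or a day of season for the inverse).
#' @export
season_day_to_date <- function(day, year) {
  as.Date(sprintf("%d-04-01", year)) + (day - 1)
}

#' @rdname season_day_to_date
#' @param date a `Date`.
#' @export
date_to_season_day <- function(date) {
  yr <- as.integer(format(date, "%Y"))
  as.integer(date - as.Date(sprintf("%d-04-01", yr))) + 1L
}

#' Published species-level slope estimates for UK butterflies
#'
#' Modal within-population (temporal) and among-population (spatial) slopes of
#' mean flight date on three-month temperature, with 95% intervals, for the
#' 31 resident univoltine/first-brood British butterfly species analysed in a
#' national monitoring-scheme study. Shipped as a plain-text reference table
#' for convention and decision-rule checks; the underlying monitoring data are
#' not included.
#'
#' @return data frame with one row per species: sample sizes, selected window
#'   month, and mode plus interval bounds for `b_time`, `b_space` and
#'   `delta_b` (days per degC).
#' @export
uk_butterfly_slopes <- function() {
  path <- system.file("extdata", "uk_butterfly_slopes.csv",
                      package = "phenodecomp", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
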