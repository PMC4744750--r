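#' Specify a synthetic monitoring landscape
#'
#' Bundles the parameters of the synthetic landscape generator: how many
#' transect sites to scatter, the spatial extent, the south-north temperature
#' gradient, and the magnitudes of the shared interannual anomaly and
#' independent month-level noise. Defaults emulate a UK-like monitoring
#' landscape: roughly a 1000-km extent, a latitudinal gradient of about
#' -5 degC per 1000 km, interannual anomalies of ~1 degC shared across the
#' whole region, and a seasonal cycle peaking in July.
#'
#' @param n_sites number of transect sites (>= 1).
#' @param extent_m extent of the square landscape per axis, metres.
#' @param temp_south_north_gradient temperature change per 1000 km of
#'   northing, degC (negative = cooler north).
#' @param annual_anomaly_sd SD (degC) of the year anomaly shared by all grid
#'   cells and months within a year.
#' @param month_noise_sd SD (degC) of the month-by-year anomaly shared by all
#'   grid cells (regionally coherent monthly weather). This is what lets a
#'   particular three-month window be identified from regionally averaged
#'   series: a purely cell-local noise would cancel in the regional mean and
#'   leave all windows carrying the same annual anomaly.
#' @param cell_noise_sd SD (degC) of independent cell-by-year-by-month
#'   residual noise on top of the shared components.
#' @param seasonal_amplitude amplitude (degC) of the sinusoidal seasonal
#'   cycle around `base_temp_c`.
#' @param base_temp_c annual mean temperature at northing 0, degC.
#' @param year_range inclusive integer span of monitoring years (>= 2 years).
#'   The generated temperature table additionally covers the year before the
#'   first and after the last so that edge running-mean windows exist.
#' @param cell_size_m side of the temperature grid cells, metres.
#' @return an object of class `landscape_spec`.
#' @seealso [make_landscape()]
#' @export
landscape_spec <- function(n_sites = 50,
                           extent_m = 1e6,
                           temp_south_north_gradient = -5,
                           annual_anomaly_sd = 1,
                           month_noise_sd = 0.8,
                           cell_noise_sd = 0.4,
                           seasonal_amplitude = 6,
                           base_temp_c = 9,
                           year_range = 1980:2009,
                           cell_size_m = 5000) {
  if (!is.numeric(n_sites) || n_sites < 1) {
    stop("n_sites must be >= 1", call. = FALSE)
  }
  if (!is.numeric(extent_m) || extent_m <= 0) {
    stop("extent_m must be positive", call. = FALSE)
  }
  sds <- c(annual_anomaly_sd, month_noise_sd, cell_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("noise SDs must be finite and >= 0", call. = FALSE)
  }
  year_range <- sort(unique(as.integer(year_range)))
  if (length(year_range) < 2) {
    stop("year_range must span at least 2 years", call. = FALSE)
  }
  if (cell_size_m <= 0) stop("cell_size_m must be positive", call. = FALSE)
  structure(list(
    n_sites = as.integer(n_sites), extent_m = extent_m,
    temp_south_north_gradient = temp_south_north_gradient,
    annual_anomaly_sd = annual_anomaly_sd, month_noise_sd = month_noise_sd,
    cell_noise_sd = cell_noise_sd,
    seasonal_amplitude = seasonal_amplitude, base_temp_c = base_temp_c,
    year_range = year_range, cell_size_m = cell_size_m
  ), class = "landscape_spec")
}

#' Generate a synthetic landscape of sites and monthly temperatures
#'
#' Scatters transect sites uniformly over a square projected extent and builds
#' a monthly mean-temperature table for every 5-km-style grid cell containing
#' a site. Cell temperature is the sum of a seasonal sine cycle, a linear
#' south-north gradient evaluated at the cell centroid, a year anomaly shared
#' across all cells and months of that year, a month-by-year anomaly shared
#' across cells, and independent cell-level month noise. Temperatures cover
#' the year before the first monitoring year
#' through the year after the last, so three-month running means exist for
#' every monitoring year.
#'
#' @param spec a [landscape_spec()].
#' @param seed integer RNG seed; the function is deterministic given
#'   `(spec, seed)`.
#' @param site_coords optional data frame with columns `easting_m`,
#'   `northing_m` (and optionally `site_id`) to place sites deterministically
#'   instead of sampling them.
#' @return a list with elements `sites` (data frame `site_id`, `easting_m`,
#'   `northing_m`) and `temperatures` (data frame `cell_e`, `cell_n`, `year`,
#'   `month`, `mean_temp_c`).
#' @export
make_landscape <- function(spec, seed = 1L, site_coords = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(as.integer(seed))
  if (is.null(site_coords)) {
    sites <- data.frame(
      site_id = sprintf("S%03d", seq_len(spec$n_sites)),
      easting_m = runif(spec$n_sites, 0, spec$extent_m),
      northing_m = runif(spec$n_sites, 0, spec$extent_m),
      stringsAsFactors = FALSE
    )
  } else {
    stopifnot(all(c("easting_m", "northing_m") %in% names(site_coords)))
    sites <- data.frame(
      site_id = if ("site_id" %in% names(site_coords)) {
        as.character(site_coords$site_id)
      } else {
        sprintf("S%03d", seq_len(nrow(site_coords)))
      },
      easting_m = site_coords$easting_m,
      northing_m = site_coords$northing_m,
      stringsAsFactors = FALSE
    )
  }
  if (any(sites$easting_m < 0) || any(sites$northing_m < 0)) {
    stop("site coordinates must be non-negative on the projected grid",
         call. = FALSE)
  }

  cells <- unique(data.frame(
    cell_e = assign_site_to_cell(sites$easting_m, spec$cell_size_m),
    cell_n = assign_site_to_cell(sites$northing_m, spec$cell_size_m)
  ))
  years <- (min(spec$year_range) - 1L):(max(spec$year_range) + 1L)
  months <- 1:12

  grid <- expand.grid(cell_i = seq_len(nrow(cells)), year = years,
                      month = months, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$cell_i, grid$year, grid$month), , drop = FALSE]

  anomaly <- setNames(rnorm(length(years), 0, spec$annual_anomaly_sd),
                      as.character(years))
  month_key <- paste(rep(years, each = 12), rep(months, length(years)))
  month_anomaly <- setNames(rnorm(length(month_key), 0, spec$month_noise_sd),
                            month_key)
  centroid_n <- (cells$cell_n + 0.5) * spec$cell_size_m
  seasonal <- spec$base_temp_c +
    spec$seasonal_amplitude * cos(2 * pi * (grid$month - 7) / 12)
  gradient <- spec$temp_south_north_gradient / 1e6 * centroid_n[grid$cell_i]
  noise <- unname(month_anomaly[paste(grid$year, grid$month)]) +
    rnorm(nrow(grid), 0, spec$cell_noise_sd)

  temperatures <- data.frame(
    cell_e = cells$cell_e[grid$cell_i],
    cell_n = cells$cell_n[grid$cell_i],
    year = grid$year,
    month = grid$month,
    mean_temp_c = seasonal + gradient + anomaly[as.character(grid$year)] + noise,
    stringsAsFactors = FALSE
  )
  rownames(temperatures) <- NULL
  list(sites = sites, temperatures = temperatures)
}
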