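#' Specify a simulated species' phenological response
#'
#' Ground-truth parameters of one simulated species: the baseline mean flight
#' date, the within-population (plastic) slope `b_time`, the local-adaptation
#' difference `delta_b` (so the among-population slope is
#' `b_space = b_time + delta_b`), the three-month cue window driving the
#' response, the width of the flight curve, expected seasonal abundance, and
#' the SDs of the population, year and residual deviations of the latent mean
#' flight date.
#'
#' @param species_id species label.
#' @param mu0 baseline mean flight date, days since 31 March (day 1 = 1 April).
#' @param b_time within-population slope, days per degC.
#' @param delta_b local-adaptation slope difference, days per degC.
#' @param cue_window centre month (1-12) of the driving three-month window.
#' @param flight_sd SD of the Gaussian flight curve, days (> 0).
#' @param site_abundance_mean expected seasonal total count per site-year
#'   (>= 0).
#' @param pop_date_sd,year_date_sd,resid_date_sd SDs (days) of the population,
#'   year and residual deviations of the latent mean date.
#' @return an object of class `species_sim`.
#' @export
species_sim <- function(species_id = "sp1",
                        mu0 = 60,
                        b_time = -6.4,
                        delta_b = 2.4,
                        cue_window = 4L,
                        flight_sd = 10,
                        site_abundance_mean = 200,
                        pop_date_sd = 3,
                        year_date_sd = 2,
                        resid_date_sd = 5) {
  if (!is.finite(flight_sd) || flight_sd <= 0) {
    stop("flight_sd must be > 0", call. = FALSE)
  }
  if (site_abundance_mean < 0) {
    stop("site_abundance_mean must be >= 0", call. = FALSE)
  }
  cue_window <- as.integer(cue_window)
  if (cue_window < 1L || cue_window > 12L) {
    stop("cue_window must be a month in 1..12", call. = FALSE)
  }
  sds <- c(pop_date_sd, year_date_sd, resid_date_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("date SDs must be finite and >= 0", call. = FALSE)
  }
  structure(list(
    species_id = as.character(species_id), mu0 = mu0, b_time = b_time,
    delta_b = delta_b, cue_window = cue_window, flight_sd = flight_sd,
    site_abundance_mean = site_abundance_mean, pop_date_sd = pop_date_sd,
    year_date_sd = year_date_sd, resid_date_sd = resid_date_sd
  ), class = "species_sim")
}

#' Simulate transect counts with known phenological ground truth
#'
#' Generates weekly (by default) transect counts for one species over a
#' synthetic landscape. For site s in year y the latent mean flight date is
#'
#' \deqn{\mu_{sy} = \mu_0 + b_{time} (T_{sy} - \bar T_s) +
#'   (b_{time} + \Delta b)(\bar T_s - \bar T) + u_{pop(s)} + v_y + e_{sy}}
#'
#' where \eqn{T_{sy}} is the site's cue-window three-month mean temperature,
#' \eqn{\bar T_s} its across-year mean and \eqn{\bar T} the grand mean over
#' sites. Counts on each scheduled visit day are Poisson (or negative
#' binomial) with mean proportional to a Gaussian flight curve centred on
#' \eqn{\mu_{sy}}, scaled so the expected seasonal total equals
#' `site_abundance_mean`.
#'
#' @param sites site table from [make_landscape()].
#' @param temperatures monthly temperature table from [make_landscape()].
#' @param sim a [species_sim()].
#' @param visit_schedule integer days of scheduled visits; default weekly
#'   visits on days 1, 8, ..., 176 (26 recording weeks from 1 April).
#' @param seed integer RNG seed.
#' @param pop_grid_m population aggregation grid used to draw the population
#'   effect, metres (default 50 km).
#' @param cell_size_m temperature grid cell size, metres.
#' @param nb_dispersion optional negative-binomial dispersion; `NULL` (the
#'   default) gives Poisson counts, otherwise counts are negative binomial
#'   with `size = 1/nb_dispersion` (variance `mu + dispersion * mu^2`).
#' @return a list with `counts` (data frame `site_id`, `species_id`, `year`,
#'   `day`, `count`) and `truth`, a list echoing the `species_sim` parameters
#'   together with the realized site-to-population map, per-site and
#'   per-population mean cue temperatures, and the latent table of
#'   site-by-year cue temperatures and mean dates.
#' @export
simulate_counts <- function(sites, temperatures, sim,
                            visit_schedule = seq(1L, 176L, by = 7L),
                            seed = 1L,
                            pop_grid_m = 50000,
                            cell_size_m = 5000,
                            nb_dispersion = NULL) {
  stopifnot(inherits(sim, "species_sim"))
  set.seed(as.integer(seed))
  visit_schedule <- sort(unique(as.integer(visit_schedule)))

  windows <- three_month_running_mean(temperatures)
  wt <- windows[windows$center_month == sim$cue_window, , drop = FALSE]

  site_cells <- data.frame(
    site_id = sites$site_id,
    cell_e = assign_site_to_cell(sites$easting_m, cell_size_m),
    cell_n = assign_site_to_cell(sites$northing_m, cell_size_m),
    stringsAsFactors = FALSE
  )
  years <- sort(unique(temperatures$year))
  years <- years[-c(1, length(years))]  # interior years have full window coverage
  if (length(years) < 1) stop("temperature table covers too few years", call. = FALSE)

  latent <- merge(
    expand.grid(site_id = sites$site_id, year = years,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    site_cells, by = "site_id"
  )
  latent <- merge(latent, wt, by = c("cell_e", "cell_n", "year"),
                  all.x = TRUE)
  if (any(is.na(latent$mean_temp))) {
    bad <- latent[is.na(latent$mean_temp), c("site_id", "year")]
    stop(sprintf(
      "missing cue-window temperature for %d site-years (first: site %s, year %d)",
      nrow(bad), bad$site_id[1], bad$year[1]
    ), call. = FALSE)
  }
  latent <- latent[order(latent$site_id, latent$year), , drop = FALSE]

  site_mean <- tapply(latent$mean_temp, latent$site_id, mean)
  grand_mean <- mean(site_mean)
  latent$t_site_mean <- as.numeric(site_mean[latent$site_id])

  pops <- aggregate_populations(sites, pop_grid_m)
  pop_of <- setNames(pops$population_id, pops$site_id)
  latent$population_id <- as.character(pop_of[latent$site_id])

  pop_levels <- sort(unique(latent$population_id))
  u_pop <- setNames(rnorm(length(pop_levels), 0, sim$pop_date_sd), pop_levels)
  v_year <- setNames(rnorm(length(years), 0, sim$year_date_sd),
                     as.character(years))
  e_sy <- rnorm(nrow(latent), 0, sim$resid_date_sd)

  latent$mu_sy <- sim$mu0 +
    sim$b_time * (latent$mean_temp - latent$t_site_mean) +
    (sim$b_time + sim$delta_b) * (latent$t_site_mean - grand_mean) +
    u_pop[latent$population_id] + v_year[as.character(latent$year)] + e_sy

  nv <- length(visit_schedule)
  wm <- vapply(latent$mu_sy,
               function(m) dnorm(visit_schedule, m, sim$flight_sd),
               numeric(nv))                      # nv x n_site_years
  ws <- colSums(wm)
  lam <- sweep(wm, 2, ifelse(ws > 0, ws, 1), "/") * sim$site_abundance_mean
  lam[, ws == 0] <- 0
  lambda <- as.vector(lam)                       # visits vary fastest
  counts <- if (is.null(nb_dispersion)) {
    rpois(length(lambda), lambda)
  } else {
    stopifnot(nb_dispersion > 0)
    rnbinom(length(lambda), mu = lambda, size = 1 / nb_dispersion)
  }

  counts_df <- data.frame(
    site_id = rep(latent$site_id, each = nv),
    species_id = sim$species_id,
    year = rep(latent$year, each = nv),
    day = rep(visit_schedule, nrow(latent)),
    count = counts,
    stringsAsFactors = FALSE
  )

  pop_mean_temp <- tapply(latent$mean_temp, latent$population_id, mean)
  truth <- list(
    sim = sim,
    site_population = pops,
    site_mean_temp = data.frame(site_id = names(site_mean),
                                mean_temp = as.numeric(site_mean),
                                stringsAsFactors = FALSE),
    population_mean_temp = data.frame(population_id = names(pop_mean_temp),
                                      mean_temp = as.numeric(pop_mean_temp),
                                      stringsAsFactors = FALSE),
    grand_mean_temp = grand_mean,
    latent = latent[, c("site_id", "population_id", "year", "mean_temp",
                        "t_site_mean", "mu_sy")]
  )
  list(counts = counts_df, truth = truth)
}
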