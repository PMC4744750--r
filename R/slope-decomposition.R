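#' Aggregate sites into populations on a square grid
#'
#' Populations are defined by overlaying a north-south/east-west grid (50 km
#' by default) on the projected site coordinates; a grid size of 0 keeps every
#' site as its own population (site-level analysis).
#'
#' @param sites data frame with `site_id`, `easting_m`, `northing_m`.
#' @param grid_size_m aggregation grid side, metres; 0 for site-level.
#' @return data frame `site_id`, `population_id`.
#' @export
aggregate_populations <- function(sites, grid_size_m = 50000) {
  if (grid_size_m < 0) stop("grid_size_m must be >= 0", call. = FALSE)
  if (grid_size_m == 0) {
    return(data.frame(site_id = sites$site_id,
                      population_id = paste0("site:", sites$site_id),
                      stringsAsFactors = FALSE))
  }
  e <- assign_site_to_cell(sites$easting_m, grid_size_m)
  n <- assign_site_to_cell(sites$northing_m, grid_size_m)
  data.frame(site_id = sites$site_id,
             population_id = sprintf("p%d_%d", e, n),
             stringsAsFactors = FALSE)
}

#' Build paired (temperature, flight date) observations
#'
#' Joins each site-year flight record to its selected-window temperature and
#' its population label, producing the unit of analysis of the bivariate
#' mixed model: one row per site-year with both responses.
#'
#' @param records flight records (one species).
#' @param window_temps window temperatures from [three_month_running_mean()].
#' @param sites site table.
#' @param center_month selected window centre month (1-12).
#' @param pop_grid_m population aggregation grid, metres (0 = site-level).
#' @param cell_size_m temperature grid cell size, metres.
#' @return data frame `population_id`, `site_id`, `year`, `temp`, `phen`.
#'   Site-years without a window temperature are dropped.
#' @export
paired_observations <- function(records, window_temps, sites, center_month,
                                pop_grid_m = 50000, cell_size_m = 5000) {
  stopifnot(center_month %in% 1:12)
  site_cells <- data.frame(
    site_id = sites$site_id,
    cell_e = assign_site_to_cell(sites$easting_m, cell_size_m),
    cell_n = assign_site_to_cell(sites$northing_m, cell_size_m),
    stringsAsFactors = FALSE
  )
  pops <- aggregate_populations(sites, pop_grid_m)
  wt <- window_temps[window_temps$center_month == center_month, , drop = FALSE]
  d <- merge(records, site_cells, by = "site_id")
  d <- merge(d, wt, by = c("cell_e", "cell_n", "year"))
  d <- merge(d, pops, by = "site_id")
  out <- data.frame(population_id = d$population_id, site_id = d$site_id,
                    year = d$year, temp = d$mean_temp,
                    phen = d$mean_flight_date, stringsAsFactors = FALSE)
  out <- out[is.finite(out$temp) & is.finite(out$phen), , drop = FALSE]
  out <- out[order(out$population_id, out$site_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Inverse-Wishart prior specification for (co)variance components
#'
#' Weakly informative default matching common practice for bivariate variance
#' components: scale matrix `V = I` (2 x 2) and degree of belief
#' `nu = 0.002`, applied to every random term and the residual.
#'
#' @param V scale matrix (p x p, positive-definite) or a scalar expanded to
#'   `diag(V, p)`.
#' @param nu degree of belief (> 0).
#' @param p response dimension used to expand a scalar `V`.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(V = 1, nu = 0.002, p = 2L) {
  if (is.matrix(V)) {
    Vm <- V
  } else {
    Vm <- diag(as.numeric(V), p)
  }
  if (nu <= 0) stop("nu must be > 0", call. = FALSE)
  ev <- eigen(Vm, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("V must be positive-definite", call. = FALSE)
  structure(list(V = Vm, nu = nu), class = "prior_spec")
}

#' Fit the bivariate Bayesian mixed model of temperature and flight date
#'
#' Treats the site-year window temperature and mean flight date as a
#' bivariate response with intercept-only fixed effects and crossed
#' population, year and residual (co)variance matrices, and samples the
#' posterior by a fully conjugate Gibbs sampler: bivariate fixed means from
#' their Gaussian full conditional (flat prior), population and year random
#' effects from multivariate-normal full conditionals, and each 2 x 2
#' covariance matrix from its inverse-Wishart full conditional.
#'
#' @param obs paired observations from [paired_observations()] (columns
#'   `population_id`, `year`, `temp`, `phen`); or, for the univariate
#'   sub-case, a data frame with a single response column named `phen` and
#'   any subset of the grouping columns.
#' @param prior a [prior_spec()]; the same prior is applied to every term.
#' @param n_iter total Gibbs iterations (default 13000).
#' @param burn_in discarded initial iterations (default 3000).
#' @param thin retention stride (default 10, giving 1000 retained draws under
#'   the defaults).
#' @param seed integer RNG seed.
#' @param terms character vector of grouping columns to fit as random terms
#'   (default `c("population_id", "year")`).
#' @param responses character vector of response columns (default
#'   `c("temp", "phen")`).
#' @return an object of class `bivariate_vcv`: retained draws of the fixed
#'   means (`mu`, draws x p), a named list `sigma` of p x p x draws arrays
#'   for each random term plus `"residual"`, effective sample sizes of the
#'   variance components, and the sampler log.
#' @export
fit_bivariate_mixed <- function(obs, prior = prior_spec(), n_iter = 13000L,
                                burn_in = 3000L, thin = 10L, seed = 1L,
                                terms = c("population_id", "year"),
                                responses = c("temp", "phen")) {
  stopifnot(inherits(prior, "prior_spec"))
  terms <- terms[terms %in% names(obs)]
  if (!length(terms)) stop("no grouping columns found in obs", call. = FALSE)
  if (!all(responses %in% names(obs))) {
    stop("missing response columns: ",
         paste(setdiff(responses, names(obs)), collapse = ", "), call. = FALSE)
  }
  Y <- as.matrix(obs[, responses, drop = FALSE])
  storage.mode(Y) <- "double"
  if (any(!is.finite(Y))) stop("responses must be finite", call. = FALSE)
  p <- ncol(Y)
  if ("temp" %in% responses && var(Y[, "temp"]) == 0) {
    stop("degenerate input: all temperatures identical", call. = FALSE)
  }
  groups <- lapply(terms, function(tm) {
    f <- factor(obs[[tm]])
    if (nlevels(f) < 2) {
      stop(sprintf("random term '%s' needs >= 2 levels", tm), call. = FALSE)
    }
    list(codes = as.integer(f) - 1L, levels = levels(f))
  })
  V <- prior$V
  if (nrow(V) != p) V <- diag(diag(prior$V)[1], p)

  set.seed(as.integer(seed))
  res <- mv_mixed_gibbs_cpp(Y, lapply(groups, `[[`, "codes"), V, prior$nu,
                            as.integer(n_iter), as.integer(burn_in),
                            as.integer(thin))
  sigma <- res$sigma_terms
  names(sigma) <- terms
  sigma$residual <- res$sigma_res
  for (nm in names(sigma)) {
    dimnames(sigma[[nm]]) <- list(responses, responses, NULL)
  }
  colnames(res$mu) <- responses
  ess <- vapply(names(sigma), function(nm) {
    effective_sample_size(sigma[[nm]][p, p, ])
  }, numeric(1))
  if (res$n_jitter > 0) {
    warning(sprintf("%d numerically non-PD updates were jittered",
                    res$n_jitter), call. = FALSE)
  }
  structure(list(
    mu = res$mu, sigma = sigma, responses = responses, terms = terms,
    n_obs = nrow(Y), n_levels = vapply(groups, function(g) length(g$levels),
                                       integer(1)),
    log = list(seed = as.integer(seed), n_iter = n_iter, burn_in = burn_in,
               thin = thin, n_retained = res$n_keep,
               update_order = c("random effects", "fixed means",
                                "covariance matrices"),
               ess = ess, n_jitter = res$n_jitter)
  ), class = "bivariate_vcv")
}

#' @export
print.bivariate_vcv <- function(x, ...) {
  cat(sprintf(
    "Bivariate mixed model fit: %d obs, responses (%s), %d retained draws\n",
    x$n_obs, paste(x$responses, collapse = ", "), x$log$n_retained
  ))
  for (nm in names(x$sigma)) {
    cat(sprintf("\nPosterior mean Sigma[%s]:\n", nm))
    print(apply(x$sigma[[nm]], c(1, 2), mean), digits = 4)
  }
  invisible(x)
}

#' Derive slope posteriors from covariance draws
#'
#' For each retained draw, the regression slope of flight date on temperature
#' at a level of the model is the covariance between temperature and flight
#' date divided by the temperature variance of that level's covariance
#' matrix: the year term gives the within-population slope `b_time`
#' (plasticity), the population term the among-population slope `b_space`,
#' and `delta_b = b_space - b_time` estimates the direction and strength of
#' temperature-mediated local adaptation.
#'
#' @param fit a `bivariate_vcv` from [fit_bivariate_mixed()].
#' @param time_term,space_term names of the random terms carrying the
#'   temporal and spatial covariance (defaults `"year"`, `"population_id"`).
#' @return an object of class `slope_posterior`: per-draw vectors `b_time`,
#'   `b_space`, `delta_b`, mode/HPD summaries of each, and the number of
#'   draws excluded for non-positive temperature variance.
#' @export
slopes_from_vcv <- function(fit, time_term = "year",
                            space_term = "population_id") {
  stopifnot(inherits(fit, "bivariate_vcv"))
  ratio <- function(arr) arr[1, 2, ] / arr[1, 1, ]
  tvar_ok <- fit$sigma[[time_term]][1, 1, ] > 0 &
    fit$sigma[[space_term]][1, 1, ] > 0
  n_excluded <- sum(!tvar_ok)
  if (n_excluded > 0) {
    warning(sprintf("%d draws with non-positive temperature variance excluded",
                    n_excluded), call. = FALSE)
  }
  b_time <- ratio(fit$sigma[[time_term]])[tvar_ok]
  b_space <- ratio(fit$sigma[[space_term]])[tvar_ok]
  delta_b <- b_space - b_time
  structure(list(
    b_time = b_time, b_space = b_space, delta_b = delta_b,
    summary = list(b_time = summarize_posterior(b_time),
                   b_space = summarize_posterior(b_space),
                   delta_b = summarize_posterior(delta_b)),
    n_excluded = n_excluded
  ), class = "slope_posterior")
}

#' @export
print.slope_posterior <- function(x, ...) {
  cat("Slope posterior (days per degC)\n")
  for (nm in c("b_time", "b_space", "delta_b")) {
    s <- x$summary[[nm]]
    cat(sprintf("  %-8s mode %7.2f  95%% HPD [%7.2f, %7.2f]\n",
                nm, s$mode, s$hpd[1], s$hpd[2]))
  }
  invisible(x)
}
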