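# Shared fixtures built in code.

# A small quiet landscape: no noise unless asked for.
quiet_landscape_spec <- function(n_sites = 4, gradient = 0, anomaly_sd = 0,
                                 month_sd = 0, cell_sd = 0, years = 2000:2004,
                                 extent_m = 1e6) {
  landscape_spec(
    n_sites = n_sites, extent_m = extent_m,
    temp_south_north_gradient = gradient, annual_anomaly_sd = anomaly_sd,
    month_noise_sd = month_sd, cell_noise_sd = cell_sd, year_range = years
  )
}

# Deterministic site placement on a vertical line of northings.
line_sites <- function(northings_m, easting_m = 2500) {
  data.frame(site_id = sprintf("L%02d", seq_along(northings_m)),
             easting_m = easting_m, northing_m = northings_m,
             stringsAsFactors = FALSE)
}

# A balanced two-level dataset drawn exactly from the bivariate mixed model.
simulate_bivariate_model <- function(n_pop, n_year, Sig_pop, Sig_year,
                                     Sig_res, mu = c(9, 140), seed = 1) {
  set.seed(seed)
  rmv <- function(n, S) {
    L <- chol(S)
    matrix(rnorm(n * nrow(S)), n) %*% L
  }
  u <- rmv(n_pop, Sig_pop)
  v <- rmv(n_year, Sig_year)
  idx <- expand.grid(p = seq_len(n_pop), t = seq_len(n_year))
  Y <- u[idx$p, , drop = FALSE] + v[idx$t, , drop = FALSE] +
    rmv(nrow(idx), Sig_res)
  data.frame(population_id = sprintf("p%03d", idx$p),
             year = idx$t, temp = mu[1] + Y[, 1], phen = mu[2] + Y[, 2],
             stringsAsFactors = FALSE)
}

# A random ultrametric tree with reproducible tip labels.
fixture_tree <- function(n_tips = 31, seed = 42) {
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}
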