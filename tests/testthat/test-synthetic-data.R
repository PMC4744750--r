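test_that("with all stochastic terms off, every cell shares one temperature series", {
  spec <- quiet_landscape_spec(n_sites = 6)
  land <- make_landscape(spec, seed = 1)
  series <- split(land$temperatures$mean_temp_c,
                  paste(land$temperatures$cell_e, land$temperatures$cell_n))
  expect_gt(length(series), 1)
  for (s in series) expect_equal(s, series[[1]])
})

test_that("a pure latitudinal gradient separates sites by exact arithmetic", {
  # -5 degC per 1000 km; sites 500 km apart in northing at the same
  # within-cell offset differ by exactly 2.5 degC in every month
  spec <- quiet_landscape_spec(gradient = -5)
  land <- make_landscape(spec, seed = 1,
                         site_coords = line_sites(c(100000, 600000)))
  tt <- land$temperatures
  cell_n <- assign_site_to_cell(c(100000, 600000), 5000)
  s1 <- tt$mean_temp_c[tt$cell_n == cell_n[1]]
  s2 <- tt$mean_temp_c[tt$cell_n == cell_n[2]]
  expect_equal(s1 - s2, rep(2.5, length(s1)))
})

test_that("landscape generation is deterministic given the seed", {
  spec <- landscape_spec(n_sites = 10, year_range = 2000:2003)
  l1 <- make_landscape(spec, seed = 9)
  l2 <- make_landscape(spec, seed = 9)
  expect_identical(l1, l2)
  l3 <- make_landscape(spec, seed = 10)
  expect_false(identical(l1$temperatures$mean_temp_c,
                         l3$temperatures$mean_temp_c))
})

test_that("landscape spec rejects invalid inputs", {
  expect_error(landscape_spec(extent_m = 0), "extent")
  expect_error(landscape_spec(year_range = 2000), "2 years")
  expect_error(landscape_spec(annual_anomaly_sd = -1), "SD")
  expect_error(species_sim(flight_sd = 0), "flight_sd")
  expect_error(species_sim(cue_window = 13), "cue_window")
})

test_that("zero expected abundance yields all-zero counts", {
  land <- make_landscape(quiet_landscape_spec(), seed = 2)
  sim <- species_sim(site_abundance_mean = 0)
  out <- simulate_counts(land$sites, land$temperatures, sim, seed = 3)
  expect_true(all(out$counts$count == 0))
})

test_that("noise-free dense sampling recovers the baseline mean date", {
  # all date SDs 0, no local adaptation, flat temperatures: every site-year
  # weighted mean should sit at mu0 up to Poisson discretisation
  land <- make_landscape(quiet_landscape_spec(n_sites = 3, years = 2000:2004),
                         seed = 4)
  sim <- species_sim(mu0 = 60, b_time = 0, delta_b = 0, flight_sd = 10,
                     site_abundance_mean = 5000, pop_date_sd = 0,
                     year_date_sd = 0, resid_date_sd = 0)
  out <- simulate_counts(land$sites, land$temperatures, sim,
                         visit_schedule = 1:182, seed = 5)
  rec <- flight_records(out$counts)
  expect_true(all(abs(rec$mean_flight_date - 60) < 0.5))
  expect_equal(out$truth$latent$mu_sy, rep(60, nrow(out$truth$latent)))
})

test_that("regression on the latent dates recovers the within-population slope", {
  spec <- landscape_spec(n_sites = 40, extent_m = 1.2e6,
                         temp_south_north_gradient = -5,
                         annual_anomaly_sd = 1, month_noise_sd = 0.3,
                         year_range = 1980:2009)
  land <- make_landscape(spec, seed = 6)
  sim <- species_sim(b_time = -6.4, delta_b = 2.4)
  out <- simulate_counts(land$sites, land$temperatures, sim, seed = 7)
  lat <- out$truth$latent
  # centre temperature within site; year + residual effects are noise
  fit <- lm(mu_sy ~ I(mean_temp - t_site_mean), data = lat)
  est <- coef(fit)[2]
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(est - (-6.4)), 2 * se + 0.3)
  # among-site slope of site means approaches b_time + delta_b
  site_df <- unique(lat[, c("site_id", "t_site_mean")])
  site_mean_mu <- tapply(lat$mu_sy, lat$site_id, mean)
  fit2 <- lm(site_mean_mu[site_df$site_id] ~ site_df$t_site_mean)
  expect_lt(abs(coef(fit2)[2] - (-4.0)), 1.2)
})

test_that("expected seasonal totals match the abundance parameter", {
  land <- make_landscape(quiet_landscape_spec(n_sites = 10, years = 2000:2004),
                         seed = 8)
  sim <- species_sim(site_abundance_mean = 200)
  out <- simulate_counts(land$sites, land$temperatures, sim, seed = 9)
  totals <- tapply(out$counts$count, paste(out$counts$site_id, out$counts$year),
                   sum)
  # Poisson total per site-year ~ Poisson(200): 3 MC SEs on the mean
  expect_lt(abs(mean(totals) - 200), 3 * sqrt(200 / length(totals)))
})

test_that("negative-binomial counts are overdispersed relative to Poisson", {
  land <- make_landscape(quiet_landscape_spec(n_sites = 10, years = 2000:2009),
                         seed = 10)
  sim <- species_sim(site_abundance_mean = 300, pop_date_sd = 0,
                     year_date_sd = 0, resid_date_sd = 0, b_time = 0,
                     delta_b = 0)
  pois <- simulate_counts(land$sites, land$temperatures, sim, seed = 11)
  nb <- simulate_counts(land$sites, land$temperatures, sim, seed = 11,
                        nb_dispersion = 0.5)
  tp <- tapply(pois$counts$count, paste(pois$counts$site_id, pois$counts$year), sum)
  tn <- tapply(nb$counts$count, paste(nb$counts$site_id, nb$counts$year), sum)
  expect_gt(var(tn), 2 * var(tp))
})

test_that("missing temperature coverage names the offending site-year", {
  land <- make_landscape(quiet_landscape_spec(n_sites = 2, years = 2000:2002),
                         seed = 12)
  tt <- land$temperatures
  tt <- tt[!(tt$year == 2001 & tt$month == 4), ]
  expect_error(
    simulate_counts(land$sites, tt, species_sim(cue_window = 4), seed = 1),
    "site-year"
  )
})

test_that("phylo estimate simulation reports the implied heritability", {
  tree <- fixture_tree(10)
  est <- simulate_phylo_estimates(tree, mu = 0, sigma_a2 = 3, sigma_e2 = 1,
                                  m_variances = 0, seed = 1)
  expect_equal(attr(est, "truth")$H2, 0.75)
  expect_equal(nrow(est), 10)
  expect_error(simulate_phylo_estimates(tree, sigma_a2 = -1), "variances")
})

test_that("without phylogenetic signal, species values are iid around the mean", {
  tree <- fixture_tree(31)
  set.seed(77)
  ys <- replicate(200, {
    est <- simulate_phylo_estimates(tree, mu = 5, beta = 0, sigma_a2 = 0,
                                    sigma_e2 = 1, m_variances = 0,
                                    seed = sample.int(1e6, 1))
    est$y
  })
  expect_lt(abs(mean(ys) - 5), 0.05)
  # cross-species correlation should vanish: compare two fixed species
  expect_lt(abs(cor(ys[1, ], ys[2, ])), 0.2)
})

test_that("on a star tree replicate draws have covariance sigma_a2 * I", {
  star <- ape::stree(8, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(88)
  draws <- replicate(600, {
    est <- simulate_phylo_estimates(star, mu = 0, sigma_a2 = 2, sigma_e2 = 0,
                                    m_variances = 0, seed = sample.int(1e6, 1))
    est$y
  })
  S <- cov(t(draws))
  expect_lt(max(abs(diag(S) - 2)), 0.5)
  expect_lt(max(abs(S[upper.tri(S)])), 0.4)
})
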