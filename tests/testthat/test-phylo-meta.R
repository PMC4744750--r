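test_that("the correlation matrix matches hand-computed shared-path fractions", {
  # star tree: no shared internal path -> identity
  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(2, nrow(star$edge))
  expect_equal(unname(phylo_correlation_matrix(star)), diag(5))
  # two tips sharing 60% of a unit depth: ((a:0.4,b:0.4):0.6);
  pair <- ape::read.tree(text = "((a:0.4,b:0.4):0.6,c:1);")
  A <- phylo_correlation_matrix(pair)
  expect_equal(A["a", "b"], 0.6)
  expect_equal(A["a", "c"], 0)
  expect_equal(diag(A), c(a = 1, b = 1, c = 1))
})

test_that("the correlation matrix is PSD with unit diagonal on random trees", {
  tree <- fixture_tree(31)
  A <- phylo_correlation_matrix(tree)
  expect_equal(diag(A), setNames(rep(1, 31), tree$tip.label))
  expect_true(isSymmetric(A))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # non-ultrametric trees are handled but flagged
  skewed <- tree
  skewed$edge.length[1] <- skewed$edge.length[1] + 1
  expect_warning(phylo_correlation_matrix(skewed), "ultrametric")
  noblen <- tree
  noblen$edge.length <- NULL
  expect_error(phylo_correlation_matrix(noblen), "branch lengths")
})

test_that("with m_var = 0 and A = I the grand mean matches the sample mean", {
  set.seed(101)
  n <- 40
  y <- rnorm(n, 3.2, 2)
  est <- data.frame(species_id = sprintf("s%02d", 1:n), y = y, m_var = 0)
  A <- diag(n)
  dimnames(A) <- list(est$species_id, est$species_id)
  fit <- fit_phylo_meta(est, A, n_iter = 6000, burn_in = 1000, thin = 5,
                        seed = 2)
  mu_draws <- fit$draws[, "mu"]
  # flat prior on mu: the marginal posterior mean of mu is exactly ybar
  mcse <- sd(mu_draws) / sqrt(effective_sample_size(mu_draws))
  expect_lt(abs(mean(mu_draws) - mean(y)), 4 * mcse)
  # total variance is identified even though the a/e split is not
  tot <- fit$draws[, "sigma_a2"] + fit$draws[, "sigma_e2"]
  expect_lt(abs(mean(tot) - var(y)), 4 * sd(tot) / sqrt(50))
})

test_that("a continuous trait coefficient is recovered from generator truth", {
  tree <- fixture_tree(31)
  est <- simulate_phylo_estimates(tree, mu = -4, beta = 1.5, trait_sd = 1,
                                  sigma_a2 = 0, sigma_e2 = 0.5,
                                  m_variances = 0.1, seed = 6)
  A <- phylo_correlation_matrix(tree)
  traits <- data.frame(species_id = est$species_id, x = attr(est, "truth")$x)
  fit <- fit_phylo_meta(est, A, traits = traits, n_iter = 6000,
                        burn_in = 1000, thin = 5, seed = 3)
  expect_true(all(c("mu", "x") %in% colnames(fit$draws)))
  bx <- fit$summary$x
  expect_true(bx$hpd[1] <= 1.5 && 1.5 <= bx$hpd[2])
  mu <- fit$summary$mu
  expect_true(mu$hpd[1] <= -4 && -4 <= mu$hpd[2])
  # oracle: with sigma_a2 = 0 the model is close to weighted least squares
  ols <- coef(lm(y ~ traits$x, data = est))[2]
  expect_lt(abs(bx$mode - ols), 0.25)
})

test_that("H2 is a valid proportion draw-wise and collapses without signal", {
  tree <- fixture_tree(31)
  est <- simulate_phylo_estimates(tree, mu = 2, sigma_a2 = 0, sigma_e2 = 1,
                                  m_variances = 0.05, seed = 9)
  fit <- fit_phylo_meta(est, phylo_correlation_matrix(tree), n_iter = 6000,
                        burn_in = 1000, thin = 5, seed = 4)
  H2 <- fit$draws[, "H2"]
  expect_true(all(H2 >= 0 & H2 <= 1))
  expect_lt(fit$summary$H2$mode, 0.15)
})

test_that("rescaling the estimates rescales locations and leaves H2 alone", {
  tree <- fixture_tree(31)
  est <- simulate_phylo_estimates(tree, mu = -6, sigma_a2 = 3, sigma_e2 = 1,
                                  m_variances = 0.2, seed = 11)
  A <- phylo_correlation_matrix(tree)
  f1 <- fit_phylo_meta(est, A, n_iter = 8000, burn_in = 2000, thin = 5,
                       seed = 5)
  est10 <- est
  est10$y <- est$y * 10
  est10$m_var <- est$m_var * 100
  f10 <- fit_phylo_meta(est10, A, n_iter = 8000, burn_in = 2000, thin = 5,
                        seed = 5)
  expect_equal(f10$summary$mu$mode, 10 * f1$summary$mu$mode, tolerance = 0.05)
  expect_equal(f10$summary$H2$mode, f1$summary$H2$mode, tolerance = 0.05)
})

test_that("an effectively infinite m_var removes a species' influence on mu", {
  set.seed(21)
  n <- 20
  y <- rnorm(n, 0, 1)
  y[1] <- 50  # wild outlier
  A <- diag(n)
  ids <- sprintf("s%02d", 1:n)
  dimnames(A) <- list(ids, ids)
  est_all <- data.frame(species_id = ids, y = y, m_var = c(1e6, rep(0.1, n - 1)))
  est_drop <- est_all[-1, ]
  f_all <- fit_phylo_meta(est_all, A, n_iter = 6000, burn_in = 1000, thin = 5,
                          seed = 7)
  f_drop <- fit_phylo_meta(est_drop, A[-1, -1], n_iter = 6000, burn_in = 1000,
                           thin = 5, seed = 7)
  expect_lt(abs(f_all$summary$mu$mode - f_drop$summary$mu$mode), 0.2)
  expect_gt(abs(mean(y) - f_drop$summary$mu$mode), 1)  # outlier would bite
})

test_that("input validation catches the documented error cases", {
  tree <- fixture_tree(10)
  A <- phylo_correlation_matrix(tree)
  est <- simulate_phylo_estimates(tree, seed = 1)
  expect_error(fit_phylo_meta(est[0, ], A), "empty")
  bad <- est
  bad$species_id[1] <- "nonesuch"
  expect_error(fit_phylo_meta(bad, A), "nonesuch")
  bad2 <- est
  bad2$m_var[1] <- -1
  expect_error(fit_phylo_meta(bad2, A), "m_var")
})

test_that("pooling over a single tree equals the direct fit", {
  tree <- fixture_tree(15)
  est <- simulate_phylo_estimates(tree, sigma_a2 = 1, sigma_e2 = 1,
                                  m_variances = 0.1, seed = 3)
  direct <- fit_phylo_meta(est, phylo_correlation_matrix(tree),
                           n_iter = 2000, burn_in = 462, thin = 4, seed = 12)
  pooled <- pool_over_trees(list(tree), est, total_iter = 2000,
                            burn_in_frac = 462 / 2000, thin = 4, seed = 12)
  expect_identical(direct$draws, pooled$draws)
})

test_that("pooling concatenates per-tree chains and skips mismatched trees", {
  tree <- fixture_tree(15)
  est <- simulate_phylo_estimates(tree, sigma_a2 = 1, sigma_e2 = 1,
                                  m_variances = 0.1, seed = 3)
  other <- fixture_tree(15)
  other$tip.label <- paste0("z", other$tip.label)
  expect_warning(
    pooled <- pool_over_trees(list(tree, other, tree), est,
                              total_iter = 3000, thin = 5, seed = 12),
    "skipped"
  )
  expect_equal(pooled$log$n_trees, 2)
  per_tree <- ceiling(3000 / 3)
  burn <- ceiling(per_tree * 3 / 13)
  expect_equal(nrow(pooled$draws), 2 * ((per_tree - burn) %/% 5))
  expect_error(suppressWarnings(pool_over_trees(list(other), est)),
               "skipped")
  # two identical trees with different seeds: same posterior, so the pooled
  # H2 distribution matches a single-tree run (Kolmogorov-Smirnov)
  p2 <- pool_over_trees(list(tree, tree), est, total_iter = 8000, thin = 4,
                        seed = 31)
  single <- fit_phylo_meta(est, phylo_correlation_matrix(tree),
                           n_iter = 8000, burn_in = 2000, thin = 4, seed = 99)
  ks <- suppressWarnings(ks.test(p2$draws[, "H2"], single$draws[, "H2"]))
  expect_gt(ks$p.value, 0.001)
})
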