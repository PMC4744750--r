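#' Simulate species-level slope estimates on a phylogeny
#'
#' Draws species values from the phylogenetic meta-analysis generating model
#' \eqn{y_i = \mu + \beta x_i + a_i + e_i + m_i}: a phylogenetic deviation
#' `a` from a zero-mean Gaussian with covariance `sigma_a2 * A(tree)`, an
#' i.i.d. species residual `e`, and a measurement error `m` with known
#' per-species variances. The continuous predictor `x` is evolved on the tree
#' as Brownian motion scaled to SD `trait_sd` (set `trait_sd = 0` for no
#' predictor effect). The true phylogenetic heritability
#' `H2 = sigma_a2 / (sigma_a2 + sigma_e2)` is reported alongside.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param n_species number of species to simulate (first `n_species` tips).
#' @param mu grand mean of the simulated estimates.
#' @param beta fixed-effect coefficient on the trait.
#' @param trait_sd SD of the Brownian trait across tips.
#' @param sigma_a2 phylogenetic variance (>= 0).
#' @param sigma_e2 residual species variance (>= 0).
#' @param m_variances per-species measurement-error variances; recycled to
#'   `n_species`.
#' @param seed integer RNG seed.
#' @return data frame `species_id`, `x`, `y`, `m_var` with attributes
#'   `truth` (list of the generating parameters, including `H2`).
#' @export
simulate_phylo_estimates <- function(tree, n_species = length(tree$tip.label),
                                     mu = -6, beta = 0, trait_sd = 1,
                                     sigma_a2 = 3, sigma_e2 = 1,
                                     m_variances = 0.25, seed = 1L) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object", call. = FALSE)
  if (length(tree$tip.label) < n_species) {
    stop("tree has fewer tips than n_species", call. = FALSE)
  }
  if (sigma_a2 < 0 || sigma_e2 < 0 || any(m_variances < 0)) {
    stop("variances must be >= 0", call. = FALSE)
  }
  set.seed(as.integer(seed))
  tips <- tree$tip.label[seq_len(n_species)]
  if (n_species < length(tree$tip.label)) {
    tree <- ape::keep.tip(tree, tips)
  }
  A <- phylo_correlation_matrix(tree)
  A <- A[tips, tips, drop = FALSE]
  m_var <- rep_len(m_variances, n_species)

  cholA <- chol(A + 1e-10 * diag(n_species))
  a <- sqrt(sigma_a2) * as.numeric(crossprod(cholA, rnorm(n_species)))
  x <- if (trait_sd > 0) {
    z <- as.numeric(crossprod(cholA, rnorm(n_species)))
    trait_sd * z
  } else {
    rep(0, n_species)
  }
  e <- rnorm(n_species, 0, sqrt(sigma_e2))
  m <- rnorm(n_species, 0, sqrt(m_var))
  y <- mu + beta * x + a + e + m

  out <- data.frame(species_id = tips, x = x, y = y, m_var = m_var,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(
    mu = mu, beta = beta, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
    H2 = if (sigma_a2 + sigma_e2 > 0) sigma_a2 / (sigma_a2 + sigma_e2) else NA_real_,
    a = setNames(a, tips), x = setNames(x, tips)
  )
  out
}
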