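#' Phylogenetic correlation matrix from a tree
#'
#' Under Brownian motion the expected covariance of a trait between two tips
#' is the shared root-to-tip path length; dividing by tree depth gives a
#' correlation matrix with unit diagonal. Non-ultrametric trees (beyond a
#' relative tolerance) are normalized per tip depth, with a warning.
#'
#' @param tree an `ape::phylo` tree with branch lengths (rooted).
#' @param tol relative tolerance on tip-depth equality for the ultrametric
#'   check.
#' @return a species-labelled symmetric positive-semidefinite matrix with
#'   unit diagonal, of class `matrix`.
#' @export
phylo_correlation_matrix <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  V <- ape::vcv(tree)
  depths <- diag(V)
  if (any(depths <= 0)) stop("tree has tips at zero depth", call. = FALSE)
  if (diff(range(depths)) > tol * mean(depths)) {
    warning("tree is not ultrametric; normalizing shared paths per tip depth",
            call. = FALSE)
  }
  A <- V / sqrt(outer(depths, depths))
  diag(A) <- 1
  (A + t(A)) / 2
}

#' Phylogenetic meta-analysis of species-level slope estimates
#'
#' Fits the measurement-error phylogenetic mixed model
#' \eqn{y_i = \mu + \beta x_i + a_i + e_i + m_i} by Gibbs sampling:
#' `a ~ N(0, sigma_a2 * A)` carries the phylogenetic signal, `e` is the
#' i.i.d. species residual, and `m` is measurement error with known,
#' fixed per-species variances (the posterior variances of the species
#' estimates from the decomposition stage). Fixed effects (grand mean and
#' optional trait coefficients) get flat priors; `sigma_a2` and `sigma_e2`
#' get scaled inverse-chi-square priors with scale `V` and degree of belief
#' `nu`. Phylogenetic heritability `H2 = sigma_a2 / (sigma_a2 + sigma_e2)` is
#' computed per draw.
#'
#' Fixed effects and the phylogenetic vector are drawn with `e + m`
#' integrated out of their full conditionals; `e` is then regenerated from
#' its conditional so both variance updates stay conjugate (a partially
#' collapsed Gibbs scheme).
#'
#' @param estimates data frame `species_id`, `y`, `m_var`.
#' @param A phylogenetic correlation matrix labelled by species (from
#'   [phylo_correlation_matrix()]).
#' @param traits optional data frame with `species_id` plus trait columns to
#'   fit as fixed effects. Categorical traits are coded as treatment
#'   contrasts against their first level; species with missing trait values
#'   are dropped listwise with a message.
#' @param prior a [prior_spec()] (its scalar scale and `nu` are applied to
#'   both variances).
#' @param n_iter,burn_in,thin chain control (defaults 13000/3000/10).
#' @param seed integer RNG seed.
#' @return an object of class `phylo_meta_fit`: a draws matrix with columns
#'   `mu`, one per trait coefficient, `sigma_a2`, `sigma_e2`, `H2`; mode/HPD
#'   summaries of each; and the sampler log.
#' @export
fit_phylo_meta <- function(estimates, A, traits = NULL, prior = prior_spec(),
                           n_iter = 13000L, burn_in = 3000L, thin = 10L,
                           seed = 1L) {
  stopifnot(all(c("species_id", "y", "m_var") %in% names(estimates)))
  if (!nrow(estimates)) stop("empty estimate list", call. = FALSE)
  if (any(estimates$m_var < 0)) stop("m_var must be >= 0", call. = FALSE)
  sp <- as.character(estimates$species_id)
  if (!all(sp %in% rownames(A))) {
    stop("species missing from the phylogenetic correlation matrix: ",
         paste(setdiff(sp, rownames(A)), collapse = ", "), call. = FALSE)
  }

  X <- matrix(1, nrow(estimates), 1, dimnames = list(NULL, "mu"))
  if (!is.null(traits)) {
    stopifnot("species_id" %in% names(traits))
    tr <- traits[match(sp, traits$species_id), , drop = FALSE]
    keep <- complete.cases(tr)
    if (!all(keep)) {
      message(sprintf("dropping %d species with missing traits (listwise)",
                      sum(!keep)))
      estimates <- estimates[keep, , drop = FALSE]
      sp <- sp[keep]
      tr <- tr[keep, , drop = FALSE]
    }
    tcols <- setdiff(names(tr), "species_id")
    if (length(tcols)) {
      mm <- model.matrix(~ ., data = tr[, tcols, drop = FALSE])
      X <- cbind(mu = 1, mm[, -1, drop = FALSE])
    }
  }
  n <- nrow(estimates)
  if (n < 3) stop("need at least 3 species", call. = FALSE)
  y <- estimates$y
  M <- estimates$m_var
  As <- A[sp, sp, drop = FALSE]
  Ainv <- tryCatch(chol2inv(chol(As)), error = function(e) {
    warning("singular phylogenetic matrix; applying ridge jitter",
            call. = FALSE)
    chol2inv(chol(As + 1e-8 * diag(n)))
  })

  nu <- prior$nu
  Vs <- prior$V[1, 1]
  k <- ncol(X)

  set.seed(as.integer(seed))
  a <- rep(0, n)
  sigma_a2 <- var(y) / 2 + 1e-6
  sigma_e2 <- var(y) / 2 + 1e-6
  n_keep <- (n_iter - burn_in) %/% thin
  draws <- matrix(NA_real_, n_keep, k + 3,
                  dimnames = list(NULL, c(colnames(X), "sigma_a2", "sigma_e2",
                                          "H2")))
  keep <- 0L
  for (it in seq_len(n_iter)) {
    D <- sigma_e2 + M                      # e + m integrated out
    # fixed effects | a
    W <- X / D
    P <- crossprod(X, W)
    bhat <- solve(P, crossprod(W, y - a))
    Rb <- chol(P)
    b <- bhat + backsolve(Rb, rnorm(k))
    # phylogenetic effects | b
    r <- y - as.numeric(X %*% b)
    Pa <- diag(1 / D) + Ainv / sigma_a2
    Ra <- chol(Pa)
    amean <- backsolve(Ra, forwardsolve(t(Ra), r / D))
    a <- amean + backsolve(Ra, rnorm(n))
    # regenerate e | a, b and update variances
    r2 <- r - a
    shrink <- sigma_e2 / (sigma_e2 + M)
    e <- rnorm(n, r2 * shrink, sqrt(shrink * M))
    sigma_e2 <- (nu * Vs + sum(e^2)) / rchisq(1, nu + n)
    qa <- as.numeric(crossprod(a, Ainv %*% a))
    sigma_a2 <- (nu * Vs + qa) / rchisq(1, nu + n)
    if (it > burn_in && (it - burn_in) %% thin == 0 && keep < n_keep) {
      keep <- keep + 1L
      draws[keep, ] <- c(b, sigma_a2, sigma_e2,
                         sigma_a2 / (sigma_a2 + sigma_e2))
    }
  }

  summaries <- lapply(colnames(draws), function(cn) summarize_posterior(draws[, cn]))
  names(summaries) <- colnames(draws)
  structure(list(
    draws = draws, summary = summaries, species = sp, n_species = n,
    fixed_effects = colnames(X),
    log = list(seed = as.integer(seed), n_iter = n_iter, burn_in = burn_in,
               thin = thin, n_retained = keep,
               ess_H2 = effective_sample_size(draws[, "H2"]))
  ), class = "phylo_meta_fit")
}

#' @export
print.phylo_meta_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic meta-analysis: %d species, %d retained draws\n",
              x$n_species, nrow(x$draws)))
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    cat(sprintf("  %-12s mode %8.3f  95%% HPD [%8.3f, %8.3f]\n",
                nm, s$mode, s$hpd[1], s$hpd[2]))
  }
  invisible(x)
}

#' Pool the meta-analysis over a sample of trees
#'
#' Runs [fit_phylo_meta()] once per tree with the total iteration budget
#' split evenly, and concatenates the retained draws, so the pooled posterior
#' carries both model and phylogeny uncertainty.
#'
#' @param trees a list of `ape::phylo` trees (or an `ape::multiPhylo`).
#' @param estimates,traits,prior as in [fit_phylo_meta()].
#' @param total_iter total iteration budget across trees (default 13000).
#' @param burn_in_frac fraction of each per-tree chain discarded (default
#'   3/13, matching the single-tree default).
#' @param thin retention stride within each per-tree chain.
#' @param seed integer base seed; tree t uses `seed + t - 1`.
#' @return a `phylo_meta_fit` with pooled draws and summaries; trees whose
#'   tips do not cover the estimate species are skipped with a warning.
#' @export
pool_over_trees <- function(trees, estimates, traits = NULL,
                            prior = prior_spec(), total_iter = 13000L,
                            burn_in_frac = 3 / 13, thin = 10L, seed = 1L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("need at least one tree", call. = FALSE)
  per_tree <- ceiling(total_iter / length(trees))
  burn <- ceiling(per_tree * burn_in_frac)
  sp <- as.character(estimates$species_id)

  fits <- list()
  for (t in seq_along(trees)) {
    tree <- trees[[t]]
    if (!all(sp %in% tree$tip.label)) {
      warning(sprintf("tree %d lacks some estimate species; skipped", t),
              call. = FALSE)
      next
    }
    A <- suppressWarnings(phylo_correlation_matrix(tree))
    fits[[length(fits) + 1L]] <- fit_phylo_meta(
      estimates, A, traits = traits, prior = prior, n_iter = per_tree,
      burn_in = burn, thin = thin, seed = as.integer(seed) + t - 1L
    )
  }
  if (!length(fits)) stop("all trees were skipped", call. = FALSE)
  if (length(fits) == 1L) return(fits[[1]])
  draws <- do.call(rbind, lapply(fits, `[[`, "draws"))
  summaries <- lapply(colnames(draws), function(cn) summarize_posterior(draws[, cn]))
  names(summaries) <- colnames(draws)
  structure(list(
    draws = draws, summary = summaries, species = fits[[1]]$species,
    n_species = fits[[1]]$n_species, fixed_effects = fits[[1]]$fixed_effects,
    log = list(seed = as.integer(seed), n_trees = length(fits),
               per_tree_iter = per_tree, burn_in = burn, thin = thin,
               n_retained = nrow(draws),
               ess_H2 = effective_sample_size(draws[, "H2"]))
  ), class = "phylo_meta_fit")
}
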