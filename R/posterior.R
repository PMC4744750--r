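#' Posterior mode and 95% HPD interval
#'
#' The mode is the argmax of a Gaussian kernel density over the draws
#' (Silverman's rule-of-thumb bandwidth); the highest-posterior-density
#' interval is the shortest interval containing the stated fraction of the
#' sorted draws.
#'
#' @param draws numeric vector of posterior draws (>= 100, unless constant).
#' @param prob interval mass (default 0.95).
#' @return list with `mode`, `hpd` (length-2 vector), `mean`, `n`.
#' @export
summarize_posterior <- function(draws, prob = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 1) stop("no finite draws", call. = FALSE)
  if (var(draws) == 0) {
    return(list(mode = draws[1], hpd = c(draws[1], draws[1]),
                mean = draws[1], n = n))
  }
  if (n < 100) stop("need >= 100 draws to summarize a posterior", call. = FALSE)
  list(mode = posterior_mode(draws), hpd = hpd_interval(draws, prob),
       mean = mean(draws), n = n)
}

#' Kernel-density posterior mode
#'
#' @param draws numeric draws.
#' @return the density argmax.
#' @export
posterior_mode <- function(draws) {
  draws <- draws[is.finite(draws)]
  if (var(draws) == 0) return(draws[1])
  d <- density(draws, bw = "nrd0", n = 2048)
  d$x[which.max(d$y)]
}

#' Shortest (highest posterior density) interval of a set of draws
#'
#' @param draws numeric draws.
#' @param prob interval mass (default 0.95).
#' @return length-2 numeric vector, lower then upper endpoint.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Effective sample size of an MCMC chain
#'
#' Initial-positive-sequence estimator: `n / (1 + 2 * sum(rho_k))` with the
#' autocorrelation sum truncated at the first non-positive lag.
#'
#' @param x numeric chain.
#' @return effective sample size (capped at `length(x)`).
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 3 || var(x) == 0) return(as.numeric(n))
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1)]
  min(n, n / (1 + 2 * sum(rho)))
}

#' Test for temperature-mediated local adaptation
#'
#' The null hypothesis (geographic covariation between temperature and flight
#' date is due to plasticity alone) is rejected when the 95% HPD of the slope
#' difference `delta_b` excludes zero; an interval touching zero counts as
#' spanning it. When rejected, `delta_b > 0` with negative slopes means the
#' spatial slope is shallower than the temporal slope (countergradient local
#' adaptation); `delta_b < 0` means the spatial slope is steeper (co-gradient).
#'
#' @param x a `slope_posterior` from [slopes_from_vcv()], or a list with
#'   elements `mode` and `hpd` for the slope difference.
#' @return list with `reject` (logical) and `direction` (`"countergradient"`,
#'   `"co-gradient"`, or `"none"` when the null is retained).
#' @export
test_local_adaptation <- function(x) {
  s <- if (inherits(x, "slope_posterior")) x$summary$delta_b else x
  if (is.null(s$hpd) || length(s$hpd) != 2) {
    stop("x must carry a delta_b mode and HPD interval", call. = FALSE)
  }
  reject <- s$hpd[1] > 0 || s$hpd[2] < 0
  if (is.null(s$mode)) s$mode <- mean(s$hpd)
  direction <- if (!reject) {
    "none"
  } else if (s$mode > 0) {
    "countergradient"
  } else {
    "co-gradient"
  }
  list(reject = reject, direction = direction)
}
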