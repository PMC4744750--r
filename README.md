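# phenodecomp

Decomposing phenology–temperature relationships into plasticity and local
adaptation from count monitoring data.

## The science

Insect flight seasons track temperature in two distinct ways. Over **time**,
a warm year advances flight within a population — phenotypic plasticity.
Over **space**, populations in warmer places fly at different dates than
populations in cooler places — the combined result of plasticity *and* of
genetic differences accumulated through local adaptation. Substituting space
for time therefore gives a test: if the within-population slope of flight
date on temperature (`b_time`, days °C⁻¹) equals the among-population slope
(`b_space`), a shared reaction norm explains everything; a difference

```
delta_b = b_space - b_time
```

implicates local adaptation. With negative slopes (warmer ⇒ earlier),
`delta_b > 0` means warm-place populations fly later than plasticity
predicts (countergradient variation), `delta_b < 0` the opposite
(co-gradient variation).

`phenodecomp` implements the full chain on transect count data:

1. **Flight phenology** — count-weighted mean flight date per
   site×year×species (day 1 = 1 April), with a sufficiency filter.
2. **Climate window selection** — three-month running-mean temperatures per
   grid cell; the most predictive window per species chosen by |t| from
   regressions of regional mean flight date on regional window temperature.
3. **Slope decomposition** — a bivariate Bayesian mixed model of
   (temperature, flight date) with crossed population and year random
   effects, fitted by a conjugate Gibbs sampler (C++/RcppArmadillo,
   inverse-Wishart priors, scale 1, ν = 0.002; 13 000 iterations, 3 000
   burn-in, thin 10 by default). Dividing each component's
   temperature–date covariance by its temperature variance, draw by draw,
   yields posteriors for `b_time` (year component), `b_space` (population
   component) and `delta_b`, summarised by posterior modes and 95% HPD
   intervals.
4. **Phylogenetic meta-analysis** — species-level estimates enter
   `y_i = mu + beta*x_i + a_i + e_i + m_i` with a Brownian phylogenetic
   effect, i.i.d. residual, and fixed, known measurement-error variances;
   phylogenetic heritability `H2 = sigma_a2/(sigma_a2 + sigma_e2)` per
   draw; optional pooling over a tree sample.

A synthetic-data generator (`make_landscape()`, `simulate_counts()`,
`simulate_phylo_estimates()`) produces UK-like monitoring data with known
ground truth — spatial temperature gradients, regionally shared interannual
and monthly anomalies, Poisson counts over Gaussian flight curves — so every
stage is validated by parameter recovery, not just unit oracles.

A reference table of published per-species slope decompositions for 31 UK
butterflies ships in `inst/extdata/` (`uk_butterfly_slopes()`), used by the
tests to pin down sign conventions and the HPD decision rule.

## Worked example

```r
library(phenodecomp)

# a 50-site, 30-year synthetic landscape with a -5 degC / 1000 km gradient
land <- make_landscape(landscape_spec(), seed = 1)

# three species: co-gradient, neutral, countergradient
counts <- do.call(rbind, lapply(1:3, function(i) {
  sim <- species_sim(sprintf("sp%d", i), b_time = -6.4,
                     delta_b = c(-1, 0, 3)[i])
  simulate_counts(land$sites, land$temperatures, sim, seed = i)$counts
}))

cfg <- pipeline_config(counts, land$sites, land$temperatures, seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)
res$summary[, c("species_id", "window_month", "b_time_mode", "b_space_mode",
                "delta_b_mode", "local_adaptation")]
```

```
  species_id window_month b_time_mode b_space_mode delta_b_mode local_adaptation
1        sp1            4       -6.11        -7.42       -1.427             TRUE
2        sp2            4       -6.87        -6.31        0.636            FALSE
3        sp3            4       -6.42        -3.17        3.198             TRUE
```

All three species find the generating cue window (month 4), recover
`b_time` near the true −6.4, and order their `delta_b` estimates as
generated (−1, 0, +3), rejecting the no-local-adaptation null exactly where
the truth is nonzero.

`plot_space_time(res$summary)` draws the species against the line of unity
(`b_space = b_time`); distance from the line is `delta_b`.

## Vignette

`vignettes/space-time-decomposition.Rmd` describes the model, the samplers,
the generator and the numerical choices in detail.
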