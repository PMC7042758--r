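# migcon — integrated Bayesian estimation of migratory connectivity

`migcon` estimates **migratory connectivity** — the proportions
*m*<sub>i,k</sub> of each breeding population *i* that spend the
nonbreeding season in each large wintering area *k* — for European barn
swallows marked in Switzerland, Germany, Sweden, and Finland and wintering
in four sub-Saharan regions (Western, Central, Eastern, Southern Africa).
Each row of the 8×4 connectivity matrix is a simplex
(Σ<sub>k</sub> m<sub>i,k</sub> = 1) shared by three data models fitted
jointly:

1. **Ring reencounters.** Multinomial mark-recovery likelihoods with
   area-specific reporting probabilities r<sub>k</sub> (order 10⁻⁴,
   Eastern = Central by constraint), separately for birds ringed as chicks
   vs full-grown and for known vs unknown numbers ringed:
   P<sub>i,k</sub> = m<sub>i,k</sub> r<sub>k</sub>, with a
   never-reencountered cell when totals are known and renormalized cell
   probabilities Q<sub>i,k</sub> when they are not.
2. **Feather stable isotopes.** A two-component bivariate-normal mixture
   over standardized (δ¹³C, δ¹⁵N) pairs separating Southern Africa from the
   pooled regions further north, with mixture weights
   (m₁+m₂+m₃, m₄) from the bird's population row and informative priors
   from independent wintering-ground reference data.
3. **Avian malaria prevalence.** Binomial infection counts for five
   *Plasmodium* lineages in the wintering areas and breeding populations,
   linked by the prevalence-mixing equation
   f<sup>b</sup><sub>i,p</sub> = a · Σ<sub>k</sub>
   f<sup>nb</sup><sub>k,p</sub> m<sub>i,k</sub>.

The joint posterior is sampled by an adaptive Metropolis-within-Gibbs
sampler with a compiled log-posterior (block updates per parameter group
plus a full-covariance adaptive-Metropolis kernel). The package also ships
convergence diagnostics (Brooks–Gelman–Rubin R-hat), prior–posterior
overlap and per-data-source contribution analyses, a full synthetic-data
generator for parameter-recovery studies, CSV readers/writers for all input
tables, and command-style entry points. Who it is for: quantitative
ecologists integrating mark-recovery data with intrinsic markers, and
anyone wanting a tested, reusable reference implementation of this class of
shared-simplex integrated model.

## Worked example

Simulate a high-information study-like data set (reporting rates inflated
50×), fit the integrated model, and inspect the southern breeding
population's wintering distribution. The generating row is
(0.55, 0.35, 0.03, 0.07).

```r
library(migcon)
bundle <- make_study_like_bundle(seed = 7, r_scale = 50)
bundle$data$rings
#> Ring-reencounter data: 8 groups x 4 wintering areas
#>   known totals:   ad 198000 ringed / 1983 reencountered; juv 402000 / 2003
#>   unknown totals: ad 23 reencounters; juv 25

fit <- run_mcmc(bundle$data,
                config = sampler_config(n_chains = 3, n_iter = 12000,
                                        burn_in = 6000, thin = 6, seed = 7))
s <- summarize_draws(fit)
subset(s, parameter %in% paste0("m[Southern_breeding,", area_labels(), "]"))
#>                        parameter       mean         sd       q2.5     median      q97.5
#> 25  m[Southern_breeding,Western] 0.49259972 0.04335211 0.40961131 0.49172612 0.57963144
#> 26  m[Southern_breeding,Central] 0.41701281 0.04306190 0.33357512 0.41721738 0.49915196
#> 27  m[Southern_breeding,Eastern] 0.02472493 0.00914194 0.01044989 0.02349059 0.04686826
#> 28 m[Southern_breeding,Southern] 0.06566255 0.01148462 0.04551029 0.06493209 0.09075950

round(max(gelman_rubin(fit)), 4)
#> [1] 1.0353
```

Reading the output: the model recovers the Eastern and Southern shares
essentially exactly, and places Western around 0.49 and Central around 0.42
against truths of 0.55 and 0.35 — the Western-vs-Central contrast is the
soft direction of this model (reporting rates and connectivity trade off
along a near-flat ridge; see the methods vignette,
`vignettes/integrated-connectivity.Rmd`, for the identifiability analysis).
The prior–posterior overlap diagnostic shows which parameters the data
actually inform — essentially fully for the northern population's Southern
share, only partially for the prevalence ratio `a`:

```r
prior_posterior_overlap(fit, parameter = c("m[SWE,Southern]", "a"))[, c("parameter", "overlap")]
#>         parameter    overlap
#> 1 m[SWE,Southern] 0.01548006
#> 2               a 0.29274199
```

Command-style entry points wrap the same pipeline:

```r
migcon_cli(c("simulate", "--seed", "1", "--out", "sim"))
migcon_cli(c("fit", "--input", "sim", "--sources", "rings,parasites",
             "--iter", "12000", "--burnin", "6000", "--seed", "1"))
migcon_cli(c("recover", "--seed", "1", "--out", "rec", "--iter", "12000",
             "--burnin", "6000"))
```

every command writes its outputs plus a `manifest.json` sufficient to
reproduce the run.

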