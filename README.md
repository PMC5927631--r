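# renaltiming

Timing the landmark somatic events of clear cell renal cell carcinoma
(ccRCC) and modelling its early clonal dynamics.

ccRCC is initiated, in most patients, by loss of the short arm of
chromosome 3 — frequently through a chromothripsis event that
simultaneously deletes 3p and gains 5q — followed years to decades later
by somatic inactivation of the remaining *VHL* allele and emergence of the
tumor's most recent common ancestor (MRCA). `renaltiming` implements, as
tested R code with a fully synthetic validation world, the quantitative
machinery needed to reconstruct that chronology from multi-region
whole-genome sequencing and population incidence data:

- **CCF / multiplicity timing** of clonal arm gains. A variant allele
  fraction is converted to mutation copies per cancer cell,
  `m = f (ψ n_t + (1 − ψ) n_n) / ψ` (purity ψ, local tumor copy number
  `n_t`), and each mutation in the gained region is voted pre- or
  post-duplication across samples (`m ≈ 2` vs `m ≈ 1` under a single-copy
  gain).
- **Dirichlet-process subclone clustering** of per-sample cancer cell
  fractions with Binomial read-count emission and a detection-sensitivity
  adjustment, ordered into a clone tree by the pigeonhole principle, and
  reduced to per-branch cumulative mutation burdens.
- **Mutation rate per year** via the no-intercept random-slope linear
  mixed model `burden_ib = (β + u_i)·age_i + ε_ib`, `u_i ~ N(0, σ_u²)`
  (REML through `lme4`), with a quadratic-in-age sensitivity check and
  parametric-bootstrap confidence intervals.
- **Gain and MRCA ages**: the fraction of clonal molecular time
  `π = 3 n_pre / (2 n_pre + n_single)`, the direct estimate
  `t = n_pre G / (r L)` for a region of `L` bp in a callable diploid
  genome of `G = 5.32` Gb, and `t_MRCA = clonal burden / r`.
- **VHL driver mutation rate per cell per year**: the cohort trinucleotide
  spectrum distributed over the 96 substitution classes per available
  genome context, every substitution in the coding sequence enumerated and
  annotated, driver classes summed; indels via the cohort's
  indel-vs-substitution slope.
- **The three-stage waiting-time model of age incidence.** Sporadic
  incidence age is `Y = Z₁ + Z₂ + Z₃` with `Z₁ ~ Γ(α₁, β₁)` (time to 3p
  loss), `Z₂ ~ Exp(λ)` with `λ = ν μ` (somatic VHL hit in a precursor
  clone of ν cells) and `Z₃ ~ Γ(α₃, β₃)` (to diagnosis); inherited
  (VHL-carrier) disease is `Y = Z₁ + Z₃`. A Gibbs sampler with
  Metropolis–Hastings Dirichlet split proposals, rejection sampling for
  censored individuals, conjugate-prior MH updates for the gamma pairs and
  an exact conjugate λ draw yields the posterior of ν — the number of
  3p-loss cells at risk — and simulates incidence curves under clone-size
  interventions (fraction ρ).
- **Chromothripsis hallmark checks**: uniformity of the four breakpoint
  join orientations and two-state copy-number oscillation.

## Worked example

```r
library(renaltiming)

truth <- synthetic_truth(rate = 87, age = 60, t_dup = 10, t_mrca = 40,
                         purity = 0.8, depth = 150)
sim <- simulate_mutation_table(truth, seed = 1)
labels <- label_gain_mutations(sim$mutations, sim$cn_segments,
  region = list(chrom = "5", start = 1e6, end = 1e6 + truth$L))
clonal <- labels$n_present == labels$n_samples & labels$min_copies >= 0.75
n_pre <- sum(labels$label == "pre" & clonal)      # 18
n_single <- sum(labels$label == "post" & clonal)  # 224

bootstrap_timing(n_pre, n_single, clonal_burden = 3634,
                 rate_mean = 87, rate_sd = 6, seed = 2,
                 method = "fraction")
#> Gain timing (fraction): 8.7 years (95% CI 5.1-12.8), MRCA at 41.8 years
bootstrap_timing(n_pre, n_single, clonal_burden = 3634,
                 rate_mean = 87, rate_sd = 6, seed = 2, method = "direct")
#> Gain timing (direct): 8.3 years (95% CI 4.6-12.5), MRCA at 41.8 years
```

The tumor was simulated with the gain at age 10 and the MRCA at age 40:
both estimators recover the gain in childhood with overlapping intervals,
and the MRCA age from the clonal burden (3634 / 87 ≈ 41.8) matches.

Fitting the incidence model to a synthetic cohort generated with a
planted precursor clone of ν = 300 cells (μ = 2.1e-6 per cell per year):

```r
coh <- simulate_incidence_cohort(nu = 300, mu = 2.1e-6,
                                 n_sporadic = 500, n_inherited = 200,
                                 seed = 3)
ages3p <- withr::with_seed(4, rgamma(12, 2.5, 0.17))
draws <- run_gibbs(coh, waiting_time_priors(ages3p), mu = 2.1e-6,
                   sampler_config(iterations = 5000, burnin = 1000,
                                  thin = 5, seed = 5))
summarize_posterior(draws)
#>   parameter     lo95   median     hi95
#> ...
#> 5    lambda 2.42e-04 4.59e-04 7.43e-04
#> 6        nu 1.15e+02 2.19e+02 3.54e+02
```

The 95% posterior interval for the clone size (115–354 cells) covers the
planted 300 — "no more than a few hundred cells", which is what makes
early intervention on the 3p-loss clone a plausible prevention strategy
(`intervention_curves(draws, rho = 0.5)` simulates halving it).

## Command line

A thin CLI wraps the pipeline (see `inst/cli/renaltiming`):
`simulate`, `fit-clones`, `fit-rate`, `time-gains`, `vhl-rate`,
`fit-incidence`, `intervene`, `hallmarks`.

## Vignette

`vignettes/waiting-time-model.Rmd` documents the model assumptions, the
synthetic world the tests are run in, numerical choices and known
limitations.
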