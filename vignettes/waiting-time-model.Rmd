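---
title: "Methods: timing somatic events in ccRCC and the three-stage incidence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: timing somatic events in ccRCC and the three-stage incidence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `renaltiming`, their
assumptions, the tunable parameters that matter, the synthetic world the
test suite runs in, and the numerical and design choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. Mutation copies and pre/post-duplication calls

Under the standard sampling model, a mutation present on `m` of the
`n_t` tumor copies at a locus, in a fraction `c` of cancer cells, in a
sample of purity `ψ` contaminated by normal cells of copy number `n_n`,
has expected variant allele fraction

    f = c ψ m / (ψ n_t + (1 − ψ) n_n).

`mutation_copies()` inverts this to `m·c` (copies per cancer cell). In a
region carrying a clonal single-copy gain (`n_t = 3`), clonal mutations
acquired before the gain were duplicated with it (`m = 2`, copies ≈ 2);
later clonal mutations sit on one of three copies (copies ≈ 1).

**Assumptions.** Clonal copy number (no subclonal CN states); normal copy
number 2 on autosomes; read counts Binomial at the expected VAF.

**Parameters.** Classification boundaries default to `(1.25, 1.75)`:
values between them are abstained on as "uncertain" rather than forced,
because at realistic depth (~67x–150x) the copies estimate of a single
mutation has a standard error of roughly 0.2–0.4 and a hard midpoint cut
would mislabel a meaningful fraction. The consensus across samples counts
only samples with at least one alt read — a mutation absent from a sample
carries no timing information for a clonal gain. Clonality of a region
mutation (needed by the fraction-of-time estimator) is operationalised in
the CLI as "detected in every sample and copies ≥ 0.75 in each": clonal
one-copy mutations sit near 1 in every sample, whereas subclonal
mutations fall well below 1 in at least one sample.

## 2. Subclone clustering and the clone tree

Per-sample cancer cell fractions are modelled with a truncated
stick-breaking Dirichlet-process mixture (default truncation 10,
concentration `alpha = 0.05`) with Binomial emission of alt reads at
`p = CCF × ψ m / (ψ n_t + (1 − ψ) n_n)` assuming multiplicity 1. The
sensitivity adjustment multiplies each cluster's prior mass by the
probability that a mutation at that CCF would have produced at least
`min_alt_reads = 3` alt reads in at least one sample — low-CCF clusters
are penalised in proportion to how hard their members are to call.

Numerical choices:

- cluster centres are updated by Gibbs sampling on a CCF grid (step 0.01)
  — robust, and exact to the resolution the data supports;
- after the final sweep, occupied clusters whose centres agree within
  `merge_tol = 0.1` in every sample are merged. Truncated stick-breaking
  mixtures routinely leave near-duplicate components on one true cluster;
  merging at the CCF resolution of the data is the standard remedy in
  subclonal-reconstruction pipelines;
- assignments are maximum-posterior hard labels (burden counts are
  integers); `alpha = 0.05` encodes that a tumor has a handful of
  subclones, not dozens.

The clone tree is built by the pigeonhole principle: cluster A may parent
B only if A's CCF is at least B's in every sample (tolerance 0.05 CCF),
and siblings' CCFs may not sum above their parent's. Among admissible
parents the **largest-CCF** parent is chosen, i.e. clusters attach as
shallowly as possible and are nested only when the sibling-sum constraint
forces it — the pigeonhole principle *forces* nestings, it never merely
suggests them. Greedy placement in decreasing CCF order is used; an
unplaceable cluster raises an error listing the violated constraints.

Branch burdens are root-to-leaf path sums of cluster sizes. This is what
lets the MRCA be placed at 50% of molecular time in a tumor whose two
subclones each carry as many mutations as the trunk, where a naive
clonal-vs-subclonal ratio would say 33%.

## 3. Mutation rate per year

Branch burdens against age at surgery, with no intercept (a newborn has
no somatic burden; intercepts were also checked and do not improve fit in
the cohort this package models):

    burden_ib = (β + u_i) · age_i + ε_ib,   u_i ~ N(0, σ_u²).

REML via `lme4`; patient-specific rates are the shrunken slopes
`β + u_i`. Branches within a patient are treated as exchangeable under
the shared random slope — the simplest structure that absorbs the
within-patient correlation from shared ancestry; the residual variance is
constant (not age-scaled). The 95% CI of β uses a parametric bootstrap
(default 1000 refits of data simulated from the fitted model). Degenerate
inputs (a single patient, or an all-zero cohort, where σ_u is
unidentifiable) fall back to least squares through the origin and are
flagged `singular`. The quadratic sensitivity variant adds a fixed
`(age/100)²` term (rescaled so the two predictors share a scale, which
changes nothing in the likelihood-ratio test) and compares by ML LRT on
1 df.

## 4. Gain and MRCA ages

With a single-copy gain at time `t` and MRCA at `T`, pre-duplication
(two-copy) mutations accrue on one haplotype for `t` years while
single-copy clonal mutations accrue on the other haplotype for `t` years
plus all three copies for `T − t` years, so with per-haplotype rate
`r L / G`:

    E[n_pre] = r t L / G,    E[n_single] = r L/G (t + 3(T − t)),

giving `π = t/T = 3 n_pre / (2 n_pre + n_single)` (clamped to [0, 1] with
a logged message). The direct method is `t = n_pre G / (r L)`. Both are
checked against the forward simulator at 10⁴ replicates (relative error
< 3%). The closed form covers single-copy gains only; other gain types
are rejected rather than guessed. Bootstrap CIs resample the counts as
Poisson at their observed values and the rate as a positive-truncated
Normal with the patient slope's mean and SD; joint resampling of σ_u is
not attempted.

## 5. VHL driver mutation rate

The genome-wide substitution rate is divided over the 96
pyrimidine-centred classes in proportion to the cohort spectrum and
normalised per available context site, so that `Σ rate × sites` recovers
the genome rate exactly (a tested conservation identity). The CDS is
evaluated on its coding strand with contexts collapsed to
pyrimidine-centred (strand-resolved 192-class spectra can be supplied by
not collapsing upstream). Every one of the `3L` substitutions is
annotated via the standard genetic code; any substitution in the start
codon counts as start-lost. The two terminal bases have no within-CDS
flanking context and carry class `NA`; a uniform class rate covers fully
synthetic tests. Driver indels use the zero-intercept least-squares slope
of indel on substitution counts across patients, times the substitution
rate, times `CDS length / G`. Splice-site drivers are outside the
CDS-only mode. The driver missense set is a plain input file (no bundled
COSMIC extract, for licensing reasons); tests use toy sets.

## 6. The three-stage waiting-time model

Sporadic: `Y = Z₁ + Z₂ + Z₃`; inherited: `Y = Z₁ + Z₃`, with
`Z₁ ~ Γ(α₁, β₁)`, `Z₂ ~ Exp(λ)`, `λ = ν μ`, `Z₃ ~ Γ(α₃, β₃)`. Waiting
times are independent; the 3p-loss clone is assumed to reach its
steady-state size quickly and stay constant; events are assumed ordered
(3p loss, then the VHL hit, then progression). Censoring is handled by
data augmentation.

Priors: `λ ~ Γ(0.01, 0.01)`; each gamma pair takes the conjugate prior
`f(α, β) ∝ p^(α−1) e^(−βq) Γ(α)^(−r) β^(αs)`. For (α₁, β₁) the prior is
informative, distilled from molecular-timing estimates of 3p-loss ages:
`p₁ = Πxᵢ`, `q₁ = Σxᵢ`, `r₁ = s₁ = n`, held in log space (`log p₁ =
Σ log xᵢ`) so the product cannot overflow. Note the exponent of β must be
**+αs** for conjugacy with the gamma likelihood; a sign-flipped form that
sometimes appears in print is not conjugate and is not what is
implemented. The uninformative setting `p = q = r = s = 1` is an
*improper* prior (its β-marginal diverges); it is usable as a posterior
ingredient but a "prior-only" chain has no stationary distribution — the
kernel oracle tests therefore always include data.

Sampler (per iteration): (1) Metropolis–Hastings Dirichlet split
proposals `z* = y · Dir(κ z / y)` for the latent times of every
uncensored individual, preserving the observed sum exactly, accepted with
the gamma/exponential density ratios times the Hastings correction;
(2) rejection sampling for censored individuals — redraw from the current
priors until the sum exceeds the censoring age; (3) MH updates of
(α₁, β₁) and (α₃, β₃) with independent gamma proposals of mean equal to
the current value (shape `γ × current`, rate `γ`, variance `current/γ`)
against the log-space conjugate posterior; (4) an exact conjugate draw
`λ ~ Γ(0.01 + n_spor, 0.01 + Σ z₂)`. Draws after burn-in, thinned, are
returned with `ν = λ / μ`.

Numerical and tuning choices:

- `κ = 10` and `γ = 1000` by default. Both are pure proposal-scale
  parameters, chosen (before any acceptance test existed) so that all
  four kernels' acceptance rates land in 0.2–0.6 on the default synthetic
  cohort; they do not change the target distribution and remain
  user-settable.
- Censored inherited individuals can stall pure rejection: when the chain
  visits (α, β) values that place ~10⁻⁶ probability beyond an
  85-year censoring age, the expected number of rejections explodes.
  After 2000 failed attempts the kernel switches to an exact inverse-CDF
  draw from the identical conditional distribution (the z₁ marginal given
  `z₁ + z₃ > c` tabulated on a 512-point grid, z₃ from the truncated
  gamma quantile function). The switch changes the sampling route, not
  the target, and is KS-tested against the rejection path. The sporadic
  group keeps rejection with the configurable attempt cap: the
  exponential component's memorylessness makes acceptance cheap whenever
  λ is small, and a genuinely pathological λ still errors loudly with a
  state dump.
- Initialisation: even split of each observed age (censored individuals
  start 20% above the censoring age so the constraint holds from sweep
  one); gamma pairs by method of moments on the initial latents; λ at
  `1/mean(z₂)`. Mixing of (α₁, β₁) is the slowest part of the chain, as
  the Z₁ and Z₃ stages are confounded except through the informative
  prior.
- A NaN in any kernel log-density aborts with the offending parameter
  values rather than propagating.

Identifiability: with only uncensored events, the λ posterior is heavy
tailed — λ → ∞ collapses the sporadic model onto the inherited one,
which event ages alone cannot rule out. Censored individuals (the vast
majority of any real sporadic cohort) are what bound λ from above, since
a large λ makes surviving to 85 without disease unlikely. Oracle checks
of the λ marginal therefore use cohorts with censoring.

Interventions: for each posterior draw, sporadic ages are re-simulated
with `Z₂ ~ Exp(ρλ)` — a precursor clone reduced to a fraction ρ — and
cumulative incidence is summarised with pointwise 95% bands. ρ = 1
reproduces the fitted posterior predictive.

## 7. The synthetic world

The generator's defaults state the world the tests run in: 87
mutations/year over a 5.32 Gb callable diploid genome, between-patient
rate SD 17/year, surgery at 60, a 133 Mb gained region, tumor purity
0.7–1, a fixed integer read depth per sample (no depth overdispersion),
Binomial read sampling, administrative censoring at age 85, and — where
the source material gives ranges rather than parameters — `Z₁ ~
Γ(2.5, 0.17)` (mean ≈ 15 y, SD ≈ 9: 3p loss in childhood or adolescence
with wide spread) and `Z₃ ~ Γ(4, 0.2)` (mean 20 y, SD 10: a 15–30-year
lag from the second hit to diagnosis). These were chosen once, for
realism, and not revisited. The breakpoint-cluster generator draws the
four join orientations uniformly with a two-state oscillating CN track
(chromothripsis) or orientation-biased joins with a staircase CN track
(sequential rearrangement).

What a green test does **not** establish: the generator has no
sequencing-error model, no depth overdispersion, no subclonal copy
number, no mutation-signature structure, and its clone trees are small
and known; real-cohort performance (variant calling, CN calling, purity
estimation) is explicitly out of scope, and the cohort-level numbers of
the motivating study are not reproducible from synthetic data.

## 8. Known limitations

- The DP clustering assumes multiplicity 1 for the emission model;
  co-clustering of copies and CCF is not attempted.
- The clone-tree builder is greedy (decreasing CCF); a constraint set
  satisfiable only with backtracking will error rather than search.
- The closed-form gain timing covers single-copy gains only; whole-genome
  doubling and subclonal gains are out of scope.
- Hard assignment slightly understates burden uncertainty relative to
  soft weights.
- Effective-sample-size style diagnostics are left to the user
  (acceptance rates are reported); no automatic convergence stopping.
- The hallmark classifier checks two of the three chromothripsis
  criteria; derivative-haplotype reconstructability requires phased data
  and is not implemented.
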