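---
title: "Cluster-sampling ICC and design effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-sampling ICC and design effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svyicc)
```

## The sampling model

`svyicc` targets single-stage cluster samples: a set of `a` primary
sampling units (hospitals, in the surveillance setting the package is
modeled on) is selected, and *every* eligible subject within each selected
unit is observed. There is no second sampling stage, no stratification and
no weighting, so all design-based variance comes from the grouping itself.
The motivating design has `a = 27` centers with the size vector returned by
`network_cluster_sizes()` — 9,555 subjects, mean cluster size 354, but
extremely unbalanced (48 to 1,086 subjects per center). That imbalance
drives several of the methodological choices below.

Every reported variable is a dichotomization of a raw chart column,
declared as a `var_spec()`: a success rule (category equality, numeric
threshold, set membership, or an arbitrary predicate) plus an optional
subpopulation rule restricting the denominator (e.g. a procedure variable
defined only among abortion cases). Missingness is handled listwise *per
variable*: a missing value removes the record from that variable's
denominator only, so each variable has its own valid `n` and — because a
sparse subpopulation may leave some centers empty — its own effective
number of clusters `a_eff`.

### Why `a_eff`?

A one-way ANOVA needs at least one observation per group. For variables
whose denominator is a handful of records (the smallest published
denominators correspond to mean cluster sizes of 8–13), not every center
can contribute. The package drops empty clusters for that variable,
records them in the `excluded_clusters` attribute, and uses `a_eff`
downstream — in the ANOVA degrees of freedom, in the empirical design
effect, and in the per-variable mean cluster size `n_a = round(valid_n /
a_eff)`. The alternative — keeping the full `a` in the formulas while some
groups are empty — is not defined.

## Estimators

**Prevalence.** The ratio estimator pools counts over clusters,
`r = Σ y_α / Σ x_α`, which equals the sample proportion over all valid
records. Cluster structure affects its *variance*, not its value.

**ICC.** The one-way ANOVA on the subject-level 0/1 values gives the
between- and within-cluster mean squares (`MSB` on `a − 1` df, `MSW` on
`n − a` df) and the moment estimator

ρ̂ = (MSB − MSW) / (MSB + (k − 1) · MSW).

Two conventions for the group-size coefficient `k` are provided:

- `k_method = "adjusted"` (default): `k₀ = (n − Σ nᵢ²/n)/(a − 1)`, the
  standard coefficient that makes the between-group mean square an
  unbiased estimate of `σ²_w + k₀ σ²_b` under unequal sizes. This is the
  convention of the classical one-way variance-components routines.
- `k_method = "mean"`: `k = n/a`, which makes ρ̂ algebraically identical
  to the F-statistic computing form `((F − 1)·a/n)/(1 + (F − 1)·a/n)`.

The two coincide for equal cluster sizes; for unequal sizes the F-form is
a documented approximation, and the test suite checks both the exact
agreement in the balanced case and the algebraic identity of the `"mean"`
variant in general. A negative moment estimate (between-variance below its
null expectation) is retained in `rho` and clamped to 0 in
`rho_reported`; the reporting layer prints values below 0.001 in the
spirit of the published tables' "<0.001" convention.

**Standard error and confidence interval.** The reported `se` is Smith's
large-sample variance of the ANOVA ICC for unequal group sizes (the
formula classical software reports alongside the one-way estimator),
always evaluated with `k₀`. Simulation during development showed that the
symmetric interval `ρ̂ ± z·se` under-covers substantially at `a = 27`
clusters of this imbalance, even for Gaussian data: the SE grows with ρ,
so a downward-fluctuating estimate gets a short interval that misses the
truth from below. The F-based ANOVA interval, exact only for balanced
designs, degrades similarly here. The default interval therefore applies
the normal approximation on the Fisher-type variance-stabilizing scale

h(ρ) = log( (1 + (k₀ − 1)ρ) / (1 − ρ) ) / k₀,

whose derivative is the reciprocal of the factor `(1 − ρ)(1 + (k₀ − 1)ρ)`
that drives the SE — the delta method then gives an approximately
constant-width interval on the `h` scale, back-transformed and clamped to
`[0, 1]`. The critical value is `t` with `a − 1` degrees of freedom, the
usual small-sample convention in cluster-sample inference where
between-cluster information comes from `a` units. The plain interval
remains available as `ci_method = "wald"`. The acceptance test verifies
empirically that the default interval's coverage lies in the 90–98% band
at the study's own operating point (binary data, μ ≈ 0.095, ρ ≈ 0.077, the
real size vector). Coverage degrades as ρ grows, because the normal-theory
SE increasingly understates the sampling variance of the estimator on
Bernoulli data; the interval is calibrated for the low-ICC regime
(ρ ≲ 0.1) in which three quarters of the published variables sit.

**Design effect.** The empirical design effect compares the achieved
variance of `r` to its SRS counterpart:

- `var_actual = Σ_α (r_α − r)² / (a(a − 1))` — the variance of a mean of
  `a` *unweighted* cluster ratios. Weighting the ratios by cluster size
  would be statistically tempting, but the unweighted form is the printed
  survey estimator this package implements, and fidelity wins;
- `var_SRS = r(1 − r)/(n − 1)` with `n` the *valid* denominator
  `Σ x_α` (for variables with missing data the SRS reference uses the
  same records the design variance uses — using the full cohort `n` would
  deflate the reference variance and inflate DEFF spuriously).

`deff = var_actual / var_SRS`, undefined (flagged) when `r ∈ {0, 1}`. For
equal cluster sizes of size `b` the classical identity
`deff ≈ 1 + (b − 1)ρ` holds in expectation; the test suite checks this by
simulation.

**Sample-size recalculation.** `n* = ceiling((a/ICC)·(DEFF − 1 + ICC))`.
With `DEFF = 1` the formula collapses to `n* = a`. The ceiling is taken
after rounding away sub-1e-8 floating-point noise so that algebraically
integer results are not bumped up a unit.

## Degenerate inputs

- `MSW = 0, MSB > 0` (every cluster internally constant): `F = ∞`,
  `ρ̂ = 1`, flag `degenerate`; no CI.
- all values identical: no variance to partition; `ρ̂` reported as 0 with
  a warning and flag `constant`.
- `MSB = 0`: the raw estimate is negative; reported as 0.
- a variable valid in fewer than 2 clusters cannot be estimated and is
  flagged as an error row by the pipeline rather than dropped silently.

## The synthetic-cohort generator

`sim_scenario()` / `generate_cohort()` draw from a beta-binomial process:
cluster `α` receives `p_α ~ Beta(μθ, (1 − μ)θ)` with `θ = (1 − ρ)/ρ`
(degenerating to `p_α = μ` at `ρ = 0`), and subjects are independent
Bernoulli(`p_α`). Under this model the marginal prevalence is exactly μ
and the intraclass correlation of the generated values is exactly ρ — no
latent-scale conversion, which makes parameter recovery a clean
validation target for the ANOVA estimator. Defaults mirror the study
conditions: the real 27-center size vector, sizes fixed rather than
resampled (the design observes every admission in every center).

What the generator deliberately does **not** emulate: informative
missingness (masking is completely at random, while real chart
abstraction loses sicker patients non-randomly), correlation between
variables (each variable in a multi-variable cohort is drawn
independently on the shared cluster frame), and any region-level structure
beyond the cluster tag. Passing recovery tests therefore demonstrates
estimator correctness under the stated model, not robustness to those
real-data features.

## Validation problem sizes

The test suite validates at sizes chosen to keep the full run around half
a minute while leaving Monte-Carlo error well inside the asserted
tolerances: 1,000 random small instances (≤ 5 clusters of ≤ 6) for exact
agreement with from-definition arithmetic at 1e−12; 200 replicate cohorts
on the full network design for recovery of (μ = 0.095, ρ = 0.077) — and of
ρ ∈ {0.02, 0.08, 0.3} — to within 0.01 on the ICC; 500 replicates for CI
coverage; 100–300 replicates for the independence limit, the strong
clustering limit, the ordering property and the `1 + (b − 1)ρ` identity.

## Reporting conventions

Report rows round prevalence to 1 decimal (in percent), ICC and CI bounds
to 3, DEFF to 2, and `n_a` to the nearest integer, matching the published
tables the embedded fixture transcribes. In fixture computations a printed
"<0.001" is valued at 0.0005 (half its bound): this preserves ordering
without inventing precision, and the affected entries lie far from any
reported median. Summary medians use R's standard midpoint rule for even
counts. The embedded table keeps the two printed duplicate row labels
unique by suffixing "(near miss criteria)" on their second occurrence.

## Known limitations

- The ANOVA ICC is the linear moment estimator on 0/1 data, as used in
  the surveillance literature this package follows; it is not a
  model-based binary ICC (no random-intercept logistic or latent-threshold
  estimator is provided, by design).
- CI coverage is calibrated for small ρ; for ρ well above ~0.1 on binary
  data both offered constructions under-cover at 27 clusters.
- Published per-variable CIs cannot be reproduced exactly without the
  original subject-level data; the fixture supports regression checks of
  the reporting layer, not re-derivation of the published values.
- No finite-population correction: centers are treated as sampled from a
  conceptually infinite population of hospitals.
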