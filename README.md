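# svyicc

Intraclass correlation and design effects for single-stage cluster
surveillance cohorts.

## The problem

Multicenter surveillance studies of severe maternal morbidity (potentially
life-threatening conditions, maternal near miss, maternal death) typically
enrol every eligible woman admitted to each participating hospital: a
single-stage cluster sample in which the hospitals are the primary sampling
units and the women the units of analysis, with no stratification or
weighting. Women treated in the same center resemble each other — shared
protocols, shared case mix — so estimates from such a design carry more
variance than a simple random sample (SRS) of the same size would. Two
quantities describe the penalty, per dichotomized variable:

- the **intraclass correlation coefficient (ICC, ρ)** — the share of
  outcome variance attributable to between-center variation;
- the **design effect (DEFF)** — the ratio of the estimator's variance
  under the cluster design to its variance under SRS.

`svyicc` implements the full estimation pipeline for this setting, for
epidemiologists planning or analysing hospital-network studies:

- **Prevalence** by the cluster ratio estimator
  `r = Σ y_α / Σ x_α` over the per-cluster valid denominators `x_α` and
  success counts `y_α` (missing values are dropped from the affected
  variable's denominator only);
- **ICC** by the one-way ANOVA (moment) estimator
  `ρ̂ = (MSB − MSW) / (MSB + (k₀ − 1)·MSW)`, where `MSB` and `MSW` are the
  between/within-cluster mean squares and
  `k₀ = (n − Σ nᵢ²/n)/(a − 1)` the unequal-group-size coefficient; for
  equal cluster sizes this equals the F-statistic computing form
  `((F − 1)·a/n) / (1 + (F − 1)·a/n)`. The standard error is Smith's
  large-sample formula; the default confidence interval applies the normal
  approximation on the variance-stabilizing scale
  `h(ρ) = log((1 + (k₀−1)ρ)/(1 − ρ))/k₀` with a `t(a−1)` critical value;
- **DEFF** empirically as
  `var_actual(r) / var_SRS(r)` with
  `var_actual = Σ(r_α − r)² / (a(a−1))` over unweighted cluster ratios and
  `var_SRS = r(1 − r)/(n − 1)`;
- **Sample-size recalculation** for a future cluster study,
  `n* = (a/ICC)·(DEFF − 1 + ICC)`, rounded up;
- a **beta-binomial cohort generator** with exactly known (μ, ρ) on the
  27-center / 9,555-subject network size structure, so every estimator is
  validated by parameter recovery without any external data;
- a **reporting pipeline** (declarative YAML dichotomization config →
  per-variable results CSV → block summaries) and an **embedded reference
  table** of 154 published per-variable estimates from the Brazilian
  severe-maternal-morbidity surveillance network for regression checks.

## Worked example

Simulate a cohort on the real network's cluster-size structure with a
near-miss-like prevalence of 9.5% and a true ICC of 0.077, then estimate:

```r
library(svyicc)

sc <- sim_scenario(mu = 0.095, rho = 0.077, seed = 4)
cohort <- generate_cohort(sc, variable = "near_miss_death")
cohort
#> <svy_cohort> 9555 subjects in 27 clusters ('cluster'), 2 columns

vr <- estimate_variable(cohort, generated_var_spec("near_miss_death"))
vr
#> <variable_result> near_miss_death [outcome]: P = 8.1%, ICC = 0.096 (CI 0.046-0.188), DEFF = 57.02, n_a = 354
```

The estimated prevalence (8.1%) and ICC (0.096, CI covering the true
0.077) are one draw from their sampling distributions; `n_a = 354` is the
mean cluster size of the full denominator. Correcting a future study's
sample size for this amount of clustering:

```r
recalc_sample_size(a = 27, icc = 0.096, deff = 57.02)
#> <sample_size_result> n* = 15783 subjects (a = 27, ICC = 0.096, DEFF = 57.02)
```

Summaries of the embedded published table reproduce the network's reported
statistics — process-of-care variables are about 2.6 times more homogeneous
across centers than outcome variables, and three quarters of all variables
have ICC < 0.1:

```r
summarize_results(network_table_fixture(), main_outcome = "Maternal Death + NM")
#> ...
#>    process          37      0.090 ...       20.52 ...
#>    outcome          69      0.021 ...        6.24 ...
#> process / outcome mean ICC ratio: 2.60
#> proportion of variables with ICC < 0.1: 0.75
#> recalculated n* for 'Maternal Death + NM': 7072 subjects (a = 27, ICC = 0.077, DEFF = 21.09) = 74% of the 9555 observed
```

A file-based pipeline (`run_pipeline()`) and a thin CLI
(`inst/scripts/svyicc-cli.R`, subcommands `estimate`, `simulate`,
`summarize`, `check`, `recalc-n`) wrap the same functions for shell use.

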