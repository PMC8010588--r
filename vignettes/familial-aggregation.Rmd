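---
title: "Familial aggregation of a binary diagnosis: methods and modelling choices"
author: "famagg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial aggregation of a binary diagnosis: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`famagg` estimates how strongly a binary diagnosis aggregates in families,
using a national-registry-style design: every person's diagnosis status is
related to the status of their relatives across four relationship classes of
graded genetic resemblance — twins, full siblings, half-siblings, and first
cousins. The package covers the whole analysis path:

1. registry input/output and follow-up window construction,
2. relative-pair extraction from parent links with eligibility rules,
3. twin zygosity composition by the Weinberg differential method,
4. familial-association estimation (incidence rates, odds ratios,
   tetrachoric correlations, a resemblance-by-family-history interaction,
   resemblance-risk trends),
5. event-free survival comparison (Kaplan-Meier, log-rank),
6. a liability-threshold registry simulator used for validation, and
7. a one-command pipeline writing a delimited-text report bundle.

Everything is driven by the central fitting function `famagg()`, which
returns a classed object with `print()`, `summary()`, `coef()` and `plot()`
methods.

# The statistical model

## Design: double-entered relative pairs

Each unordered relative pair {i, j} contributes two analysis rows, one with
each member as the index person ("double entry"). The exposure is the
relative's status; the outcome is the index person's own diagnosis. Double
entry makes the 2×2 cross-classification symmetric by construction
(`n10 == n01`), so the crude odds ratio and the tetrachoric correlation are
invariant to orientation.

A person-level summary sits next to the pair-level table: a person is
*exposed* if they have at least one affected relative of the class under
study, classified at baseline (ever-affected during the study window). The
incidence rates, rate ratio, and crude OR are computed from this
person-level summary; the adjusted OR and interaction model are fitted on
the pair-level rows.

With `entry = "single"` each unordered pair contributes one regression row.
Because exposure is an attribute of the person, the 2×2 table and the
person-level summary are always formed from the full double-entered pair
set; single entry thins only the regression rows. Consequently the crude OR
and tetrachoric point estimates are identical between the two settings, and
the adjusted OR changes only by fitting noise while its confidence interval
widens — the expected behaviour of the single-entry sensitivity analysis.
Standard errors under double entry are reported as fitted, without a
clustering correction; the single-entry refit is the honest companion
analysis.

## Estimators

**Incidence rate.** `1000 · cases / person-years`. The default 95% interval
is the exact Poisson (gamma) interval; `ci_method = "lognormal"` gives the
Wald interval on the log rate, `rate · exp(±1.96/√cases)`. Both are offered
because the two conventions coexist in the applied literature and differ
visibly at small case counts; the exact interval is the default because it
has guaranteed coverage. Published unexposed-group rates in this design are
sometimes not exactly reproducible from their own printed numerator and
denominator (e.g. a printed 1.34 where the printed counts give 1.33);
`famagg` always reports full-precision rates computed from the data rather
than matching any rounded display value.

**Crude OR.** Woolf (log-OR Wald) interval. A zero cell triggers the
Haldane–Anscombe 0.5 continuity correction with a warning — standard,
documented, and testable behaviour rather than a silent failure.

**Adjusted OR.** Logistic regression of the index person's status on the
relative's status, adjusted for any of birth year, sex, county, and
education (>11 years). Covariates that are constant in the data are dropped
rather than producing rank-deficient fits; coefficient magnitudes above 15
on the log scale raise an explicit separation error.

**Tetrachoric correlation.** The correlation of a latent bivariate normal
inferred from the 2×2 table, by two-step maximum likelihood: thresholds are
fixed at the probits of the margins, then the likelihood is maximised over
ρ alone. The bivariate normal CDF uses the single-integral reduction
`Φ₂(h,k,ρ) = Φ(h)Φ(k) + ∫₀^ρ φ₂(h,k,r) dr`, which is deterministic and
accurate without any external dependency. Two-step ML (rather than full ML
over thresholds and ρ jointly) is standard practice for tables of this
size and keeps the estimate deterministic. Perfectly concordant tables are
clamped to ρ → ±1 with a warning; degenerate margins (an empty row or
column) are an error. The test suite checks the estimator against an
independent brute-force oracle that grid-searches ρ with numerically
integrated orthant probabilities.

**Resemblance-by-family-history interaction.** All pair rows across the
relationship classes are pooled and a logistic model with
`relative affected × genetic resemblance` is fitted. Genetic resemblance is
1.0 for MZ twins, 0.5 for DZ twins and full siblings, 0.25 for
half-siblings, 0.125 for first cousins; the twin class, whose zygosity is
latent, carries the Weinberg mean resemblance (see below). Resemblance is
coded continuously by default — the natural reading of "an interaction term
between genetic resemblance and syncope in relatives" — with
`coding = "categorical"` available because the choice is not forced by the
design. A positive interaction is the package-level test of the genetic
gradient: risk in the index person rises more steeply with family history
the more genome the pair shares.

**Trend.** `pearson_trend()` correlates the per-class resemblance values
with the per-class estimates (tetrachoric or adjusted OR); it requires at
least three classes and refuses zero-variance input.

## The Weinberg differential method

Twin zygosity is not observed in registry data. Because DZ co-twins have
independent sexes, the DZ pair count is estimated as twice the
opposite-sex pair count, MZ as the remainder:

```
n_DZ = 2 · n_opposite_sex
n_MZ = n_pairs − n_DZ
mean resemblance = (1.0 · n_MZ + 0.5 · n_DZ) / n_pairs
```

`weinberg()` implements exactly this and errors on a negative MZ remainder
(more opposite-sex than same-sex pairs, impossible under the model). In a
`famagg()` fit the estimated mean resemblance replaces the twin class's
default resemblance of 0.66 whenever twin pairs are present.

## Follow-up windows

Follow-up runs from `max(birth year, study start)` to
`min(first event year, death, emigration, study end)`, in whole years — the
resolution of registry extracts. Persons whose window closes before it
opens (died or emigrated before study start, or born after study end) are
flagged `excluded`. A person whose event falls in their first follow-up
year receives 0.5 person-years rather than zero, so no event carries zero
exposure time; this floor is stated explicitly so that tests are
deterministic.

## Eligibility rules

`exclusion_rules()` reproduces a registry study's cohort definition: both
parents identifiable; born in the country; no emigration before age 17;
index generation born within a fixed span (default 1948–2005) and parents
within theirs (default 1932–1985); and removal of whole nuclear families in
which any member died or emigrated before study start. Exclusions operate
at the person level and poison every pair the person belongs to; a log of
dropped unordered pairs per rule is attached to the result.

## Survival comparison

`km_curve()` and `log_rank()` wrap `survival::survfit()`/`survdiff()` —
the product-limit and log-rank machinery is deliberately *not*
reimplemented; the package adds the grouping by family history
(`relative_history_groups()`), the window-to-time adaptation, and tidy
output. The test suite still validates both against hand-rolled oracles so
that the adaptation layer (time origin, the 0.5-year floor, tie-handling
convention) is pinned down.

# The registry simulator

`simulate_registry()` generates a synthetic multigeneration registry from a
liability-threshold model, primarily to validate the estimators by
parameter recovery.

## Structure

Each simulated family spans three generations: a founder couple with two
full-sibling children, whose own marriages produce two cousin-linked
sibships; with probability `twin_prob` a sibship opens with a twin pair
(MZ with probability `mz_fraction_of_twins`; MZ co-twins share sex and
additive genotype), and with probability `half_sib_prob` one parent has a
child by another partner, creating half-sibling links. This yields all four
relationship classes with correct kinship coefficients, verified in tests
against a brute-force O(n²) kinship classifier.

## Liability model

Liability is `L = A + C + E` with variances `h2`, `c2`, `1 − h2 − c2`.
Additive values are transmitted as
`A_child = (A_mother + A_father)/2 + N(0, h2/2)`, which induces additive
correlations of 1 (MZ), 0.5 (DZ/full siblings), 0.25 (half-siblings),
0.125 (first cousins) without ever materialising a joint covariance
matrix. A person is liable when `L` exceeds a threshold chosen by
root-finding so that the *population* prevalence matches
`target_prevalence` under the sex-mixture marginal (females receive a mean
liability shift `female_liability_shift`, producing the female excess seen
in syncope cohorts).

## Default parameters and why

The defaults are the study conditions the simulator is meant to emulate;
they are not free knobs:

- `target_prevalence = 0.023` — a 2.3% diagnosed fraction over a
  19-year national follow-up.
- `mz_fraction_of_twins = 0.31` — the MZ share implied by a twin set whose
  Weinberg mean resemblance is 0.66.
- `female_liability_shift = 0.15` — reproduces a roughly 2.9% vs 1.7%
  female/male affected split at the default prevalence.
- `differential_frac = 0.0207` — a ~2% rate of differential
  (non-reflex) transient-loss-of-consciousness codes, so the
  `exclude_differential` sensitivity analysis has something to remove.
- onset age ~ lognormal(log 22, 0.537) — median 22 with interquartile
  range ≈ 16–33, matching a young, right-skewed first-event distribution.
- `h2 = 0.25`, `c2 = 0` — a modest heritability consistent with observed
  tetrachoric gradients (≈ g·h2 per class).

## What the simulator does and does not emulate

It emulates: graded familial correlation of a binary lifetime diagnosis,
latent zygosity, female excess, censoring by death/emigration/study end,
year-granularity events, differential diagnosis codes, and registry-shaped
tables. It does **not** emulate: assortative mating, shared-environment
structure beyond a single `c2` component, secular trends in diagnosis
rates, sibship-size variation beyond the configured counts, age-dependent
hazards beyond the onset-age draw, or diagnostic misclassification.

One deliberate simplification matters for interpretation: each liable
person's onset age is drawn *truncated into their follow-up window*, so in
censoring-free configurations "affected" coincides exactly with "liable".
This makes parameter recovery exact (prevalence and per-class tetrachoric
values match their liability-scale targets up to Monte-Carlo error) at the
cost of not modelling lifetime-vs-window attenuation. Validation tests
exploit this; analyses of real extracts are unaffected.

# Numerical choices

- Thresholds and orthant probabilities use `stats::qnorm` /
  `stats::integrate` with tight tolerances; no stochastic integration.
- The tetrachoric SE comes from a numeric second difference of the profile
  log-likelihood at the optimum.
- Person-time is computed in whole years with the 0.5-year event floor.
- Display rounding is two decimals for rates, ORs, and correlations;
  internal values are never rounded.
- Age strata default to bands `<20`, `20–39`, `≥40` at first event
  (configurable via `age_breaks`).

# Limitations

- Double-entry standard errors ignore the dependence between the two
  orientations of a pair and between pairs sharing a person; compare with
  the `single_entry` sensitivity refit for honest uncertainty.
- The Weinberg method estimates composition, not individual zygosity; the
  twin class's resemblance is a mixture mean.
- Year-granularity follow-up cannot resolve within-year timing; all
  persons with an event in their first year receive the same 0.5
  person-years.
- Exposure is classified at baseline (ever-affected relative); a
  time-dependent exposure analysis is out of scope.
- The pipeline analyses one diagnosis code at a time (default `"R559"`).

# A worked run

```{r}
library(famagg)
sim <- simulate_registry(liability_params(n_families = 5000, twin_prob = 0.5,
                                          half_sib_prob = 0.5, seed = 1))
fit <- famagg(sim$registry)
summary(fit)
coef(fit)                      # adjusted ORs per relationship class
logrank_by_relation(fit)
plot(fit)                      # KM panels by family history
```

Or, end to end with a written report bundle:

```{r}
cfg <- run_config(params = liability_params(n_families = 5000, seed = 1),
                  stratify_by = "sex", sensitivity = "single_entry")
res <- run_all(cfg, out_dir = "famagg-report")
```
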