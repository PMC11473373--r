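---
title: "Methods: two-stage meta-analytic mediation of correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage meta-analytic mediation of correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapath)
```

## The statistical problem

Each included study contributes one independent sample with three Pearson
correlations: physical activity with resilience (r_XM), physical activity
with a mental-health indicator (r_XY), and resilience with that indicator
(r_MY), plus the sample size n. Mental health is treated under a two-factor
view — positive indicators (subjective well-being, life satisfaction) and
negative indicators (depression, anxiety, negative affect) form separate
analysis strata, because the two families of outcomes need not mirror each
other. The question is whether resilience mediates the activity–mental
health association, answered in two stages: pool the correlations across
studies, then fit a path model to the pooled matrix.

## Stage 1: random-effects pooling on the Fisher-z scale

All pooling happens on the variance-stabilized scale
z = ½·ln((1+r)/(1−r)), with sampling variance 1/(n−3); the r scale is used
only for presentation (point estimates and CI endpoints are
back-transformed with tanh). No small-sample bias correction is applied to
r before transformation. The random-effects model assumes study-true
effects scatter around a common mean with between-study variance τ²,
estimated by the DerSimonian–Laird moment formula

τ² = max(0, (Q − df) / (Σw − Σw²/Σw)),  w = 1/v,

the default because it is also the default of the commercial software most
correlation meta-analyses in this literature are run with; a
restricted-maximum-likelihood estimator is available through
`tau2_estimator = "reml"` (profiled to an absolute tolerance of 1e-10).
Confidence intervals are Wald intervals on the z scale with normal
quantiles, back-transformed; α = 0.05 two-sided throughout. With a single
study the "pooled" result is that study with τ² = 0; Q and I² require at
least two.

One reporting caveat is deliberate: the Wald statistic we report is
z*/se* from the random-effects model. Published tables of this design
sometimes print z statistics that are inconsistent with their own printed
confidence intervals (plausibly from a different test); we make no attempt
to reproduce such columns.

## Publication-bias diagnostics

* **Fail-safe N** uses Rosenthal's Stouffer-sum formulation with per-study
  deviates u = z·√(n−3) and the two-tailed criterion z = 1.959964:
  N_fs = ⌈(Σu)²/1.96² − k⌉, clipped at zero. The ceiling is intentional —
  the count of additional null studies *needed* to overturn significance
  rounds up — and matches how the reference software prints these values.
  The conventional robustness threshold 5k + 10 is attached to the result.
* **Funnel data** are exported as (z, se) points with pseudo-confidence
  guide lines; the package deliberately has no plotting dependency.
* **Trim-and-fill** implements the Duval–Tweedie iterative L₀ estimator.
  In each iteration the funnel is centred on the pooled estimate of the
  currently trimmed set computed under the *same random-effects model as
  the main analysis* (not fixed-effect weights); absolute centred effects
  are ranked with ties broken by position, the signed-rank sum yields
  k0 = max(0, round((4·T − k(k+1))/(2k − 1))), and the k0 most extreme
  same-side studies are trimmed until k0 stabilizes (cap: 50 iterations).
  Mirrored studies are then imputed about the final centre and the filled
  set is re-pooled with τ² re-estimated. `side = "auto"` assumes
  suppression on the side toward the null. Random-effects centring matters:
  with fixed-effect centring the highly heterogeneous strata of the
  packaged table would spuriously impute studies. Fewer than three studies
  yields a warning and k0 = 0. We always run trim-and-fill and report k0;
  whether bias is "confirmed" is left to the analyst reading the combined
  diagnostics.

## Stage 2: pooled matrix and saturated path model

Each of the three cells is pooled *independently* by the univariate
machinery above, and the unit-diagonal 3×3 matrix is assembled and checked
for positive definiteness (failure is an error naming the offending
triple). This two-stage, per-cell formulation is a deliberate design
choice: the published record this package reproduces pooled its matrix
with a one-stage web tool whose internal cells differ slightly (third
decimal) from univariate pooling, but its downstream path table is exactly
recoverable from its printed matrix via the closed forms below. We
therefore treat the printed pooled matrices
(`published_pooled_matrices()`) as the canonical stage-2 input, accept the
small stage-1 discrepancies, and document them; multivariate (GLS) stage-1
pooling is out of scope.

The effective sample size attached to a pooled matrix is the harmonic mean
of the stratum's study sizes — common two-stage MASEM practice; it affects
only fit-block scaling and any n-based cell variances, never the point
estimates.

The mediation model (X → M → Y with a direct X → Y path) is saturated:
df = 0, the implied matrix reproduces the input exactly, and the fit block
is trivially perfect (χ² ≈ 0, CFI = TLI = 1, RMSEA = 0) — reported for
completeness, not as evidence of fit. Standardized coefficients come from
the closed forms

a = r_XM, b = (r_MY − r_XM·r_XY)/(1 − r_XM²), c = (r_XY − r_XM·r_MY)/(1 − r_XM²),

with ab = a·b, d = ab + c = r_XY, and proportion mediated 100·ab/d
(sign-safe; |ab| > |d| flags inconsistent mediation with a warning, d = 0
leaves the proportion undefined). `method = "ml"` minimizes the
normal-theory discrepancy F = log|Σ(θ)| + tr(SΣ(θ)⁻¹) − log|S| − 3 over
(a, b, c) with analytic gradients, BFGS, and a Newton polish on the
gradient (stopping at a gradient norm of 1e-13). This is a first-class
independent numerical route — the tests require it to agree with the
closed forms to 1e-8 across random positive-definite inputs.

## Confidence intervals for the paths

The published record's CI machinery for the paths is not fully specified
("likelihood method" via a web tool), so we chose the standard robust
construction and hold comparisons to it only loosely. The default is Monte
Carlo: each cell is drawn on the z scale from Normal(z_pooled, se_z²)
using the stage-1 random-effects standard errors, back-transformed, pushed
through the closed forms, and summarised by 2.5/97.5 percentiles — the
usual asymmetric interval for a product of coefficients. The default is
10⁵ replicates with a mandatory seed; fewer than 10³ is refused. The delta
method (first-order propagation; var(ab) = a²·var(b) + b²·var(a)) serves
as the symmetric cross-check, and the tests require the two constructions
to agree within 15% of the Monte-Carlo interval width on the packaged
matrices.

## The synthetic-data generator

`simulate_coding_table()` emulates exactly the data-generating process the
random-effects pooling assumes: study-true Fisher-z cells drawn
independently per cell from Normal(atanh(ρ), τ²), back-transformed,
repaired to the nearest positive-definite correlation matrix when a draw
strays (eigenvalues clipped at 1e-6, diagonal re-normalized — a rare,
deterministic fix), study sizes uniform over a configured range
(minimum 10), and sample correlations computed from actually generated
trivariate-normal observations rather than drawn from an asymptotic
distribution — exactness over speed at desk scale. Generation is fully
reproducible under the configured seed.

Two limitations are intentional and documented rather than fixed: the
generator puts *independent* heterogeneity in each cell (no correlated
random effects between cells), matching the univariate stage-1 pooling it
is meant to validate; and it contains no publication-bias selection
mechanism, so passing recovery tests says nothing about the bias
diagnostics' power. It also cannot mimic features of real coding tables
such as shared sub-samples, non-normal item distributions, or indicator
heterogeneity within a stratum.

`recovery_experiment()` runs the full pipeline per replicate and reports
mean bias, empirical SE, and 95% CI coverage for the pooled cells, τ², and
the paths. The validation scenario exercised in the tests uses the
positive-stratum population values ρ = (0.263, 0.27, 0.453) with τ = 0.10,
k = 20 studies of 400–2,400 subjects, and 200 replicates with 4,000
Monte-Carlo draws per interval — sizes chosen to estimate coverage to a
few percentage points while keeping the suite quick at a desk. Coverage
for τ² is reported as NA: the DL machinery carries no τ² interval.

## Degenerate inputs and numerical conventions

* n < 4 is rejected everywhere (1/(n−3) must be finite and positive);
  |r| ≥ 1 is a domain error; tanh/atanh are used for the transforms, which
  are numerically safe for large |z|.
* An empty CSV with a valid header reads as a zero-row table with a
  warning; strict mode (default) turns any row-level invariant violation
  into an error, lenient mode drops offending rows with one warning each.
* Sub-samples coded from the same subjects are linked via
  `shares_sample_with`; subject totals count each linked group once (the
  packaged table's two linked rows are how its 16 samples contain 17,043
  unique subjects). The positive stratum of the packaged table has 9 rows
  while parts of the published record tabulate k = 8 without naming the
  exclusion; `subset_by_polarity()` and `run_config()` therefore accept an
  explicit `exclude_ids` so both runs are expressible. All headline checks
  use the unambiguous 7-row negative stratum.
* Report rendering prints correlations and CIs to 3 decimals and I² to 2,
  and is byte-deterministic for identical bundles.
* There is no command-line binary: the exported functions, the packaged
  table, and `scripts/acceptance.R` are the scripting surface.

## Known limitations

Moderator/subgroup analyses, meta-regression, Hartung–Knapp adjustment,
prediction intervals, Egger-type regression tests, selection models,
one-stage MASEM, and latent measurement models are out of scope. The
per-cell pooling ignores within-study correlation between the three
effects; with the small per-stratum k here that choice is pragmatic, but
it is the main structural approximation of the pipeline.
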