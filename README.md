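# metapath

Correlation meta-analysis with meta-analytic path (mediation) modeling.

`metapath` implements the complete quantitative pipeline of a two-stage
meta-analytic structural equation model (MASEM) for a three-variable
mediation question: does resilience mediate the association between
physical activity (PA) and mental health? It is aimed at meta-analysts in
psychology, epidemiology, and sports science who code per-study Pearson
correlations and want a reproducible, scriptable route from a coding table
to pooled correlations, publication-bias diagnostics, and indirect-effect
inference.

## The model

Per-study correlations r are pooled on the Fisher-z scale,
z = ½·ln((1+r)/(1−r)), with sampling variance Vz = 1/(n−3). A
random-effects model combines studies with weights wᵢ* = 1/(vᵢ + τ²),
where τ² (between-study variance) is estimated by DerSimonian–Laird
moments (REML optional). Heterogeneity is summarised by Cochran's
Q = Σwᵢ(zᵢ − z̄)² and I² = max(0, (Q − df)/Q)·100. Publication bias is
assessed by Rosenthal's fail-safe N (Stouffer sum, two-tailed criterion,
reference threshold 5k + 10), funnel-plot data export, and Duval–Tweedie
trim-and-fill with the L₀ estimator.

Stage 2 assembles the pooled 3×3 correlation matrix among PA (X),
resilience (M), and a mental-health indicator (Y) — positive indicators
(well-being, life satisfaction) and negative indicators (depression,
anxiety) are pooled as separate strata — and fits the saturated
standardized path model

    M = a·X + e₁
    Y = c·X + b·M + e₂

with closed forms a = r_XM, b = (r_MY − r_XM·r_XY)/(1 − r_XM²),
c = (r_XY − r_XM·r_MY)/(1 − r_XM²), indirect effect ab, total effect
d = ab + c = r_XY, and proportion mediated 100·ab/d. A
maximum-likelihood discrepancy fit of the same model is available as an
independent numerical route, and confidence intervals for the paths come
from Monte-Carlo propagation of the pooled cells (delta method as a
cross-check).

The package ships a coded study table of 16 independent samples from 15
published reports (17,043 unique subjects) relating the three constructs,
plus a synthetic coding-table generator with known population structure
for parameter-recovery validation.

## Worked example

```r
library(metapath)

tab <- pa_resilience_studies()            # packaged coding table
neg <- subset_by_polarity(tab, "negative")

pool_random(effects_from_table(neg, "re_mh"))
#> Random-effects pooled correlation (k = 7, tau2 = 0.0025 [dl])
#>   r = -0.321, 95% CI [-0.360, -0.280], z = -14.656, p = 1.23e-48
#>   Q = 22.667 (df = 6, p = 0.000916), I2 = 73.53%

fail_safe_n(effects_from_table(neg, "re_mh"))
#> Fail-safe N = 1480 (k = 7, threshold 5k+10 = 45, alpha = 0.05)

m <- fit_mediation(published_pooled_matrices()$negative)
m
#> Saturated mediation model (negative stratum, k = 7, n_eff = 864.1)
#>   a (X->M) = 0.273, b (M->Y|X) = -0.269, c (X->Y|M) = -0.183
#>   indirect ab = -0.073, total d = -0.256, mediated = 28.70%
#>   fit: chi2 = 0, df = 0, CFI = 1, TLI = 1, RMSEA = 0

ci <- mediation_ci(published_pooled_matrices()$negative,
                   "monte_carlo", reps = 1e5, seed = 42)
round(ci$ab, 3)
#> [1] -0.100 -0.049
```

Reading: resilience and negative mental-health indicators correlate at
−0.321 across the seven negative-indicator samples, with substantial
between-study heterogeneity (I² = 73.5%) and no fail-safe-N evidence of
publication bias (1480 ≫ 45). In the mediation model, PA relates to lower
depression/anxiety both directly (c = −0.183) and through resilience
(ab = −0.073, 95% MC CI [−0.100, −0.049]), the indirect path carrying
about 29% of the total effect of −0.256.

The full pipeline — both strata, all three relationships, bias
diagnostics, matrix pooling, mediation, rendered TSV tables and a JSON
bundle — runs as:

```r
cfg <- run_config(system.file("extdata", "pa_resilience_mh_studies.csv",
                              package = "metapath"),
                  seed = 42, output_dir = "out")
bundle <- run_full_analysis(cfg)
```

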