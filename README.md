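# medhaz

Mediation analysis of DNA copy-number effects on patient survival, with the
mediator being mRNA expression of the same gene.

## Who this is for

Integrative genomics studies measure DNA copy-number aberrations (DCNA) and
mRNA expression (both as continuous log2 ratios against normal tissue) on
the same tumors, together with follow-up time and vital status. Asking only
whether DCNA correlates with expression ignores the clinical endpoint;
putting DCNA and mRNA side by side in a Cox model treats them as independent
factors and can entirely miss an effect that is routed through
transcription. medhaz is for statisticians and bioinformaticians who want to
test, gene by gene and at genome scale, whether the effect of a copy-number
change on survival is *mediated* by the expression of that gene — the
signature of a driver rather than a passenger.

## The model

For each gene, two regressions:

- mediator model (OLS): `mRNA = α0 + α_m · DCNA + ε`
- outcome model (additive hazards, time-constant coefficients):
  `hazard(t | x) = β0(t) + λ_m · mRNA + λ_c · DCNA`

Because covariate effects add to the hazard, the decomposition is exact:

- mediated (indirect) effect: `α_m λ_m`
- direct effect: `λ_c`
- total effect: `α_m λ_m + λ_c`
- relative magnitude: `P_M = α_m λ_m / (α_m λ_m + λ_c)`

Inference for the mediated and total effects uses Delta-method variances,
e.g. `σ²_Med = α_m² σ²_λm + λ_m² σ²_αm`, with Z-tests and Wald intervals;
`P_M` uses generic gradient propagation `gᵀΣg`. For benchmarking, the
package also provides normal-product-distribution intervals (seeded Monte
Carlo) and four nonparametric bootstrap intervals (normal, basic,
percentile, BCa; case resampling of whole patients). A simulation engine
evaluates bias, MSE, coverage, interval width and tail errors of all
methods across sample sizes, and a screening pipeline runs the analysis
genome-wide with Benjamini–Hochberg FDR control and classifies genes into
complete / partial mediation, direct-only, or none.

The additive-hazards fitter is the closed-form constant-coefficient
estimating-equation solution with a sandwich covariance; the methods
vignette (`vignettes/mediation-survival.Rmd`) documents the estimator, the
generator design, all conventions (ties, quantile interpolation, seeds) and
known limitations.

## Worked example

```r
library(medhaz)

cfg <- sim_config(seed = 1)          # generative defaults, see vignette
cohort <- simulate_cohort(cfg, n = 300)
res <- mediate_survival(cohort)      # OLS + additive hazards + Delta method
res
```

```
Survival mediation analysis (Delta-method inference)
  n = 300 samples, 133 events; level = 0.95
               term estimate std.error statistic p.value conf.low conf.high
           mediated   0.2913    0.1216    2.3962 0.01657  0.05303    0.5296
              total  -0.2916    0.3286   -0.8872 0.37495 -0.93563    0.3525
             direct  -0.5829    0.3399   -1.7149 0.08637       NA       NA
 relative_magnitude  -0.9991    1.2357        NA      NA -3.42102    1.4229
  note: relative-magnitude inference is unstable at moderate n
```

Reading this: the mediated effect `α̂_m λ̂_m = 0.29` adds an estimated 0.29
events per time unit to the hazard via the transcriptional route and is
significant (p = 0.017) — close to the generative truth 0.31 of the default
configuration. The direct path estimate is negative and not significant at
the 5% level in this particular cohort, so the total effect is washed out;
the relative magnitude is meaningless here (its instability is exactly why
it is flagged). `tidy(res)` and `glance(res)` return the same information
as tibbles, `autoplot(res)` draws the interval plot.

The Monte-Carlo engine and its acceptance band:

```r
coverage_band(0.95, 1000)
#>   low  high
#> 0.936 0.964

report <- run_study(cfg, n_grid = c(25, 50, 75, 100),
                    methods = c("delta", "product_normal"))
autoplot(report, "coverage")
```

Genome-wide screening on a synthetic fixture with planted pathway genes:

```r
fx <- make_fixture(tempfile(), n_genes = 200, n_samples = 300,
                   n_pathway_genes = 20, config = sim_config(seed = 1))
aligned <- match_platforms(fx$data$dcna, fx$data$mrna, fx$data$survival)
hits <- screen_genes(aligned, family = "prefiltered", fdr = 0.05)
dplyr::count(hits, classification)
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/medhaz.R` (subcommands `simulate`, `fit`, `screen`).

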