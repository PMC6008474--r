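# repromr

Mendelian randomisation (MR) of reproductive timing — genetically predicted
age at menarche, age at natural menopause, and their combination as lifetime
endogenous oestrogen exposure — on colorectal cancer (CRC) risk in women.

The package is aimed at genetic epidemiologists who want the full analysis
as tested, composable functions: instrument curation exactly as a consortium
analysis performs it, weighted genetic risk scores with year-scaling,
one-sample GRS logistic MR with stratified and BMI-sensitivity variants,
two-sample summary-statistics estimators, instrument diagnostics, and power
calculation. A synthetic cohort generator reproduces the statistical
structure of a 12,944-case / 10,741-control female case-control consortium,
so every stage is testable without any individual-level data access.

## The model in brief

For woman *k* the genetic risk score over the curated instrument SNPs is the
plain weighted dosage sum

> GRS_k = Σ_n β_n G_kn,   G_kn ∈ [0, 2]

with β_n the published per-allele effect in years. The score is divided by a
calibration constant (0.57 menarche, 0.98 menopause; estimable per study by
`fit_scaling()`, the reciprocal of the first-stage slope of age on the
score) so the scaled score is the predicted exposure in years and the
logistic regression

> logit P(CRC) = α + θ · GRS_scaled + age + study + PCs

gives θ as the causal log odds ratio per year of exposure. Two-sample
estimators operate on per-SNP Wald ratios β_Y/β_X: inverse-variance
weighting, MR-Egger (intercept = directional-pleiotropy test), and the
weighted median with parametric-bootstrap standard errors. Instrument
strength is F = R²(n−K−1)/((1−R²)K) with the score as one instrument, and
power for the score's Wald test uses the normal approximation
Φ(|log OR|·√(N·R²·φ(1−φ)) − z) (+ the mirror tail), φ being the case
fraction.

## Worked example

```r
library(repromr)

# instrument manifest with the published curation accounting:
# 389 menarche SNPs, 12 on sex chromosomes, 42 needing proxies (7 unmatched),
# 12 correlated exclusions -> 358 analysed
manifest <- generate_manifest(389, n_sex_chr = 12, n_missing = 42,
                              n_no_proxy = 7, n_correlated = 12, seed = 389)
curated <- curate_instruments(manifest)
nrow(curated)
#> [1] 358

# synthetic cohort with a true effect of OR 0.90 per year of menarche age
spec <- simulation_spec(n_cases = 2000, n_controls = 2000, n_snps = 358,
                        causal_logor_per_year = log(0.9), n_studies = 4,
                        seed = 42)
ds <- generate_cohort(spec, curated)

grs_raw <- compute_grs(ds$dosages, ds$manifest,
                       controls = ds$cohort$case_status == "control")
scaling <- fit_scaling(grs_raw, ds$cohort$self_reported_menarche,
                       ds$cohort$study)
scaling
#> <scaling_fit> pooled beta = 0.5275 ( se 0.0316 ) from 4 study(ies)

fit_grs_logistic(ds$cohort, scale_grs(grs_raw, scaling))
#> <mr_estimate: grs_logistic> OR 0.906 (95% CI 0.773-1.062), p = 0.222

# two-sample estimators on matching summary statistics
ss <- generate_summary_stats(curated, spec)
mr_twosample_all(ss, n_boot = 1000, seed = 7)[, c("method", "or", "ci_lower",
                                                  "ci_upper", "pvalue")]
#> # A tibble: 3 × 5
#>   method             or ci_lower ci_upper pvalue
#>   <chr>           <dbl>    <dbl>    <dbl>  <dbl>
#> 1 ivw             1.07     0.801     1.43  0.639
#> 2 egger           0.835    0.520     1.34  0.455
#> 3 weighted_median 1.12     0.711     1.77  0.620

# diagnostics at the study's parameters
instrument_strength(c(0.069, 0.057), n = 23685)
#> # A tibble: 2 × 5
#>      r2     n     k     f strong
#>   <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1 0.069 23685     1 1755. TRUE
#> 2 0.057 23685     1 1432. TRUE
mr_power(12944, 10741, 0.069, 0.85)
#> [1] 0.9050364
mr_power(12944, 10741, 0.057, 0.90)
#> [1] 0.486997
```

The one-sample fit recovers the simulated OR 0.90 per year within its CI;
the scaling constant pools to ~0.53 (true value 0.57); the two-sample
estimators agree with the simulated null-to-weak effect; F-statistics of
1755 and 1432 mark both instruments as strong; the study-scale power is 91%
to detect OR 0.85 per SD of exposure and ~49% for OR 0.90.

`run_pipeline(run_config(...))` chains all stages — curation, genotype QC,
scoring, scaling, one-sample MR with BMI-adjusted and restricted-score
variants, stratified analyses, two-sample estimators, confounder screen,
funnel data and power — into a report object with deterministic TSV/JSON
writers (`write_report()`).

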