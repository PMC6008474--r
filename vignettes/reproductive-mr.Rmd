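---
title: "Mendelian randomisation of reproductive timing and colorectal cancer risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomisation of reproductive timing and colorectal cancer risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repromr)
```

## The question and the design

Exogenous oestrogen exposure (menopausal hormone therapy) is associated with
lower colorectal cancer (CRC) risk in women, but observational findings on
*endogenous* oestrogen exposure — proxied by age at menarche and age at
natural menopause — are inconsistent, plausibly because of recall bias and
confounding (childhood body mass in particular influences both menarche
timing and CRC risk). Mendelian randomisation (MR) sidesteps these problems
by using germline variants as instrumental variables: alleles are randomised
at conception, so a genetic score that shifts menarche or menopause timing
is, under the instrumental-variable assumptions, an unconfounded handle on
the exposure.

`repromr` implements that analysis as a reusable pipeline: instrument
curation, weighted genetic risk scores (GRS) with year-scaling, one-sample
GRS logistic MR with stratified and BMI-sensitivity variants, two-sample
summary-statistics estimators (IVW, MR-Egger, weighted median), instrument
diagnostics, and power calculation — together with a synthetic cohort
generator so every stage is testable without access to consortium
individual-level data.

## Instrument curation

Published instruments for the two exposures (389 menarche SNPs, 54 menopause
SNPs at genome-wide significance) are curated the way a consortium analysis
would:

* **sex-chromosome variants** are removed (not available in the genotype
  data);
* **missing variants** are substituted by linkage-disequilibrium proxies
  with \(r^2 > 0.8\), re-harmonised to the trait-increasing allele; variants
  with no qualifying proxy are dropped;
* **correlated instruments** (\(r^2 > 0.01\)) are pruned by removing the
  member of each pair with the higher exposure p-value, iterating until no
  offending pair remains. Ties are broken by dropping the lexicographically
  larger rsid, which makes curation deterministic and independent of row
  order.

Genotype QC removes score SNPs with call rate below 0.98, Hardy–Weinberg
equilibrium p below \(10^{-4}\) in controls (1-df chi-square on hard-called
genotypes — dosages are continuous, HWE is a genotype-level test), or minor
allele frequency at or below 1%.

For the lifetime-exposure score, menarche instruments are re-harmonised to
the menarche-*decreasing* allele (earlier menarche means longer oestrogen
exposure) before being combined with the menopause instruments, and
cross-trait correlated pairs (\(r^2 > 0.01\)) are pruned by the same
higher-p rule. A restricted menarche score excludes BMI-associated
instruments.

Strand-ambiguous (A/T, C/G) variants with effect-allele frequency in
[0.4, 0.6] are flagged but kept by default, preserving the published
instrument counts; `harmonise_instruments(drop_palindromic = TRUE)` drops
them.

## The genetic risk score and year-scaling

For woman \(k\), the raw score is the plain weighted dosage sum

\[ \mathrm{GRS}_k = \sum_n \beta_n G_{kn}, \]

with \(\beta_n\) the published per-allele effect (years) and
\(G_{kn} \in [0,2]\) the imputed allele dose. It is *not* divided by the SNP
count. Missing dosages are mean-imputed per SNP from controls (standard GRS
practice, unbiased under missingness at random); a strict-error mode is
available.

Raw scores are scaled into year units so that logistic odds ratios read as
risk change per year of exposure. The scaled score is the raw score divided
by a calibration constant (defaults 0.57 for menarche, 0.98 for menopause).
A point worth being explicit about, because it is easy to get wrong: the
constant that achieves a per-year causal interpretation is the *reciprocal
of the first-stage slope* — the slope of regressing self-reported exposure
age on the raw score. Dividing by that reciprocal makes the scaled score
exactly the two-stage-least-squares predicted exposure, and the logistic
coefficient of the scaled score is then the causal log odds ratio per year.
Dividing instead by either naive regression slope between score and age
attenuates the estimate (by roughly \(R^2\) or by the square of the weight
mis-calibration factor); our simulation oracles show 95% CI coverage
collapsing to ~35% under that mistake, versus nominal coverage under the
implemented construction. A menopause constant of 0.98 (close to 1) says
the published menopause weights are almost perfectly calibrated in the
analysis sample; 0.57 for menarche reflects substantial weight
mis-calibration. `fit_scaling()` estimates the constant per study
(delta-method standard error) and pools by inverse-variance fixed effects —
fixed rather than random effects, for consistency with the outcome
meta-analysis and because only two calibration studies are envisaged.

The lifetime score is the sum of the two scaled scores (menarche component
built on the flipped instrument set), so higher values mean longer
endogenous oestrogen exposure.

## One-sample MR

`fit_grs_logistic()` fits maximum-likelihood logistic regression of case
status on the scaled GRS, adjusted for age, study, and ancestry principal
components (complete-case within each model). Convergence is IRLS with
relative tolerance \(10^{-8}\) and up to 100 iterations; non-convergence and
apparent complete separation raise explicit errors rather than returning
degenerate output. Confidence intervals use the normal multiplier 1.96
throughout (large-sample setting). Consortium results are pooled by
fixed-effects (inverse-variance) meta-analysis under a common-effect
assumption.

Stratified analyses (`stratified_analysis()`) fit the model within each
stratum and test heterogeneity by a likelihood-ratio test comparing the
pooled model with and without a GRS-by-stratum interaction (chi-square,
levels − 1 df). The colon-versus-rectum contrast uses a case-only logistic
regression of site on the GRS. BMI sensitivity comes in two forms:
adjustment by an auxiliary BMI genetic score passed as an extra covariate,
and the restricted instrument set excluding BMI-associated SNPs.

## Two-sample MR

From per-SNP exposure/outcome associations the package computes Wald ratios
\(\hat\theta_j = \beta_{Y_j}/\beta_{X_j}\) with first-order delta-method
standard errors \(se_j = se_{Y_j}/|\beta_{X_j}|\), and three estimators:

* **IVW** — zero-intercept weighted regression of outcome on exposure betas
  with weights \(1/se_{Y_j}^2\), equal to the precision-weighted mean of
  ratios; fixed-effect standard error without over-dispersion scaling.
* **MR-Egger** — the same regression with a free intercept, after orienting
  exposure betas non-negative (Egger regression is not
  orientation-invariant). The intercept estimates average directional
  pleiotropy; the slope is a pleiotropy-adjusted causal estimate under the
  InSIDE assumption. Standard errors are residual-variance based, so
  balanced pleiotropy widens them appropriately — our calibration oracle
  confirms ~95% intercept CI coverage under balanced pleiotropy and ≥80%
  rejection at a mean direct effect of 0.02 across 50 instruments.
* **Weighted median** — ratios are ordered, inverse-variance weights
  normalised and accumulated, and the estimate linearly interpolated at
  cumulative weight 1/2 with SNP \(j\) at position \(S_j - w_j/2\).
  Exactly tied ratios are merged (weights summed) before interpolation;
  this leaves generic inputs untouched and makes the estimator exactly
  invariant to duplicating every SNP. The standard error is a parametric
  bootstrap (default 10,000 replicates): both beta columns are resampled
  from normal distributions at their reported SEs and the estimator
  recomputed; the CI is estimate ± 1.96·SE. The estimator is consistent
  while valid instruments carry at least half the weight.

Funnel data pair each ratio with its precision \(1/se_j\); the asymmetry
test regresses the standardised ratio on precision and reports the
intercept p-value (an Egger-type funnel test).

## Diagnostics and power

Instrument strength is summarised by
\(F = R^2(n-K-1) / ((1-R^2)K)\) with the GRS treated as a single instrument
(\(K = 1\)) and \(n\) the analysis sample size — the convention under which
the published strengths (1755 for menarche at \(R^2 = 0.069\), 1431 for
menopause at \(R^2 = 0.057\), \(n = 23{,}685\)) follow from the formula.
With \(K\) set to the SNP count the same formula gives values two orders of
magnitude smaller, so both parameters are explicit arguments rather than
guessed.

The confounder screen regresses each risk factor on the GRS among controls
— linear for continuous factors, logistic for binary, multinomial with a
likelihood-ratio p for multi-level factors — and reports raw p-values
(screens are descriptive; no multiplicity correction).

Analytic power for the two-sided Wald test of the score is

\[ \Phi\!\left(|\log OR|\sqrt{N R^2 \varphi(1-\varphi)} - z_{1-\alpha/2}\right)
 + \Phi\!\left(-|\log OR|\sqrt{N R^2 \varphi(1-\varphi)} - z_{1-\alpha/2}\right), \]

with \(\varphi\) the case fraction; it reduces exactly to \(\alpha\) at the
null. The simulation mode draws replicate score-outcome cohorts
(standard-normal score, exposure of which the score explains \(R^2\),
logistic risk, retrospective sampling to exact counts) and counts Wald
rejections; the two modes agree within Monte-Carlo error. At the study's
sizes the analytic power is 90.5% for OR 0.85 per SD at \(R^2 = 0.069\) and
84.4% at \(R^2 = 0.057\); at OR 0.90 per SD it is 56.4% and 48.7%
respectively. The published "around 50%" figure for OR 0.90 is therefore
the one reproduced at the menopause instrument's explained variance — the
weaker of the two instruments, which is the binding constraint on
detectability claims made for both exposures jointly.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes. Defaults are the study's conditions: 12,944 cases and 10,741
controls, a 358-SNP menarche instrument with \(R^2 = 0.069\) (menopause:
51 SNPs, \(R^2 = 0.057\)), exposure SDs of 1.5 years (menarche, mean 13)
and 4.8 years (menopause, mean 50), 26 contributing study labels (the real
consortium's per-study sizes are not public, so labels are drawn with equal
probability), no causal effect on disease (the study's conclusion), and a
weak BMI path into both exposure (−0.05 y per kg/m²) and disease (0.02
log-odds per kg/m²).

Mechanics and deliberate simplifications:

* Hard genotypes are binomial(2, eaf) per SNP, independent across SNPs — LD
  exists only as flagged correlated/proxy pairs in the manifest, not in the
  genotypes themselves. Imputation is mimicked by shrinking hard calls
  toward \(2\times\)eaf with a per-SNP quality drawn from [0.9, 1]
  (matching reported mean imputation quality of 0.97–0.98); values stay in
  [0, 2] by construction.
* The exposure is the weighted score plus the BMI term plus a normal
  residual whose variance is calibrated so the score explains exactly the
  target \(R^2\); the manifest's betas are scaled so the theoretical score
  SD reproduces the published year-scaling constants. An unreachable
  target (confounder variance exceeding the residual budget) is a
  calibration error, not a silent renormalisation.
* Disease follows a logistic model with the stated log-OR per year of
  exposure (per year of the menopause-minus-menarche window when both
  trait instrument sets are present), the BMI effect, and per-allele direct
  effects for a configurable pleiotropic SNP subset. Cases and controls are
  sampled retrospectively to *exact* counts by oversampling a population
  (~2.4× the larger arm at ~50% prevalence) and sampling without
  replacement within outcome classes — valid because logistic odds ratios
  are invariant to outcome-dependent sampling.
* Principal components are standard normals uncorrelated with genotype
  (population structure itself is out of scope; PCs are consumed only as
  adjustment covariates), and self-reported exposure ages are the true
  simulated exposures — reporting error, parity, breastfeeding and real
  covariate correlation structure are *not* emulated. Passing tests
  therefore demonstrate statistical correctness of the estimators under
  the assumed model, not robustness to those real-data features.
* Every stochastic operation takes an explicit seed, derives any internal
  streams from it, and restores the caller's RNG state; outputs are
  bit-reproducible.

Two-sample summary statistics take exposure betas/SEs from the manifest and
draw outcome betas around the ratio-implied values (causal effect ×
exposure beta, plus any direct effect) with SEs sized for a case-control
GWAS of the configured sample: \(se_Y = (2f(1-f)\,N\varphi(1-\varphi))^{-1/2}\).

## Numerical conventions and edge cases

* Pruning tie-break: lexicographically larger rsid dropped.
* HWE on hard calls (rounded dosages), controls only; monomorphic SNPs get
  HWE p = 1 and are caught by the MAF filter instead.
* Curation order: proxies first, then pruning (the narrative order of the
  source curation; the result is insensitive for disjoint flag sets, which
  the generator guarantees).
* Egger needs ≥3 SNPs and nonzero exposure-beta variance; the weighted
  median needs ≥2 SNPs and ≥100 bootstrap replicates (smaller bootstraps
  give unstable SEs and are refused).
* `meta_fixed` of \(k\) identical estimates has \(se/\sqrt{k}\); a single
  estimate is returned unchanged.
* Zero-variance scores, one-class outcomes, single-level strata and absent
  tumour sites raise explicit, classed errors.

## Problem sizes used in the test suite

The simulation oracles run at sizes chosen to give stable Monte-Carlo
verdicts while keeping the default suite quick: parameter-recovery and
coverage checks use 200 replicates of 2,000-case/2,000-control cohorts with
20 SNPs; Egger intercept calibration uses 500 replicate 50-SNP summary
tables; power simulation uses 2,000 replicates at the full 23,685-woman
size. The binding checks (coverage in 93–97%, type-I near 5%, power ≥80%)
were verified against these replicate counts' Monte-Carlo error before
being frozen.

## Known limitations

* No LD-aware estimation: correlated instruments are pruned, never
  modelled; the generator draws independent genotypes.
* No MR-PRESSO, mode-based, multivariable or random-effects variants; no
  over-dispersion scaling of IVW/Egger standard errors.
* The year-scaling constants are point values; uncertainty in the
  calibration regression is not propagated into the MR confidence
  intervals (matching standard practice).
* The case-only site test and stratified analyses assume the stratum and
  covariates are measured without error and missing completely at random
  within model (complete-case).
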