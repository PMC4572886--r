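---
title: "Methods: summary-statistic Mendelian randomization with mrivw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistic Mendelian randomization with mrivw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrivw)
```

## The estimation problem

Observational associations between a metabolic exposure (say, fasting
insulin) and a disease are vulnerable to confounding and reverse causation.
Mendelian randomization (MR) sidesteps both by using genetic variants as
instrumental variables: alleles are assigned at conception, independently of
the lifestyle and physiological confounders that distort observational
estimates. If a variant affects the disease only through the exposure, the
ratio of its disease effect to its exposure effect estimates the causal
effect of the exposure.

`mrivw` implements the two-sample summary-statistic form of this design.
The inputs are per-SNP regression summaries from two non-overlapping
samples: an exposure GWAS giving $(\hat\gamma_j, \sigma_{\gamma j})$, the
per-allele effect of SNP $j$ on the exposure, and a disease case-control
GWAS giving $(\hat\Gamma_j, \sigma_{\Gamma j})$, the per-allele log odds
ratio. No individual-level data are required for estimation.

## The estimator

Each SNP contributes a Wald ratio

$$\hat\beta_j = \frac{\hat\Gamma_j}{\hat\gamma_j}, \qquad
  \mathrm{se}(\hat\beta_j) = \frac{\sigma_{\Gamma j}}{|\hat\gamma_j|},$$

the standard error being the leading (first-order) delta-method term: the
uncertainty in $\hat\gamma_j$ is deliberately not propagated, which is the
classical fixed-effect convention for summary-data MR with strong
instruments. The combined inverse-variance weighted (IVW) estimate is the
precision-weighted mean

$$\hat\beta_{IVW} = \frac{\sum_j w_j \hat\beta_j}{\sum_j w_j}, \qquad
  w_j = \mathrm{se}(\hat\beta_j)^{-2}, \qquad
  \mathrm{se}(\hat\beta_{IVW}) = \Big(\sum_j w_j\Big)^{-1/2},$$

algebraically identical to the slope of a weighted regression of
$\hat\Gamma$ on $\hat\gamma$ through the origin with weights
$\sigma_{\Gamma j}^{-2}$ — an identity the test suite checks against an
independent `lm()` oracle to near machine precision. No heterogeneity
inflation (multiplicative or additive) is applied, and no Egger, median or
modal estimator is provided; the package targets the fixed-effect IVW
analysis and its sensitivity companions.

### Reporting scale

The combined $\hat\beta_{IVW}$ is in disease log-odds per native exposure
unit. Reports convert it to the odds ratio per standard deviation of the
genetically predicted exposure: $\mathrm{OR} = \exp(\hat\beta_{IVW} s)$
with 95% CI $\exp((\hat\beta_{IVW} \pm z_{0.975}\,\mathrm{se}) s)$, where
$s$ is the exposure SD in native units (an [`exposure_spec()`] field, e.g.
0.60 ln(pmol/L) for log fasting insulin or 4.81 kg/m² for BMI) and
$z_{0.975} = \Phi^{-1}(0.975) = 1.959964$ at full precision. For a binary
exposure such as type 2 diabetes the scale is fixed at $s = 1$: the OR is
per unit increase in genetically predicted log-odds of the exposure.
P-values are two-sided standard normal, unchanged by the scaling. Display
formatting (OR and CI to 2 decimals, p as bare decimals or
$m.m \times 10^{-k}$) is confined to `format_or()`/`format_pvalue()`; full
precision is retained everywhere else.

Published results reported only as OR (95% CI) can be ingested via
`se_from_ci()`, which inverts the normal-interval arithmetic. Because
printed values are rounded to two decimals, a round-trip through
`se_from_ci()` reproduces the printed row only up to one unit in the last
printed digit; the acceptance checks propagate that ±0.005 rounding
explicitly rather than pretending the inversion is exact.

## Harmonization and quality control

Instrument and outcome tables may label the same SNP with opposite allele
orientations. `harmonize()` joins the tables by rsID, negates the outcome
log-OR when the allele pair is exactly swapped, and drops incompatible
pairs. Palindromic SNPs (A/T, C/G) cannot be strand-resolved from labels:
the default `"trust"` policy matches them by label — appropriate for
curated instrument lists whose strands were resolved at publication — while
`"strict"` drops them. Records are finally oriented so the effect allele is
the exposure-increasing allele ($\hat\gamma_j \ge 0$); the IVW estimate is
invariant to this convention (a tested property), it exists purely so
scatter and leave-one-out displays read naturally. Instruments missing from
the outcome table are warned about and dropped — no LD-proxy lookup is
attempted, since that would require an external reference panel.

`qc_filter()` encodes the array-genotyping thresholds used for case-control
outcome data: call rate ≥ 0.95 with MAF ≥ 0.05, or call rate ≥ 0.99 with
MAF < 0.05; Hardy-Weinberg p strictly greater than $10^{-12}$ in cases and
$10^{-7}$ in controls; imputation $R^2 \ge 0.6$ for imputed variants.
Inclusive versus strict inequalities follow the stated rules exactly and
are pinned by an exhaustive boundary-grid test.

## Cross-cohort meta-analysis

When outcome associations come from several case-control cohorts (e.g. a UK
and an Australian study), `meta_outcome_tables()` pools them per SNP with a
fixed-effect inverse-variance meta-analysis *before* MR estimation — the
pooling applies to the association analyses, not to cohort-level MR
estimates. Cohort records are first re-aligned to a common allele
orientation; Cochran's Q is computed per SNP and attached for inspection
but never used to filter. SNPs present in a single cohort pass through
unchanged, with contributing cohorts recorded. Random-effects pooling is
out of scope.

## Sensitivity analyses

Three complementary checks probe the "no pleiotropy" assumption:

* **Bonferroni screen** (`screen_snps()`): each SNP's disease association
  is tested at $\alpha = 0.05/n$ (e.g. $0.05/49 \approx 1.0\times10^{-3}$
  for a 49-SNP instrument); the p-value uses the normal approximation on
  the GWAS log-OR scale and is invariant to allele orientation.
* **Exclusion reruns** (`rerun_excluding()`): the full pipeline is re-run
  without flagged (or a-priori named) variants, keeping baseline and rerun
  side by side; a causal interpretation is supported when exclusions leave
  the estimate essentially unchanged.
* **Leave-one-out** (`leave_one_out()`): $n$ re-estimates each omitting one
  SNP, plus a per-SNP $(\hat\gamma_j, \hat\Gamma_j)$ scatter export
  (`scatter_data()`). Plot rendering is deliberately left out of the
  package surface so no test depends on graphics.

A-priori exclusion lists are first-class config entries because instrument
curation routinely demands them — e.g. removing an adiposity locus whose
exposure effect is mediated by BMI from an insulin instrument set, or
removing a variant shared between two instrument sets from one of them for
a sensitivity run.

## Genetic-score confounder scans

`build_unweighted_score()` counts exposure-increasing alleles per
individual (orientation taken from the harmonized instrument table;
missing dosages error by default, with optional per-SNP mean imputation).
`scan_confounders()` regresses a panel of candidate confounders on the
score — linear for quantitative traits, logistic for binary — and flags
associations at a family-wise Bonferroni threshold. The shipped trait panel
follows the 11-trait epidemiological convention (age, age at menarche, age
at menopause, BMI, fasting glucose, fasting insulin, 30-minute insulin,
physical activity, energy intake, education, smoking), and the 55-test
family ($\alpha = 0.05/55 = 9.1\times10^{-4}$) corresponds to five
instrument scores scanned against these 11 traits. Regressions are
unadjusted: the score is the sole predictor.

## The synthetic-data generator

Because the real instrument weights and disease associations live in a
publication supplement rather than a public repository, every pipeline
stage is exercised against a simulator with known ground truth:

$$g_{ij} \sim \mathrm{Bin}(2, f_j), \quad
  X_i = \textstyle\sum_j \gamma_j g_{ij} + a U_i + \varepsilon_i, \quad
  \mathrm{logit}\,P(D_i{=}1) = b_0 + \beta X_i + d U_i +
  \textstyle\sum_j \rho_j g_{ij}$$

with $U, \varepsilon$ standard normal. $U$ confounds exposure and disease;
$\rho_j$ plant direct (pleiotropic) SNP effects. Genotypes are
Hardy-Weinberg and LD-free, mirroring instrument sets of independent loci.
The exposure GWAS and the case-control GWAS are drawn from separate RNG
streams, so the two samples' estimation errors are independent by
construction. Summary statistics are produced exactly as a GWAS would:
per-SNP marginal linear regression in the exposure cohort (closed form,
vectorised over SNPs, verified against `lm()`) and per-SNP logistic
regression of case status on dosage (`glm.fit`).

Default design, chosen once as a realistic insulin-trait scenario: 36 SNPs
with effect-allele frequencies uniform on (0.1, 0.4), jointly explaining
2% of exposure variance in equal shares (instrument sets for insulin traits
explain on the order of 1%; 2% keeps the mean per-SNP F-statistic near 28
at $n = 50{,}000$, a strong-instrument regime), exposure SD 0.60 in native
units, true causal effect $\beta = 0.85$ log-odds per exposure unit (per-SD
OR $e^{0.85 \times 0.60} \approx 1.67$), confounder loadings 0.3 on both
arms, baseline disease log-odds −2, and an outcome GWAS of 1,287 cases and
8,273 controls — the scale of the endometrial-cancer application this
package is modelled on. Case-control sampling draws population batches
until the quotas fill, erroring with advice if prevalence is too low.

What the simulator does *not* model — LD between instruments, population
stratification, genotyping error, imputation noise, winner's curse in
instrument selection — bounds what passing tests show: calibration results
transfer to real data only to the extent those features are absent or
handled upstream (e.g. stratification adjusted out of the supplied summary
statistics, as cohort GWAS pipelines do with principal components).

One numerical subtlety is intentional: with a binary outcome the per-SNP
marginal log-OR is slightly attenuated relative to $\beta\gamma_j$ by
logistic non-collapsibility (marginalising over the residual exposure and
confounder variance), of order 5% at the default design. This bias is small
against the sampling error at the study's scale, so 95% CI coverage stays
within Monte-Carlo bounds of nominal — the calibration study
(`mr_calibration_study()`) measures exactly this.

## Problem sizes and numerical choices

The Monte-Carlo calibration runs 500 replicates at the full study scale
(exposure GWAS $n = 50{,}000$; 1,287/8,273 case-control) for both the
effect and the null design — enough to bound coverage within ±2.5
percentage points of Monte-Carlo error while completing in minutes on one
CPU. Unit tests use scaled-down designs (thousands of individuals, ~6
SNPs) since they check identities and contracts, not calibration. All
intervals use $z_{0.975}$ at full floating-point precision; p-values come
from the standard normal, never from a t reference, matching the
large-sample GWAS setting. Degenerate inputs fail loudly: zero exposure
effects (undefined Wald ratio), empty estimator input, exclusions that
empty the instrument set, and single-class binary traits are all explicit
errors or warnings rather than silent NAs.

## Pipeline orchestration

`run_pipeline()` drives the whole analysis from a YAML/JSON config
(validated by `validate_config()`, which collects every error rather than
failing fast): read and validate tables → a-priori exclusions → cross-cohort
meta-analysis → harmonization → IVW per exposure → Bonferroni screen at
$0.05/n_{\mathrm{SNPs}}$ → flagged-SNP rerun with leave-one-out. Outputs
are a per-exposure main table (SD, $n$, OR per SD, CI, p), a
post-exclusion sensitivity table, the per-SNP screen block, scatter and
leave-one-out exports, and a JSON-lines manifest carrying a config hash
and package version for provenance. Report tables are deterministic given
config and inputs; the manifest alone carries a timestamp. The package is
a library first — the same operations are exported R functions — with a
thin command-line wrapper in `inst/scripts/mr-pipeline.R` for shell use.

## Known limitations

* First-order Wald-ratio weights understate uncertainty when instruments
  are weak; no weak-instrument correction is applied.
* Fixed-effect IVW assumes balanced (ideally absent) horizontal pleiotropy;
  the screen and leave-one-out diagnostics detect gross single-SNP
  violations, not directional pleiotropy spread across many SNPs.
* `se_from_ci()` inherits the display rounding of published tables.
* The simulator's logistic non-collapsibility means the estimand of the
  per-SNP log-OR regression is a few percent smaller than the
  conditional causal effect; at realistic precision this is immaterial,
  but it would surface in ultra-large simulated outcome samples.
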