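---
title: "Methods: Mendelian randomization with mrcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization with mrcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcohort)
```

## The problem

Observational associations between an exposure such as body mass index
(BMI) and social or socio-economic outcomes are vulnerable to confounding
(e.g. by parental circumstances) and reverse causation (outcomes feeding
back onto the exposure). Mendelian randomization (MR) addresses both by
using genetic variants as instrumental variables: alleles are randomly
assigned at conception, so a weighted genetic risk score (GRS) for the
exposure is, under the instrumental-variable assumptions, independent of
the confounders that distort the observational estimate.

`mrcohort` implements the full analysis stack around that idea —
score construction, one-sample MR for continuous and binary outcomes,
sex-difference testing, summary-statistic pleiotropy sensitivity
estimators, non-linear MR over exposure strata, and within-sibling
estimators — together with a synthetic cohort generator that encodes the
exact violations (confounding, pleiotropy, dynastic effects, assortative
mating, non-linearity) each estimator is supposed to detect or resist.
Every estimator is therefore testable by parameter recovery against known
ground truth.

## The genetic risk score

With per-allele weights $\beta_i$ and dosages $g_i \in [0,2]$,

$$\text{weighted score} = \sum_i \beta_i g_i, \qquad
  \text{rescaled score} = \text{weighted score} \times
  \frac{n_{\text{snps}}}{\sum_i \beta_i},$$

the rescaled form putting the score on the trait-raising allele-count
scale. All IV estimates are invariant to this linear rescaling (a test
asserts this). Dosage alignment flips `2 - dosage` when a stored panel
counts the opposite allele, and refuses strand-ambiguous (A/T, C/G)
flips. Missing dosages are a hard error by default; per-variant mean
imputation must be requested explicitly, because silent imputation
corrupts the score.

## One-sample estimators

* **Observational**: linear or logistic regression of outcome on exposure
  plus covariates.
* **2SLS** (continuous): the just-identified IV estimator with the score
  as the single instrument. Standard errors use residuals computed with
  the *observed* exposure (not the first-stage fit) and are
  heteroskedasticity-robust (HC1), or cluster-robust when requested.
* **Two-stage logistic** ("2SPS", binary): logistic regression of the
  outcome on the first-stage fitted exposure plus covariates, sandwich
  SEs. We use the plug-in form rather than a control-function variant
  because the plug-in is the construction the headline analyses describe;
  its conditional-estimand caveats are inherited knowingly.
* **Fisher z sex difference**:
  $z = (\beta_m - \beta_f)/\sqrt{SE_m^2 + SE_f^2}$, two-sided normal
  p-value; both estimates must be on the same scale.

The first stage uses the same covariate set as the second stage (age,
sex, and optionally centre and ancestry PCs) — the natural default when
the source analyses do not state otherwise; it is a function argument,
not a constant. A first-stage partial F below 10 raises a warning, never
an error: an analysis pipeline must be able to proceed with the
instrument it has, reporting the F alongside.

Confidence intervals are Wald 95% ($\beta \pm 1.96\,SE$) throughout, with
two-sided normal p-values, matching the arithmetic of conventionally
reported CIs. No multiple-testing adjustment is applied; rows carry raw
p-values.

## Two-sample sensitivity estimators

Per-variant effect pairs $(\hat\beta_{gx}, \hat\beta_{gy})$ — computed
in-sample by `variant_summary_stats()` (with the attendant sample-overlap
caveat) or supplied externally — feed the standard pleiotropy triad:

* **IVW**: weighted through-the-origin slope, weights $1/se_{gy}^2$;
  fixed-effect SE by default, multiplicative random effects behind a
  flag.
* **MR-Egger**: the same regression with a free intercept. The intercept
  estimates directional pleiotropy; the slope is the adjusted effect.
  SEs use the multiplicative overdispersion convention (residual sigma
  floored at 1) with $t_{m-2}$ p-values, the convention of the era's
  standard two-sample toolchain.
* **Weighted median**: interpolated weighted median of per-variant Wald
  ratios with delta-method weights; SE by parametric bootstrap (1000
  draws, fixed seed), consistent when at least half the weight is valid.

Harmonization orients every variant to its exposure-raising allele by
negating both betas when $\hat\beta_{gx} < 0$.

## Non-linear MR

Stratifying on the raw exposure would condition on a collider (the
exposure is downstream of the instrument), so strata are formed on the
*IV-free exposure*: residuals from regressing exposure on the score (plus
covariates). Deciles are the default granularity. Within stratum $k$ the
localized average causal effect (LACE) is

$$\hat\theta_k = \frac{\widehat{\text{score} \to \text{outcome}}_k}
                      {\widehat{\text{score} \to \text{exposure}}},$$

with the denominator taken from the full sample (assumed homogeneous;
per-stratum denominators available as a sensitivity flag) and a
delta-method SE that propagates denominator uncertainty. The
residual-based stratification is used deliberately rather than the
doubly-ranked method, which belongs to a later methodological generation
than the design being reimplemented.

The per-stratum slopes integrate into a continuous piecewise-linear
effect curve anchored at a reference exposure (default: the lowest
knot; shifting the reference translates the curve). Non-linearity is
tested two ways: `p_quadratic` from a fixed-effect meta-regression of
LACE on mean stratum exposure (a zero-slope test — a trend in local
slopes is exactly a quadratic component in the curve), and `p_cochran_q`
from the usual heterogeneity statistic against $\chi^2_{K-1}$. With
$k = 1$ the machinery collapses exactly (to 1e-8) to the linear 2SLS
estimate.

## Within-sibling estimators

Population-level MR can be confounded by *dynastic effects* (parental
genotype shaping the rearing environment) and *assortative mating*
(parental score correlation inducing gene–environment correlation).
Both act through family-constant quantities, so centring the exposure
(non-genetic analysis) or the score (MR) within sibships removes them.

The within estimators regress on the centred variable while including
the family mean as a covariate, rather than absorbing thousands of
family fixed effects; for balanced sibships the two are identical (a
test asserts equality for two-sib families), and the centred-plus-mean
form is far cheaper. Covariates such as age and sex enter uncentred —
they vary within family and are not the confounders being purged.
SEs are cluster-robust by family throughout. For two-sib families the
continuous sib-MR estimator coincides exactly with the sib-pair
difference IV estimator $\sum \Delta g \Delta y / \sum \Delta g \Delta x$
(asserted to 1e-8).

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. One
configuration object fixes the full data-generating process:

* **Variant panel**: `n_variants` (default 73) independent biallelic
  variants, effect-allele frequencies uniform on (0.05, 0.95), weights
  drawn half-normal *truncated below* (a GWAS-selected panel carries no
  near-zero effects — discovery significance bounds them away from zero)
  and rescaled analytically so the Hardy–Weinberg score variance
  $\sum_i 2 p_i (1 - p_i) \beta_i^2$ equals `target_r2` (default 0.017,
  the 1.7% of exposure variance the 73-variant BMI score explains).
* **Exposure**: centred score + `confounder_effect_on_exposure` × U +
  Gaussian noise, standardized to unit variance; natural units via
  mean 27.4 and SD 4.8 kg/m², the BMI distribution of the motivating
  cohort. U is a single standard-normal individual-level factor — the
  minimal structure producing observational-vs-MR discordance — with an
  optional family-shared variance fraction for shared-environment
  scenarios in sibships.
* **Outcomes**: two continuous (`tdi`, `income`, opposite signs) and two
  binary (`cohabit`, `degree`) columns share one linear predictor built
  from the causal shape (`linear`, `quadratic`, or `piecewise`,
  optionally per-sex), the confounder, and — for binary outcomes — a
  logit link with intercept `binary_baseline_logodds` (default 1.01,
  i.e. ~73% baseline prevalence, the cohabitation rate). One simulation
  thus serves both regression families.
* **Sibships**: two parents per family in HWE; assortative mating as a
  Gaussian-copula rank coupling of parental *scores* (not raw exposure —
  coupling scores directly induces the IV-violating G–E correlation) at
  the configured correlation, leaving marginals untouched; each sib
  draws one allele per parent per variant (so sib–sib dosage correlation
  is 0.5 under random mating); dynastic effects enter as
  `dynastic_effect` × standardized mid-parental score in every offspring
  outcome. Sibship size is a config knob (`sibs_per_family`, default 2)
  since no canonical distribution is available.

Default cohort sizes (10 000 unrelated individuals, 5 000 families) are
deliberately modest; validation scenarios override them explicitly
(50 000–100 000 unrelated, 10 000 two-sib families — the scale of the
motivating sibling sample of 19 475 families).

What the generator does *not* emulate: linkage disequilibrium,
X-chromosome dosages, genotyping error, population stratification,
selection/collider effects of cohort participation, and missing data
mechanisms. Passing recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to these further
features of real biobank data.

## Phenotype transformation

Continuous outcomes are inverse-normal transformed:
$\Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$ with average ranks for ties.
The Blom offset and average-rank tie policy are the standard
epidemiology defaults; the source description names only "the inverse
normal function", so the choice is recorded in every `TransformRecord`
(`tie_policy`) for auditability rather than asserted as authorial
intent. Transformation happens on the analysis sample after missing-data
exclusion, before covariate adjustment. SD-scale effects convert back to
natural units by multiplying by the outcome's natural SD (e.g.
`0.05 * 2.99 = 0.150` deprivation-index units), rounded to 3 decimals
for reporting.

## Orchestration

`analysis_plan()` + `run_plan()` fill an outcome × method × subgroup
grid deterministically, flagging (not crashing on) failed cells, logging
per-outcome missingness exclusions, and emitting one tidy CSV row per
estimate — the forest-plot-ready result currency. The package is driven
from R; the exported functions and this vignette are the interface, and
deterministic seeds in the config make reruns byte-identical.

## Numerical choices and degenerate inputs

* Ties in stratum assignment break by stable input order; stratum counts
  differ by at most 1.
* Covariates that are constant within an analysis subset (e.g. sex in a
  sex-stratified subgroup) are absorbed into the intercept and dropped
  instead of producing a rank-deficiency failure.
* `rescale_score` refuses $\sum\beta = 0$; `mr_ivw` needs ≥ 2 variants,
  `mr_egger` and the weighted median ≥ 3; zero-$\beta_{gx}$ variants are
  dropped from the weighted median with a warning.
* A weak LACE denominator ($|z| < 2$) warns rather than errors.
* Degenerate binary outcomes (single level) and perfect-separation
  non-convergence raise estimation-failure errors.

## Validation problem sizes

The test suite validates by parameter recovery at sizes chosen to make
Monte-Carlo error small relative to the tolerances: 2SLS recovery and CI
coverage over 200 replicates of n = 50 000; Egger/IVW over 500
summary-level replicates of 73 variants at discovery-GWAS precision;
U-shape sign recovery over 200 replicates of n = 30 000 and trend-test
calibration over 1000 replicates of n = 5 000; sibling MR over 200
replicates of 10 000 two-sib families; sex-difference calibration over
2000 null replicates. The acceptance script reruns the same scenarios
(some at reduced replicate counts, stated in its output `n` fields) from
a single command-line seed.

## Known limitations

* The two-stage logistic estimand is a conditional log-OR given the
  fitted-value construction; non-collapsibility means it is not exactly
  the marginal causal OR.
* In-sample summary statistics reuse the one-sample data, so the
  two-sample estimators inherit sample-overlap bias toward the
  observational estimate; they are sensitivity analyses here, not
  independent replications.
* Ordinal outcome models and multivariable MR are out of scope; binary
  and continuous families cover the headline analyses.
* The weighted median SE is a bootstrap and hence seed-dependent; the
  seed is part of the call signature for reproducibility.
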