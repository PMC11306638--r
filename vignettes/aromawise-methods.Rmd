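---
title: "Methods: matched gene-environment analysis of prenatal BPA and aromatase activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched gene-environment analysis of prenatal BPA and aromatase activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

aromawise implements a cohort analysis chain for a gene-environment
interaction hypothesis: that prenatal bisphenol A (BPA) exposure raises the
risk of autism-spectrum outcomes specifically in boys whose genetic
predisposition implies low activity of brain aromatase (CYP19A1). This
vignette explains each model in the chain, the assumptions it makes, the
tunable parameters and their defaults, what the synthetic-cohort generator
does and does not emulate, and the numerical choices a maintainer should
know about.

## Exposure model

Urinary BPA concentrations are diluted to varying degrees. `sg_correct()`
applies the Levine-Fahy specific-gravity correction
$c' = c\,(SG_{ref}-1)/(SG_{obs}-1)$ with the cohort median as reference
density. The correction formula itself is a package choice — standard
practice in urinary biomarker epidemiology — since several variants
circulate.

Because roughly half of the measures in the motivating setting fall below
the assay limit of detection (LOD), the primary exposure contrast is a
dichotomization at the empirical 75th percentile (`dichotomize_exposure()`,
type-7 quantile, strictly-greater cut). The cut is unaffected by how
censored values are coded, which is the point of dichotomizing. For
continuous log2 analyses, censored values are imputed at LOD/√2
(`impute_below_lod()`, overridable to leave values as reported).

One numerical fact worth knowing: imputing all censored values at a single
constant compresses the lower tail of log2 exposure, so a slope measured
against the *latent* exposure is rescaled (by a factor of about 1.3 under
the default scenario) when estimated against the imputed one. The generator
therefore stores its latent exposure in `bpa_true`; parameter-recovery
tests regress on that ground-truth column, while analysis paths on real
data use the reported values with the configured policy. A real analysis
can avoid the issue altogether by using the categorical contrast, which is
what the primary analyses here do.

Dose translation (`urinary_to_intake()`) assumes steady state: intake
(ng/kg/day) = concentration (µg/L) × urine output (L/day, default 1.6) ×
1000 / (fractional excretion, default 1 × bodyweight, default 80.1 kg).
Both the exact value and an integer-floored presentation value are
returned, because regulatory discussions quote whole ng/kg. Safety factors
(`apply_safety_factors()`) divide by the product of the supplied unitless
factors; an empty list is the identity.

## Genetic aromatase scores

The unweighted score counts five CYP19A1 genotypes associated with lower
estrogen levels; "three or more" classifies a child low-activity, which
empirically lands near the top quartile. The count is inclusive at the
boundary, and the weighted analogue keeps that convention: the
NES-weighted, reversed allele-count score classifies low when the score is
at or above the type-7 75th percentile of cohort scores. The comparison
uses a relative tolerance of 1e-8 so that rescaling all weights by a
positive constant (which the classification is invariant to, in exact
arithmetic) cannot flip boundary subjects through floating-point noise.

NES weights are runtime configuration: the published analysis drew them
from a tissue-expression database, and they are not redistributable
numbers. `weighted_score_definition()` without arguments installs a clearly
documented synthetic placeholder set used by the test-suite only.

## Matched design

`build_matched_sets()` implements iterative round-robin greedy matching: m
rounds (default m = 8); in each round the cases are permuted by a dedicated
seeded RNG stream, and each case claims its nearest not-yet-used control.
"Nearest" is lexicographic: absolute screen-date difference in days, ties
broken by absolute age difference in years, then by subject id for
determinism. The source procedure names date and age but no combined
metric; the lexicographic rule is this package's declared choice because it
is deterministic and auditable, not a claim about the original authors'
intent. Controls are never reused; exhausted supply leaves short sets with
a log entry. With a single case per stratum the greedy result provably
equals exhaustive nearest-k selection, which the test-suite checks against
a brute-force oracle.

## Conditional logistic regression

`clr_fit()` maximizes the exact conditional likelihood for one-case sets,
$\ell(\beta)=\sum_s [x_{case}'\beta - \log\sum_{j\in s} e^{x_j'\beta}]$,
by Newton-Raphson from $\beta = 0$ with step-halving on likelihood
decrease, a gradient-norm tolerance of 1e-8 and at most 50 iterations. The
likelihood is concave and the sets are small, so the Hessian (observed
information) is cheap and exact; standard errors come from its inverse.
Sets without within-set covariate variation contribute a constant and are
dropped and counted. Confidence intervals are Wald on the log-odds scale —
the convention of the matched analyses this mirrors — not profile
likelihood. Separation (the norm of $\beta$ drifting beyond 15 with a
still-nonvanishing gradient) is flagged and the estimates suppressed;
penalized repairs are out of scope by design.

For 1:1 binary-exposure designs the estimator collapses to the
discordant-pair ratio $n_{10}/n_{01}$, which the tests exploit as a closed
form; general fits are verified against brute-force grid maximization and
against an independent fitter.

`stratified_interaction_analysis()` runs the subgroup chain: dichotomize
exposure, classify aromatase activity, and fit one conditional model per
(sex × low/high) cell, matching within ancestry × urine-collection-time
strata. Cells with fewer than 3 exposed cases are skipped with a recorded
reason — sparse cells otherwise produce separation artefacts — mirroring
how such analyses suppress cells that cannot support a model.

## Risk metrics

Miettinen's case-based attributable fraction $p_c(OR-1)/OR$ suits a
matched case-control design with a rare outcome, where the OR approximates
the risk ratio; that approximation is an assumption of this estimator, not
a theorem. Its interval comes from a set-level (cluster) bootstrap —
resampling whole matched sets and refitting — which respects the matching;
2000 replicates by default. ROC analysis goes through pROC (Mann-Whitney
AUC with tie correction, DeLong interval). Likelihood ratios are returned
without continuity correction: a perfect-sensitivity screen has LR− exactly
0, and an infinite LR+ is returned with a flag rather than fudged.

## Methylation association and mediation

Window methylation is the arithmetic mean of member CpG beta values;
windows are defined extensionally by CpG ID lists (`methyl_window()`), so
annotation drift cannot silently change membership, with 1-based inclusive
coordinates carried for reporting. Effects are reported in percentage
points (100 × beta) per log2 µg/L — the reporting convention that keeps a
0.05-point effect from being misread as 5 points. The association model is
ordinary least squares with a t-based two-sided p and interval; robust
standard errors are not used because the reference analyses do not state
them.

Mediation uses the product-of-coefficients estimator: $a$ from
mediator ~ exposure + covariates, $b$ and the direct effect from
outcome ~ mediator + exposure + covariates, indirect $= ab$, with a
percentile bootstrap over subjects (default 1000 replicates) and
$p = 2\min(\text{tail fractions})$ floored at $2/B$. In this linear,
no-interaction setting total = direct + indirect is an exact OLS identity,
asserted to 1e-10 in the tests. Exposure enters mediation as the
categorical >4 µg/L contrast (`categorize_for_epigenetics()`, both the
">4 vs rest" and ">4 vs <1" variants), while window association uses
continuous log2 exposure — the two analyses' respective conventions.

A distributional caution documented by the test-suite: under the
single-path null ($a \neq 0$, $b = 0$) the bootstrap indirect-effect
p-values are approximately uniform (Kolmogorov distance ≈ 0.06 over 200
replicates), but under the complete null ($a = b = 0$) the
product-of-coefficients test is conservative (p-values pile up near 1).
This is the known behaviour of the estimator, not an implementation
artefact.

## Direction concordance

`opposite_direction_binomial()` is the exact one-sided tail
$P(X \ge k \mid n, 1/2)$: the alternative of interest is that two
perturbations oppose each other *more* often than coin-flipping, and for
9 opposed pathways of 11 the one-sided tail is 67/2048 ≈ 0.033 (a
two-sided doubling would give 0.065, inconsistent with how such results
are reported). `term_direction_fisher()` builds the 2×2 of term-match ×
direction for one condition and returns the exact two-sided hypergeometric
p. Both are verified against complete enumeration. How directions were
extracted from an upstream enrichment tool is out of scope; the module
consumes a prepared table.

## The synthetic cohort

`sim_scenario()` defaults encode the study conditions the chain assumes:

| parameter | default | rationale |
|---|---|---|
| n_subjects | 1074 | recruited-cohort scale |
| exposure | lognormal, meanlog = log 0.68, sdlog ≈ 1.727 | median 0.68 µg/L and 75th percentile 2.18 µg/L |
| lod | 0.57 µg/L | ≈46% of draws censored |
| frac_bpa_missing | 0.21 | 847 of 1074 with a measure |
| interaction_or / baseline_or | 3.5 / 1.0 | effect confined to the (male, low) stratum |
| male_or | 1.65 | with prop_male 0.52 and the interaction lift, gives a ≈2.1:1 male:female case ratio |
| outcome_prevalence | 0.04 | ≈43 cases per 1074 |
| asp_high_prev | 0.368 | ASP T-score above 50 |
| meth_slope_per_log2 | 0.05 pp | promoter window effect size |
| mediation a, b | 0.5, 0.4 | indirect effect 0.2 |
| mediation_noise_sd | 0.15 | sampling SD of the indirect estimate ≈ 0.012 at n = 1000, small against the truth |
| noise_sd_meth | 0.01 beta | array-scale per-CpG noise |

Genotypes are drawn independently under Hardy-Weinberg (per-locus risk
homozygote frequency 0.36, putting the "three or more" class at ≈25%); the
score treats loci additively, so linkage structure is irrelevant to its
arithmetic and is not simulated. Methylation noise lives on the beta scale,
clipped to [0, 1]. The binary outcome comes from a logistic model whose
intercept is calibrated numerically (by `uniroot` on the mean predicted
probability) so the marginal prevalence hits its target exactly in
expectation.

What the generator does **not** emulate: genome-wide methylation structure,
linkage disequilibrium, assay batch effects, covariate confounding between
exposure and outcome (exposure is assigned independently of everything but
the outcome model), or selection/attrition mechanisms beyond
missing-completely-at-random exposure and ASP values. Passing tests
therefore demonstrate that the estimators recover what the generator
injects under clean conditions — not that the pipeline is robust to
confounding or informative missingness in real data.

## Problem sizes and calibration checks

The test-suite sizes its simulations to be informative while staying
desk-runnable: interval-coverage checks use 200 cohorts of n = 2000;
methylation recovery uses 200 cohorts of n = 800; mediation recovery uses
one cohort of n = 1000 with 1000 bootstrap replicates. Within the
(male, low-aromatase) cell at n = 2000 the matched analysis has a median of
only ~9 informative sets, and there the Wald interval is discretely
conservative under the null (measured coverage ≈ 0.99); the full-sample
matched fit, with ~58 informative sets, is calibrated (coverage ≈ 0.93–0.95
across effect and null conditions). That small-cell conservatism is a
property of Wald intervals at these set counts, worth remembering when
reading subgroup intervals from real cohorts of this size.

## Known limitations

* One case per set is enforced structurally; K-case sets are out of scope
  because the design never produces them.
* No exact conditional inference or penalized (Firth-type) fits; separation
  is reported, not repaired.
* The PAF interval method is this package's declared choice (set-level
  percentile bootstrap); published intervals produced by other methods will
  not be numerically reproduced.
* Complete-case handling of missing covariates is the explicit,
  config-visible default (`complete_case`); no imputation machinery is
  provided.
* Window definitions and NES weights must be user-supplied for real
  analyses; the bundled versions are synthetic placeholders for testing.
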