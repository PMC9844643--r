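---
title: "Methods: joint metabolic and polygenic risk modelling of GI cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint metabolic and polygenic risk modelling of GI cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gimets` estimates how metabolic syndrome (MetS) and a composite
gastrointestinal polygenic risk score (GI-PRS) jointly shape the hazard of
incident GI cancer (esophageal, gastric, colorectal) in a prospective
cohort. This vignette is the package's account of its models, its
numerical conventions, and the design choices that were genuinely open.

## 1. The statistical model

The core is a Cox proportional-hazards model on follow-up time from
baseline,

$$\lambda_i(t) = \lambda_0(t)\,\exp\{\beta_M M_i + \boldsymbol\beta_Z' \mathbf{Z}_i\},$$

where the exposure $M_i$ is MetS status (or the component-count band, the
genetic risk category, the standardized score, or the 6-level joint
exposure) and $\mathbf{Z}_i$ is one of two adjustment sets: *model 1*
(age group, sex, qualification, Townsend deprivation index, family
history of cancer) and *model 2* (model 1 plus smoking, alcohol, physical
activity, fruit, vegetable, red/processed meat, regular
aspirin/ibuprofen). Models containing a genetic exposure additionally
adjust the top 10 genetic principal components. Estimation is delegated
to `survival::coxph` with the Efron ties approximation (the statistical
default; the choice is testable — without tied event times Efron and
Breslow must agree to 10 decimal places, and a brute-force
partial-likelihood grid oracle pins the coefficient on small data).
Hazard ratios are $e^{\hat\beta}$ with Wald 95% intervals
$e^{\hat\beta \pm 1.96\,\mathrm{SE}}$. Proportionality is checked by the
correlation of scaled Schoenfeld residuals with time (identity
transform).

MetS follows NCEP-ATP III: at least three of central obesity (waist
> 102 cm men / > 88 cm women), hypertension (SBP ≥ 130 or DBP ≥ 85 mmHg),
dyslipidemia (HDL < 1.03 / < 1.29 mmol/L), hypertriglyceridemia
(TG ≥ 1.7 mmol/L), hyperglycemia (HbA1c ≥ 42 mmol/mol, the standard
surrogate where fasting glucose is unavailable). Boundary conventions —
strict `>` for waist, `≥` elsewhere, `<` for HDL — and every cutoff are
configurable through `mets_criteria()`, because the defining study's
supplementary cutoff table is not always available to a reuser; the
defaults are the standard published values. Whether medication use
(antihypertensives, lipid- or glucose-lowering drugs) counts toward a
flag is likewise supported but **off** by default, since the primary
definition in the source analyses does not state it. `obesity_mode =
"bmi30"` swaps the waist criterion for BMI > 30 kg/m² (sensitivity
variant i); it provably changes only the obesity flag.

The GI-PRS is the incidence-rate-weighted sum of three site scores,
$\mathrm{GIPRS}_i = \sum_s w_s \sum_j d_{ij}\beta_j$. The
age-standardized incidence rates used as weights are population
statistics not printed in the defining study; the shipped defaults
(ESC 14, GC 11, CRC 70 per 100,000 person-years) are explicit stand-ins
on the right scale, and no test depends on their absolute values — only
on the weighting mechanics (doubling all weights must leave the
standardized score unchanged). The alternative `mean_standardized` mode
divides each site score by its cohort mean before weighting (sensitivity
variant v); it requires the risk-allele orientation (all effect sizes
positive after flipping, a per-variant constant shift) so that site means
are positive. Quintiles are computed on the post-eligibility analysis
cohort — the source is silent on the ordering of exclusions vs quantile
computation, and the analysis cohort is the population the categories
describe; values equal to a cut point go to the lower quintile.

## 2. Harmonization conventions

Summary statistics pass through an explicit status machine: every input
variant ends with exactly one terminal status (`pass`, `proxy:<id>`, or a
named failure), and the per-status counts must sum to the input count.
Decisions a reuser should know:

* Proxy search requires r² **strictly** greater than 0.8; equal-r² ties
  break by smallest genomic position (arbitrary but deterministic).
* Allele reconciliation allows an effect/other swap (effect size
  negated, `swapped` flagged) and a strand flip (both alleles
  complemented); palindromic variants (A/T, G/C) are dropped when the
  minor allele frequency is ≥ 0.45, where strand cannot be resolved.
* Frequency discordance beyond 0.10 against the reference fails the
  variant.
* Clumping is greedy lowest-p-first within each cancer site, removing
  variants at r² ≥ 0.2 to the current index; p ties break by position.
  Variant pairs absent from the LD table count as unlinked (r² = 0) with
  a warning; `strict = TRUE` errors instead. An empty LD table is read
  as "all unlinked" silently.
* Scores are expressed on the effect-allele scale of the harmonized
  record; a flipped variant contributes `(2 − d)·|β|`, which shifts all
  participants by the same constant and cannot change ranks, categories,
  or the standardized score.

## 3. The synthetic cohort generator

The generator exists so that every downstream stage is testable without
individual-level biobank data. Its defaults *are* the emulated study
conditions: 430,036 participants, median ~10.9-year administrative
follow-up, 13/3/90 risk variants for ESC/GC/CRC, ~25.6% MetS prevalence,
and a crude GI event fraction of ~1.28% split 782:516:4205 across sites.

**Metabolic components.** Five latent Gaussian traits share a single
factor (compound-symmetric latent correlation; the defining study reports
no joint distribution, so this is a stated assumption, not a source
value). We calibrated the two free quantities — the common latent
correlation and a common shift of the component thresholds around a
realistic prevalence pattern — by numerical integration so the emergent
cohort matches **two** published facts at once: the 25.58% MetS
prevalence and the ~15.6% share of person-time contributed by
participants with zero components. The result is ρ = 0.18 with component
prevalences (obesity 0.349, hypertension 0.571, low HDL 0.215, high TG
0.471, hyperglycemia 0.131). A single-target calibration at ρ = 0.3 (a
plausible alternative) reproduces the MetS prevalence but inflates the
zero-component group to ~21%, making the band-model reference group
unrealistically large; matching the component-count distribution was
judged the better emulation, and ρ is configurable.

**Measurements.** Continuous measurements are monotone back-transforms of
the latent traits anchored at the clinical cutoffs (e.g. waist =
sex-cutoff + 13.49·(Z − c); TG is log-linear to stay positive), so the
classifier reproduces the latent flags exactly and the marginal means/SDs
approximate the emulated cohort's descriptives. These marginals are
*not* realistic in fine structure (no digit preference, no device
rounding, symmetric tails), which is irrelevant to threshold-based
classification but means the generator should not be used to study
measurement error.

**Genotypes.** Dosages are Binomial(2, MAF) per variant — Hardy–Weinberg
by construction, LD-free, and independent of the metabolic traits, so
the score–MetS association is null by design and the adjusted logistic
odds ratio must cover 1 at the nominal rate.

**Outcomes.** Event times are exponential: hazard
$\lambda_0 \exp\{\sum_k \theta_k x_{ik}\}$ with administrative censoring
at `followup_years` (optionally an earlier second horizon for a random
subset, mimicking country-specific registry end dates). The constant
baseline is a deliberate simplification — Cox estimation is agnostic to
the baseline shape, and the exponential gives closed-form oracles (the
crude rate ratio equals the hazard ratio). The default planted effects
are the emulated study's fully adjusted estimates: the component-band
gradient (HR 1.12 for 1–2 components, 1.41 for ≥ 3, vs 0) and HR 1.35
per SD of GI-PRS. Under the calibrated band distribution the band
gradient *implies* a binary MetS-vs-non-MetS hazard ratio of
1.41 / [(P₀ + P₁₂·1.12)/(P₀+P₁₂)] ≈ 1.29 — reproducing the binary,
band, and trend rows of the emulated association table simultaneously,
which a single binary term cannot do. Covariates carry zero hazard by
default so the recovery targets stay interpretable; confounding and
interaction scenarios are opt-in (`planted_loghr` accepts any covariate
column and a `mets_x_gi_prs_z` product term). Event sites are assigned
independently of which site's score drove the composite — a composite-
level simplification; per-site analyses of synthetic data therefore show
equal attenuated site effects rather than site-specific architecture.

Because the generator is exactly multiplicative, the expected
(high genetic, MetS) joint-cell hazard ratio is the product
≈ 1.29 × 2.32 ≈ 2.9–3.0, slightly above the emulated study's observed
2.75 (whose own printed margins, 1.28 × 2.28 = 2.92, are also
sub-multiplicative). A generator that printed 2.75 exactly would need a
planted negative interaction the source explicitly found non-significant
(p = 0.32); we prefer the cleaner null-interaction model and note the
expected ~6% excess in the joint cell.

**Seeds.** One global seed expands into per-stage child seeds (panel,
genotypes, phenotypes, outcomes, missingness) via a fixed sampling rule,
so stages are independently reproducible and identical `(config, seed)`
give byte-identical cohorts.

**Missingness and eligibility.** Fields are blanked (continuous) or set
to a refusal token (categorical) independently at `missing_rate`
(default 2%); planted ineligibility flags follow the emulated exclusion
proportions (≈ 5.9% prevalent cancer with a retained C44 share, 5.7%
non-white, 2.6% missing genotypes, etc.). "Diagnosed within the first
year" is implemented as event time < 1 year. Imputation replaces missing
continuous values by sex-specific medians and maps refusals to an
explicit `"missing"` level; it is idempotent and retains the unimputed
table for the complete-case sensitivity variant.

## 4. Risk translation

The 5-year absolute risk is **crude cumulative incidence** — events
within 5 years over baseline stratum size, per mille — matching the
"percentage of incident cases" definition; a Kaplan–Meier mode is
offered because the phrase is ambiguous under censoring, but with
administrative censoring well beyond year 5 the two are practically
identical here. The absolute risk increase is the exact difference of
the two per-mille risks, and the number of MetS subjects per additional
case is `round(1000 / ARI)` computed from the *unrounded* ARI. (Applying
the reciprocal to printed rounded risks can differ in the last digit:
1000/1.49 = 671, while unrounded inputs can legitimately print 669 — a
known arithmetic trap this package sidesteps by never rounding
intermediates.) Bootstrap intervals are percentile-method over
participant resamples (B = 1000 by default; the method is the simplest
defensible choice where none is specified), seeded and reproducible, and
abort if the statistic fails on more than 1% of resamples.
Standardized event rates use direct standardization to the whole-cohort
age-group × sex person-time distribution (the standardization variables
are a package choice; they are configurable).

## 5. Verification strategy, problem sizes, and what tests do not show

The test suite (all sizes chosen as package defaults for a single CPU):

* **Exact arithmetic**: the published stratification-table differences
  (4.22 − 2.73 = 1.49‰; 6.88 − 4.13 = 2.75‰) and the number-needed 364
  from the intermediate stratum reproduce exactly.
* **Deterministic oracles**: a brute-force partial-likelihood grid on
  ≤ 8-subject data (tolerance 1e-4), Efron = Breslow without ties,
  invariance to time rescaling, greedy clumping vs an independent
  matrix implementation on ≤ 12-variant panels, allele/strand-flip
  invariances, unit site-means in mean-standardized mode (1e-12).
* **Parameter recovery**: five cohorts of 200,000 participants are
  simulated, analysed end-to-end, and pooled by inverse variance; each
  pooled hazard ratio (MetS, bands, per-SD, categories, joint cell) must
  land in the emulated study's printed interval for that estimate.
* **Calibration**: with all planted effects zero, 300 small replicates
  (n = 2,500, inflated baseline hazard 0.01/py so each carries ~270
  events) give 95% Wald coverage within ±3 points and
  Kolmogorov–Smirnov-uniform Schoenfeld and interaction p-values; the
  default generator hits 25.58% ± 0.5 points MetS prevalence at full
  cohort size, and the score–MetS odds-ratio interval covers 1 in ≥ 8 of
  10 seeds.

Passing these shows the *machinery* is correct under the generator's
assumptions. It does not show that real cohort data satisfy those
assumptions: real metabolic components are not a one-factor Gaussian
copula, real baseline hazards are age-shaped, real scores sit on LD
structure and population stratification, and real missingness is not
completely at random. The pipeline's surfaces accept real inputs
precisely so those assumptions can be dropped wholesale.

## 6. Known limitations

* No competing-risks decomposition (death censors), no time-varying
  covariates beyond the PH diagnostic, no frailty terms.
* LD r² is consumed, never estimated from a genotype reference panel.
* Relatedness is a binary "has relative" flag sufficient for the
  unrelated-subset sensitivity analysis, not a kinship network.
* The restricted cubic spline uses 4 knots at the 5th/35th/65th/95th
  percentiles (configurable); the source does not state its knot scheme.
* The interaction between genetic category and MetS is parameterized
  both as binary × 3-category (2 df, the default) and as binary ×
  continuous score (1 df); the source's exact parameterization is
  unstated, so neither is asserted as "the" published one.
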