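# gimets

Joint metabolic and polygenic risk modelling of gastrointestinal (GI)
cancer — esophageal (ICD-10 C15), gastric (C16), and colorectal (C18–C20)
cancers combined — in prospective cohorts.

## The problem

Metabolic syndrome (MetS) — having at least three of five components
(central obesity, hypertension, low HDL, high triglycerides,
hyperglycemia) under the NCEP-ATP III definition — and common germline
variation both predict incident GI cancer. `gimets` implements the full
analysis a biobank-scale study of their joint effect needs:

* **Composite GI polygenic risk score.** Site-specific scores
  `PRS_s = Σ_j d_ij β_j` (dosage × per-allele effect size) are built from
  GWAS summary statistics after harmonization against a reference panel
  (p < 5×10⁻⁸ and MAF ≥ 0.01 filters, proxy substitution at r² > 0.8,
  allele/strand reconciliation, palindromic exclusion at MAF ≥ 0.45,
  frequency-discordance > 0.10, greedy LD clumping at r² < 0.2), then
  combined as `GI-PRS = Σ_s w_s · PRS_s` with age-standardized incidence
  rates as weights, and banded into low / intermediate / high genetic risk
  (bottom quintile / quintiles 2–4 / top quintile).
* **MetS classification** with the HbA1c ≥ 42 mmol/mol surrogate for
  fasting glucose, an eligibility cascade, and sex-specific-median
  imputation with explicit "missing" categories.
* **Cox proportional-hazards inference** (`survival::coxph`, Efron ties):
  two covariate-adjustment sets, Schoenfeld diagnostics, trend and
  interaction tests, subgroup analyses, a logistic model of MetS on the
  score, and a restricted-cubic-spline dose–response.
* **Risk translation:** per (genetic category × MetS) stratum, the 5-year
  absolute risk `AR₅ = events ≤ 5y / n` (per mille), absolute risk
  increase `ARI = AR₅(MetS) − AR₅(no MetS)`, the number of MetS subjects
  per additional case `NN = round(1000 / ARI)`, and percentile bootstrap
  confidence intervals over participants.
* **A synthetic cohort generator** (latent-Gaussian copula for the
  metabolic components, Hardy–Weinberg genotypes, exponential
  proportional-hazards outcomes with planted effects) so that the whole
  pipeline is testable end-to-end without access to individual-level
  biobank data.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
have `tidy()` / `glance()` methods and `plot_*()` / `autoplot()` figures.

## Worked example

```r
library(gimets)

cfg    <- scenario_config(n_participants = 200000)  # UK-Biobank-like scenario
report <- run_full_analysis(cfg, seed = 42)

dplyr::filter(report$mets_models, model == "model2")
#>   model  term           estimate std.error    hr conf.low conf.high    p.value
#> 1 model2 mets_factoryes    0.218    0.0492  1.24     1.13      1.37 0.00000966

report$joint$cells
#>   joint_category           n cases person_years    hr conf.low conf.high
#> 1 low.no_mets          25592   190      278008.  1      NA         NA
#> 2 low.mets              8733    74       94797.  1.15    0.877      1.50
#> 3 intermediate.no_mets 77200   802      837602.  1.40    1.20       1.64
#> 4 intermediate.mets    25774   343      279274.  1.80    1.51       2.15
#> 5 high.no_mets         25721   414      278292.  2.18    1.84       2.59
#> 6 high.mets             8604   168       92938.  2.65    2.15       3.26
```

The first table is the fully adjusted (model 2) hazard ratio for MetS vs
no MetS: carrying the syndrome raises the GI cancer hazard by ~24% in
this simulated cohort (the generator plants a component-band gradient
implying ≈ 1.29). The second is the 6-level joint exposure: hazard ratios
against participants at low genetic risk without MetS; the high-genetic
plus MetS cell carries a ~2.7-fold hazard. `report$joint$table3`
translates these into 5-year absolute risks per mille, absolute risk
increases, and the number of MetS subjects per additional case;
`run_sensitivity_suite(report)` reruns the headline models under five
robustness variants (BMI-based obesity, 2-year landmark, complete cases,
unrelated subset, mean-standardized score).

Real data enter through the same surfaces: `read_gwas_sumstats()`,
`read_reference_panel()`, `read_ld_table()`, `harmonize_variants()`,
`read_dosage_csv()` / `read_dosage_vcf()`, and a phenotype table with the
documented columns.

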