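#' Scenario configuration for the synthetic cohort generator
#'
#' A `scenario_config` bundles every tunable of the synthetic cohort: its
#' size, the variant panel, the latent-Gaussian model for the five metabolic
#' syndrome components, the covariate marginals, the proportional-hazards
#' outcome model with planted effects, follow-up/censoring, and missingness.
#'
#' Defaults emulate a UK-Biobank-scale prospective cohort: 430,036
#' participants followed for a median of about 10.9 years, a metabolic
#' syndrome prevalence of about 25.6%, 13/3/90 risk variants for
#' esophageal/gastric/colorectal cancer, and roughly 1.28% of participants
#' experiencing an incident gastrointestinal cancer.
#'
#' The five metabolic components share a single latent factor (compound
#' symmetric latent correlation, default 0.18). Component thresholds are set
#' from `component_target_prevalence`; the defaults were calibrated once, by
#' numerical integration over the latent factor, so the emergent cohort
#' reproduces both a 25.58% MetS prevalence and a ~15.6% share of
#' participants with zero components.
#'
#' The default planted log hazard ratios encode the component-count gradient
#' (1–2 components: HR 1.12; 3 or more: HR 1.41, each vs zero components)
#' and a per-SD composite polygenic score effect of HR 1.35. Under the
#' default component distribution this implies a binary MetS-vs-no-MetS
#' hazard ratio of about 1.29. A single binary `mets` term may be planted
#' instead (`planted_loghr = list(mets = log(1.28), ...)`), as may any
#' covariate column name, and `mets_x_gi_prs_z` for a multiplicative-scale
#' interaction.
#'
#' @param n_participants Cohort size before eligibility filtering.
#' @param n_snps_per_site Named integer vector, variants per cancer site;
#'   names must be `ESC`, `GC`, `CRC`.
#' @param maf_range Length-2 numeric in (0, 0.5], range of simulated minor
#'   allele frequencies.
#' @param effect_size_range Length-2 positive numeric; per-allele log-scale
#'   effect-size magnitudes are drawn uniformly from this range with random
#'   sign.
#' @param decoy_fraction Fraction of additional variants, per site, planted
#'   with QC defects (palindromic near 0.5 frequency, or reference-discordant
#'   frequency) for exercising the harmonization filters. Default 0.
#' @param planted_loghr Named list of log hazard ratios entering the linear
#'   predictor of the outcome model. Recognised special terms:
#'   `mets_band_12`, `mets_band_3plus`, `mets`, `gi_prs_z`,
#'   `mets_x_gi_prs_z`; any other name must match a numeric or 0/1 column of
#'   the phenotype table.
#' @param component_latent_corr 5x5 latent correlation matrix for the
#'   metabolic components (unit diagonal, positive semi-definite), or a
#'   single scalar giving a compound-symmetric correlation.
#' @param component_target_prevalence Named numeric, marginal flag prevalence
#'   of each component (`central_obesity`, `hypertension`, `dyslipidemia`,
#'   `hypertriglyceridemia`, `hyperglycemia`), each in [0, 1).
#' @param followup_years Administrative censoring horizon in years.
#' @param second_censor Optional earlier administrative horizon applied to a
#'   random subset, mimicking country-specific registry end dates: a list
#'   `list(years =, fraction =)`. Default fraction 0 (single horizon).
#' @param baseline_hazard Baseline event rate (events per person-year) of the
#'   exponential outcome model.
#' @param site_mix Length-3 fractions summing to 1; probability that an event
#'   is assigned to ESC, GC, CRC respectively.
#' @param missing_rate Per-field missingness probability injected after
#'   outcome simulation (continuous fields blanked; categorical fields set to
#'   `"prefer not to answer"`).
#' @param eligibility_rates Named list of rates for the planted
#'   ineligibility flags (prevalent cancer, retained C44 skin cancer,
#'   all-components-missing, pregnancy, non-white ancestry, reported/genetic
#'   sex mismatch, missing genotypes, other cancer preceding GI cancer).
#' @param seed Default integer seed used by [simulate_cohort()] when none is
#'   given.
#'
#' @return An object of class `scenario_config` (a validated named list).
#' @seealso [simulate_cohort()], [make_variant_panel()]
#' @export
#' @examples
#' cfg <- scenario_config(n_participants = 5000)
#' cfg$n_snps_per_site
scenario_config <- function(n_participants = 430036,
                            n_snps_per_site = c(ESC = 13L, GC = 3L, CRC = 90L),
                            maf_range = c(0.05, 0.5),
                            effect_size_range = c(0.05, 0.3),
                            decoy_fraction = 0,
                            planted_loghr = list(mets_band_12 = log(1.12),
                                                 mets_band_3plus = log(1.41),
                                                 gi_prs_z = log(1.35)),
                            component_latent_corr = 0.18,
                            component_target_prevalence = c(
                              central_obesity = 0.349,
                              hypertension = 0.571,
                              dyslipidemia = 0.215,
                              hypertriglyceridemia = 0.471,
                              hyperglycemia = 0.131),
                            followup_years = 10.9,
                            second_censor = list(years = 6.9, fraction = 0),
                            baseline_hazard = 0.00096,
                            site_mix = c(ESC = 782, GC = 516, CRC = 4205) / 5503,
                            missing_rate = 0.02,
                            eligibility_rates = list(
                              prevalent_cancer = 0.0592,
                              prevalent_c44 = 0.02,
                              all_components_missing = 0.0013,
                              pregnant = 0.0003,
                              nonwhite = 0.057,
                              sex_mismatch = 0.0007,
                              genotype_missing = 0.026,
                              other_cancer_first = 0.0008,
                              has_relative = 0.30),
                            seed = 1L) {
  if (length(component_latent_corr) == 1L) {
    r <- component_latent_corr
    component_latent_corr <- matrix(r, 5, 5)
    diag(component_latent_corr) <- 1
  }
  cfg <- structure(list(
    n_participants = as.integer(n_participants),
    n_snps_per_site = n_snps_per_site,
    maf_range = maf_range,
    effect_size_range = effect_size_range,
    decoy_fraction = decoy_fraction,
    planted_loghr = planted_loghr,
    component_latent_corr = component_latent_corr,
    component_target_prevalence = component_target_prevalence,
    followup_years = followup_years,
    second_censor = second_censor,
    baseline_hazard = baseline_hazard,
    site_mix = site_mix,
    missing_rate = missing_rate,
    eligibility_rates = eligibility_rates,
    seed = as.integer(seed)
  ), class = "scenario_config")
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (is.na(cfg$n_participants) || cfg$n_participants < 1L)
    abort("`n_participants` must be a positive integer.")
  sites <- c("ESC", "GC", "CRC")
  if (!identical(sort(names(cfg$n_snps_per_site)), sort(sites)))
    abort("`n_snps_per_site` must be named ESC, GC, CRC.")
  if (any(cfg$n_snps_per_site < 0))
    abort("`n_snps_per_site` must be non-negative.")
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || diff(cfg$maf_range) < 0)
    abort("`maf_range` must be increasing within (0, 0.5].")
  R <- cfg$component_latent_corr
  if (!is.matrix(R) || any(dim(R) != 5L))
    abort("`component_latent_corr` must be a 5x5 matrix.")
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8))
    abort("`component_latent_corr` must be symmetric with unit diagonal.")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    abort("`component_latent_corr` is not positive semi-definite.")
  pv <- cfg$component_target_prevalence
  need <- c("central_obesity", "hypertension", "dyslipidemia",
            "hypertriglyceridemia", "hyperglycemia")
  if (!all(need %in% names(pv)))
    abort(paste0("`component_target_prevalence` must name: ",
                 paste(need, collapse = ", ")))
  if (any(pv < 0 | pv >= 1))
    abort("component target prevalences must lie in [0, 1).")
  if (abs(sum(cfg$site_mix) - 1) > 1e-6 || any(cfg$site_mix < 0))
    abort("`site_mix` must be non-negative fractions summing to 1.")
  if (cfg$baseline_hazard <= 0) abort("`baseline_hazard` must be > 0.")
  if (cfg$followup_years < 0) abort("`followup_years` must be >= 0.")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    abort("`missing_rate` must lie in [0, 1).")
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  participants:", x$n_participants, "\n")
  cat("  variants/site:", paste(names(x$n_snps_per_site),
                                x$n_snps_per_site, sep = "=", collapse = " "), "\n")
  cat("  planted log-HRs:",
      paste(names(x$planted_loghr),
            sprintf("%.4f", unlist(x$planted_loghr)), sep = "=", collapse = " "), "\n")
  cat("  follow-up:", x$followup_years, "y; baseline hazard:",
      x$baseline_hazard, "/py\n")
  invisible(x)
}

# Deterministic per-stage child seeds from one global seed, so each
# generation stage is independently reproducible.
derive_stage_seeds <- function(seed) {
  stages <- c("panel", "genotypes", "phenotypes", "outcomes", "missingness",
              "extra")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  setNames(sample.int(2147483646L, length(stages)), stages)
}

#' Read / write a scenario configuration as YAML
#'
#' Every field of [scenario_config()] is a key; absent keys take the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return `scenario_from_yaml()` returns a `scenario_config`;
#'   `scenario_to_yaml()` writes and returns `path` invisibly.
#' @export
scenario_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    abort(paste0("Unknown scenario config key(s): ", paste(bad, collapse = ", ")))
  if (!is.null(raw$n_snps_per_site)) raw$n_snps_per_site <- unlist(raw$n_snps_per_site)
  if (!is.null(raw$component_target_prevalence))
    raw$component_target_prevalence <- unlist(raw$component_target_prevalence)
  if (!is.null(raw$site_mix)) raw$site_mix <- unlist(raw$site_mix)
  if (!is.null(raw$component_latent_corr) && is.list(raw$component_latent_corr))
    raw$component_latent_corr <- do.call(rbind, raw$component_latent_corr)
  do.call(scenario_config, raw)
}

#' @rdname scenario_from_yaml
#' @param cfg A `scenario_config`.
#' @export
scenario_to_yaml <- function(cfg, path) {
  x <- unclass(cfg)
  x$component_latent_corr <- apply(x$component_latent_corr, 1, as.numeric,
                                   simplify = FALSE)
  for (f in c("n_snps_per_site", "component_target_prevalence", "site_mix"))
    x[[f]] <- as.list(x[[f]])
  yaml::write_yaml(x, path)
  invisible(path)
}
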