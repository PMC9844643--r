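#' Generate a synthetic risk-variant panel
#'
#' Creates a panel of independent risk variants for the three
#' gastrointestinal cancer sites (esophageal, gastric, colorectal), with
#' per-allele effect sizes, genome-wide-significant p-values, and allele
#' frequencies. No variant is shared between sites. Optionally a fraction of
#' decoy variants with planted QC defects (palindromic alleles near 0.5
#' frequency, or reference-discordant frequency) is appended per site to
#' exercise the harmonization filters.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; defaults to the panel-stage child seed derived
#'   from `config$seed`.
#' @return A tibble of class `variant_panel` with columns `variant_id`,
#'   `chr`, `pos`, `effect_allele`, `other_allele`, `beta`, `p`, `maf_gwas`,
#'   `maf_ref`, `site`, `decoy`, `qc_status`.
#' @export
#' @examples
#' panel <- make_variant_panel(scenario_config(n_participants = 100))
#' table(panel$site)
make_variant_panel <- function(config,
                               seed = derive_stage_seeds(config$seed)[["panel"]]) {
  validate_scenario_config(config)
  counts <- config$n_snps_per_site[c("ESC", "GC", "CRC")]
  if (sum(counts) == 0L)
    abort("Variant panel would be empty: all `n_snps_per_site` are zero.")
  set.seed(seed)
  allele_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  one_site <- function(site, n) {
    if (n == 0L) return(NULL)
    pr <- allele_pairs[sample.int(length(allele_pairs), n, replace = TRUE)]
    tibble(
      variant_id = sprintf("rs%s%04d", site, seq_len(n)),
      chr = as.character(sample.int(22L, n, replace = TRUE)),
      pos = sample.int(2.4e8, n),
      effect_allele = vapply(pr, `[`, "", 1L),
      other_allele = vapply(pr, `[`, "", 2L),
      beta = sample(c(-1, 1), n, replace = TRUE) *
        runif(n, config$effect_size_range[1], config$effect_size_range[2]),
      p = 10^runif(n, -30, log10(5e-8)),
      maf_gwas = runif(n, config$maf_range[1], config$maf_range[2]),
      site = site
    )
  }
  panel <- bind_rows(
    one_site("ESC", counts[["ESC"]]),
    one_site("GC", counts[["GC"]]),
    one_site("CRC", counts[["CRC"]])
  )
  # reference frequencies concordant within the QC tolerance
  panel$maf_ref <- pmin(pmax(panel$maf_gwas +
                               runif(nrow(panel), -0.02, 0.02), 0.01), 0.5)
  panel$decoy <- FALSE
  if (config$decoy_fraction > 0) {
    nd <- counts
    nd[] <- pmax(1L, round(counts * config$decoy_fraction))
    decoys <- bind_rows(
      one_site("ESC", nd[["ESC"]]), one_site("GC", nd[["GC"]]),
      one_site("CRC", nd[["CRC"]])
    )
    decoys$variant_id <- paste0(decoys$variant_id, "d")
    decoys$maf_ref <- decoys$maf_gwas
    half <- seq_len(nrow(decoys)) %% 2 == 0
    # palindromic, strand-ambiguous near 0.5
    decoys$effect_allele[half] <- "A"
    decoys$other_allele[half] <- "T"
    decoys$maf_gwas[half] <- runif(sum(half), 0.45, 0.5)
    decoys$maf_ref[half] <- decoys$maf_gwas[half]
    # frequency-discordant with the reference (shift away from the bounds)
    decoys$maf_ref[!half] <- ifelse(decoys$maf_gwas[!half] > 0.35,
                                    decoys$maf_gwas[!half] - 0.15,
                                    decoys$maf_gwas[!half] + 0.15)
    decoys$decoy <- TRUE
    panel <- bind_rows(panel, decoys)
  }
  panel$qc_status <- "pass"
  class(panel) <- c("variant_panel", class(tibble()))
  panel
}

#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each variant's dosages are drawn independently as Binomial(2, MAF), so
#' observed allele frequencies converge to the panel frequencies and
#' genotype counts satisfy Hardy-Weinberg proportions.
#'
#' @param panel A `variant_panel` (see [make_variant_panel()]).
#' @param n Number of participants (>= 1).
#' @param seed Integer seed.
#' @return An integer matrix (participants x variants) with values 0/1/2,
#'   `dimnames = list(participant_id, variant_id)`.
#' @export
simulate_genotypes <- function(panel, n, seed) {
  if (n < 1) abort("`n` must be at least 1.")
  set.seed(seed)
  G <- vapply(panel$maf_gwas,
              function(f) rbinom(n, 2L, f),
              integer(n))
  if (n == 1L) G <- matrix(G, nrow = 1L)
  dimnames(G) <- list(sprintf("p%07d", seq_len(n)), panel$variant_id)
  G
}

# internal: draw from N(0, R) via eigen square root (R may be semi-definite)
rmvn_corr <- function(n, R, what = "component_latent_corr") {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    abort(paste0("Correlation matrix `", what, "` is not positive semi-definite."))
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R))
  matrix(rnorm(n * nrow(R)), n) %*% t(A)
}

#' Simulate metabolic phenotypes, covariates, and eligibility flags
#'
#' Five latent Gaussian traits with the configured correlation matrix are
#' thresholded so that each component's flag prevalence matches its target;
#' continuous measurements (waist, blood pressure, triglycerides, HDL,
#' HbA1c) are back-transformed monotone functions of the latent traits,
#' anchored so the NCEP-ATP III classifier of [flag_components()] crosses
#' its clinical cutoff exactly where the latent trait crosses its threshold.
#' Covariates and planted ineligibility flags are drawn from fixed
#' marginals. Genotypes are simulated elsewhere and are independent of the
#' metabolic traits by construction.
#'
#' @inheritParams make_variant_panel
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return A tibble with one row per participant (no outcome columns).
#' @export
simulate_metabolic_phenotypes <- function(config, n = config$n_participants,
                                          seed = derive_stage_seeds(config$seed)[["phenotypes"]]) {
  validate_scenario_config(config)
  set.seed(seed)
  prev <- config$component_target_prevalence[
    c("central_obesity", "hypertension", "dyslipidemia",
      "hypertriglyceridemia", "hyperglycemia")]
  cc <- qnorm(1 - prev)  # latent thresholds
  Z <- rmvn_corr(n, config$component_latent_corr)

  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.536, 0.464))
  waist_cut <- ifelse(sex == "male", 102, 88)
  hdl_cut <- ifelse(sex == "male", 1.03, 1.29)

  out <- tibble(
    id = sprintf("p%07d", seq_len(n)),
    sex = sex,
    waist = pmax(waist_cut + 13.49 * (Z[, 1] - cc[1]), 55),
    bmi = pmax(30 + 4.7 * (Z[, 1] - cc[1]) + rnorm(n, 0, 1.5), 15),
    sbp = pmax(130 + 18.07 * (Z[, 2] - cc[2]), 80),
    dbp = pmax(85 + 9.84 * (Z[, 2] - cc[2]), 45),
    hdl = pmax(hdl_cut - 0.36 * (Z[, 3] - cc[3]), 0.3),
    tg = 1.7 * exp(0.55 * (Z[, 4] - cc[4])),
    hba1c = pmax(42 + 6.35 * (Z[, 5] - cc[5]), 18),
    age_group = sample(c("40-49", "50-59", "60-69"), n, TRUE, c(0.26, 0.40, 0.34)),
    qualification = sample(c("degree", "other", "none"), n, TRUE, c(0.33, 0.47, 0.20)),
    townsend = rnorm(n, -1, 3),
    family_history = sample(c("no", "yes"), n, TRUE, c(0.68, 0.32)),
    smoking = sample(c("never", "former", "current"), n, TRUE, c(0.55, 0.35, 0.10)),
    alcohol = sample(c("never", "moderate", "frequent"), n, TRUE, c(0.08, 0.52, 0.40)),
    physical_activity = sample(c("low", "moderate", "high"), n, TRUE, c(0.20, 0.45, 0.35)),
    fruit = sample(c("low", "medium", "high"), n, TRUE, c(0.30, 0.40, 0.30)),
    vegetable = sample(c("low", "medium", "high"), n, TRUE, c(0.25, 0.45, 0.30)),
    red_processed_meat = sample(c("low", "medium", "high"), n, TRUE, c(0.30, 0.45, 0.25)),
    aspirin_ibuprofen = sample(c("no", "yes"), n, TRUE, c(0.73, 0.27))
  )
  pcs <- matrix(rnorm(n * 10L), n, dimnames = list(NULL, paste0("pc", 1:10)))
  out <- bind_cols(out, as_tibble(pcs))

  er <- config$eligibility_rates
  code_probs <- c(1 - er$prevalent_cancer - er$prevalent_c44,
                  er$prevalent_cancer, er$prevalent_c44)
  out$prevalent_cancer_code <- sample(c(NA, "C50", "C44"), n, TRUE, code_probs)
  out$pregnant <- out$sex == "female" & runif(n) < er$pregnant / 0.536
  out$ancestry <- sample(c("white", "other"), n, TRUE,
                         c(1 - er$nonwhite, er$nonwhite))
  out$sex_mismatch <- runif(n) < er$sex_mismatch
  out$genotype_available <- runif(n) >= er$genotype_missing
  out$other_cancer_first <- runif(n) < er$other_cancer_first
  out$has_relative <- runif(n) < er$has_relative

  all_miss <- runif(n) < er$all_components_missing
  metab <- c("waist", "sbp", "dbp", "tg", "hdl", "hba1c")
  out[all_miss, metab] <- NA_real_
  out
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with individual hazard
#' `baseline_hazard * exp(sum planted_loghr[term] * x_term)`, censored
#' administratively at `followup_years` (optionally at an earlier second
#' horizon for a random subset, mimicking country-specific registry end
#' dates). Events are assigned a cancer site by `site_mix`.
#'
#' @param records Phenotype tibble from [simulate_metabolic_phenotypes()].
#' @param gi_prs_z Numeric vector, one standardized composite polygenic
#'   score per record (used by the `gi_prs_z` planted term).
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return `records` with columns `time` (years), `event` (0/1), `site`
#'   (`NA`, `"ESC"`, `"GC"`, or `"CRC"`).
#' @export
simulate_outcomes <- function(records, gi_prs_z, config,
                              seed = derive_stage_seeds(config$seed)[["outcomes"]]) {
  n <- nrow(records)
  if (length(gi_prs_z) != n)
    abort("`gi_prs_z` must have one value per record.")
  set.seed(seed)
  lp <- rep(0, n)
  terms <- config$planted_loghr
  needs_bands <- any(c("mets", "mets_band_12", "mets_band_3plus",
                       "mets_x_gi_prs_z") %in% names(terms))
  if (needs_bands) {
    fl <- flag_components(records, mets_criteria(), allow_missing = TRUE)
    ncomp <- ifelse(is.na(fl$n_components), 0L, fl$n_components)
  }
  for (nm in names(terms)) {
    b <- terms[[nm]]
    x <- switch(nm,
      mets = as.numeric(ncomp >= 3L),
      mets_band_12 = as.numeric(ncomp >= 1L & ncomp <= 2L),
      mets_band_3plus = as.numeric(ncomp >= 3L),
      gi_prs_z = gi_prs_z,
      mets_x_gi_prs_z = as.numeric(ncomp >= 3L) * gi_prs_z,
      {
        if (!nm %in% names(records))
          abort(paste0("Planted term `", nm, "` matches no column."))
        v <- records[[nm]]
        if (is.character(v) || is.factor(v)) {
          v <- as.character(v)
          if (!all(v %in% c("no", "yes")))
            abort(paste0("Planted term `", nm, "` must be numeric or yes/no."))
          as.numeric(v == "yes")
        } else as.numeric(v)
      })
    lp <- lp + b * x
  }
  rate <- config$baseline_hazard * exp(lp)
  t_event <- rexp(n, rate)
  horizon <- rep(config$followup_years, n)
  sc <- config$second_censor
  if (!is.null(sc) && sc$fraction > 0)
    horizon[runif(n) < sc$fraction] <- sc$years
  event <- as.integer(t_event <= horizon)
  records$time <- pmin(t_event, horizon)
  records$event <- event
  records$site <- NA_character_
  ne <- sum(event)
  if (ne > 0)
    records$site[event == 1L] <- sample(c("ESC", "GC", "CRC"), ne, TRUE,
                                        config$site_mix)
  records
}

#' Blank fields at random to emulate survey and assay missingness
#'
#' Continuous metabolic fields are independently set to `NA` with
#' probability `config$missing_rate`; categorical covariates are set to the
#' token `"prefer not to answer"` with the same probability.
#'
#' @inheritParams simulate_outcomes
#' @return `records` with injected missingness.
#' @export
inject_missingness <- function(records, config,
                               seed = derive_stage_seeds(config$seed)[["missingness"]]) {
  rate <- config$missing_rate
  if (rate < 0 || rate >= 1) abort("`missing_rate` must lie in [0, 1).")
  if (rate == 0) return(records)
  set.seed(seed)
  n <- nrow(records)
  continuous <- intersect(c("waist", "sbp", "dbp", "tg", "hdl", "hba1c", "bmi"),
                          names(records))
  categorical <- intersect(c("qualification", "family_history", "smoking",
                             "alcohol", "physical_activity", "fruit",
                             "vegetable", "red_processed_meat",
                             "aspirin_ibuprofen"), names(records))
  for (f in continuous)
    records[[f]][runif(n) < rate] <- NA_real_
  for (f in categorical)
    records[[f]][runif(n) < rate] <- "prefer not to answer"
  records
}

#' Simulate a complete analysis-ready cohort
#'
#' Runs the full generation chain: variant panel, Hardy-Weinberg genotypes,
#' correlated metabolic phenotypes and covariates, composite polygenic score
#' (scored from the simulated dosages and the panel effect sizes, combined
#' with the default incidence weights), proportional-hazards outcomes with
#' the planted effects, and missingness injection. One global seed expands
#' into independent per-stage child seeds, so identical `(config, seed)`
#' yield byte-identical cohorts.
#'
#' @inheritParams make_variant_panel
#' @param seed Integer seed (defaults to `config$seed`).
#' @return An object of class `gi_cohort`: a list with elements
#'   `participants` (tibble incl. outcomes and a `gi_prs_z_true` column used
#'   by the outcome model), `genotypes` (dosage matrix), `panel`
#'   (variant tibble), `prs` (per-participant score tibble), `config`, and
#'   `seeds` (the per-stage child seeds).
#' @export
#' @examples
#' coh <- simulate_cohort(scenario_config(n_participants = 500), seed = 7)
#' mean(coh$participants$event)
simulate_cohort <- function(config, seed = config$seed) {
  validate_scenario_config(config)
  seeds <- derive_stage_seeds(seed)
  panel <- make_variant_panel(config, seed = seeds[["panel"]])
  scoring <- panel[!panel$decoy, , drop = FALSE]
  G <- simulate_genotypes(panel, config$n_participants, seed = seeds[["genotypes"]])
  pheno <- simulate_metabolic_phenotypes(config, config$n_participants,
                                         seed = seeds[["phenotypes"]])
  sites <- split(scoring, scoring$site)
  site_scores <- tibble(id = pheno$id)
  for (s in c("ESC", "GC", "CRC"))
    site_scores[[s]] <- if (is.null(sites[[s]])) 0 else
      score_site_prs(G, sites[[s]], orient = "risk")
  prs <- combine_gi_prs(site_scores, incidence_weights())
  pheno$gi_prs_z_true <- prs$gi_prs_z
  pheno <- simulate_outcomes(pheno, prs$gi_prs_z, config,
                             seed = seeds[["outcomes"]])
  pheno <- inject_missingness(pheno, config, seed = seeds[["missingness"]])
  structure(list(participants = pheno, genotypes = G, panel = panel,
                 prs = prs, config = config, seeds = seeds),
            class = "gi_cohort")
}

#' @export
print.gi_cohort <- function(x, ...) {
  cat("<gi_cohort>", nrow(x$participants), "participants,",
      nrow(x$panel), "variants,", sum(x$participants$event), "events\n")
  invisible(x)
}
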