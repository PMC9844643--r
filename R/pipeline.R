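#' Run the full joint metabolic-genetic analysis
#'
#' Orchestrates the complete pipeline on a synthetic cohort (or a supplied
#' one): eligibility cascade, covariate imputation, NCEP-ATP III
#' classification, composite polygenic score with quintile categories
#' (recomputed on the post-eligibility analysis cohort), the adjusted Cox
#' models (metabolic syndrome binary and component-count bands with trend,
#' per-component mutually adjusted models, per-SD and categorical genetic
#' models, per-site outcomes), the 6-level joint-effect model with the
#' absolute-risk translation, subgroup analyses, the score-on-MetS
#' logistic model, the restricted-cubic-spline dose-response, the
#' Schoenfeld proportional-hazards diagnostics, and the multiplicative
#' interaction test.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param cohort Optional pre-built `gi_cohort` (skips simulation).
#' @param criteria A [mets_criteria()].
#' @param weights An [incidence_weights()].
#' @param bootstrap_B Bootstrap resamples for absolute-risk confidence
#'   intervals (0 skips).
#' @return A list of class `gi_report`; see Details for components.
#' @details Components: `manifest`, `eligibility_log`, `table1`,
#'   `mets_models`, `trend`, `component_models`, `prs_models`,
#'   `per_site`, `joint` (a `joint_effect`), `subgroups`, `logistic`,
#'   `rcs`, `ph`, `interaction`, and `analysis` (the analysis-ready
#'   tibble, retained for sensitivity reruns).
#' @export
run_full_analysis <- function(config = scenario_config(),
                              seed = config$seed,
                              cohort = NULL,
                              criteria = mets_criteria(),
                              weights = incidence_weights(),
                              bootstrap_B = 0L) {
  t0 <- Sys.time()
  if (is.null(cohort)) cohort <- simulate_cohort(config, seed)
  stage_log <- list()
  note_stage <- function(name, d)
    stage_log[[name]] <<- tibble(stage = name, rows = nrow(d),
                                 checksum = rlang::hash(d))

  eligible <- apply_eligibility(cohort$participants)
  el_log <- eligibility_log(eligible)
  note_stage("eligibility", eligible)

  imputed <- impute_covariates(eligible)
  analysis <- classify_cohort(imputed, criteria)
  note_stage("classification", analysis)

  # composite score recomputed on the analysis cohort
  prs <- cohort$prs[match(analysis$id, cohort$prs$id), ]
  scores <- combine_gi_prs(prs[, c("id", "ESC", "GC", "CRC")], weights)
  analysis$gi_prs <- scores$gi_prs
  analysis$gi_prs_z <- scores$gi_prs_z
  gc <- assign_genetic_category(analysis$gi_prs)
  analysis$quintile <- factor(gc$quintile)
  analysis$genetic_category <- gc$genetic_category
  note_stage("prs", analysis)

  table1 <- analysis |>
    mutate(case = ifelse(.data$event == 1L, "case", "noncase")) |>
    group_by(.data$case) |>
    summarise(n = n(),
              across(all_of(c("waist", "sbp", "dbp", "tg", "hdl", "hba1c")),
                     mean),
              mets_pct = 100 * mean(.data$mets),
              .groups = "drop")

  fit_m1 <- fit_cox(analysis, "mets_factor", "model1")
  fit_m2 <- fit_cox(analysis, "mets_factor", "model2")
  fit_band <- fit_cox(analysis, "mets_band", "model2")
  mets_models <- bind_rows(
    tidy(fit_m1) |> mutate(model = "model1", .before = 1),
    tidy(fit_m2) |> mutate(model = "model2", .before = 1),
    tidy(fit_band) |> mutate(model = "model2_bands", .before = 1)) |>
    filter(startsWith(.data$term, "mets"))
  trend <- trend_test(analysis, "mets_band", "model2")

  comp <- c("central_obesity", "hypertension", "dyslipidemia",
            "hypertriglyceridemia", "hyperglycemia")
  for (cmp in comp) analysis[[paste0(".", cmp)]] <- as.numeric(analysis[[cmp]])
  fit_comp <- fit_cox(analysis, paste0(".", comp), "model2")
  cont_map <- c(central_obesity = "waist", hypertension = "sbp",
                dyslipidemia = "hdl", hypertriglyceridemia = "tg",
                hyperglycemia = "hba1c")
  for (cmp in comp)
    analysis[[paste0(".c_", cmp)]] <- scale(analysis[[cont_map[[cmp]]]])[, 1]
  fit_comp_c <- fit_cox(analysis, paste0(".c_", comp), "model2")
  component_models <- bind_rows(
    tidy(fit_comp) |> mutate(mode = "dichotomous", .before = 1),
    tidy(fit_comp_c) |> mutate(mode = "continuous", .before = 1)) |>
    filter(grepl(paste(comp, collapse = "|"), .data$term))

  fit_sd <- fit_cox(analysis, "gi_prs_z", "model2", pcs = TRUE)
  fit_cat <- fit_cox(analysis, "genetic_category", "model2", pcs = TRUE)
  fit_quint <- fit_cox(analysis, "quintile", "model2", pcs = TRUE)
  prs_models <- bind_rows(
    tidy(fit_sd) |> mutate(model = "per_sd", .before = 1),
    tidy(fit_cat) |> mutate(model = "category", .before = 1),
    tidy(fit_quint) |> mutate(model = "quintile", .before = 1)) |>
    filter(grepl("gi_prs_z|genetic_category|quintile", .data$term))

  per_site <- purrr::map(c("ESC", "GC", "CRC"), function(s) {
    f <- tryCatch(fit_cox(analysis, "mets_factor", "model2", outcome = s),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    tidy(f) |> filter(.data$term == "mets_factoryes") |>
      mutate(outcome = s, .before = 1)
  }) |> list_rbind()

  joint <- joint_effect_table(analysis, bootstrap_B = bootstrap_B,
                              seed = seed)
  subgroups <- purrr::map(
    c("sex", "age_group", "smoking", "alcohol", "physical_activity"),
    function(sv) {
      sg <- subgroup_analysis(analysis, sv, exposure = "mets")
      sg$strata |> mutate(stratifier = sv,
                          p_heterogeneity = sg$p_heterogeneity, .before = 1)
    }) |> list_rbind()
  logistic <- logistic_prs_on_mets(analysis)
  rcs <- rcs_dose_response(analysis)
  ph <- schoenfeld_ph_test(fit_m2)
  inter <- interaction_test(analysis, "category")

  manifest <- list(seed = seed, config_hash = rlang::hash(unclass(config)),
                   package_version = as.character(utils::packageVersion("gimets")),
                   started = t0, finished = Sys.time(),
                   stages = list_rbind(stage_log))
  structure(list(manifest = manifest, eligibility_log = el_log,
                 table1 = table1, mets_models = mets_models, trend = trend,
                 component_models = component_models,
                 prs_models = prs_models, per_site = per_site,
                 joint = joint, subgroups = subgroups, logistic = logistic,
                 rcs = rcs, ph = ph, interaction = inter,
                 analysis = analysis, cohort_prs = cohort$prs,
                 config = config, criteria = criteria),
            class = "gi_report")
}

#' @export
print.gi_report <- function(x, ...) {
  cat("<gi_report> seed", x$manifest$seed, "|",
      nrow(x$analysis), "participants,", sum(x$analysis$event), "events\n")
  cat("MetS model 2 HR:\n")
  print(x$mets_models |> filter(.data$model == "model2"))
  cat("Joint-effect cells:\n")
  print(x$joint$cells)
  invisible(x)
}

# refit the headline MetS and per-SD models on a modified analysis table
refit_headline <- function(analysis, label) {
  f1 <- fit_cox(analysis, "mets_factor", "model2")
  t1 <- tidy(f1) |> filter(.data$term == "mets_factoryes")
  t2 <- tryCatch({
    f2 <- fit_cox(analysis, "gi_prs_z", "model2", pcs = TRUE)
    tidy(f2) |> filter(.data$term == "gi_prs_z")
  }, error = function(e) NULL)
  bind_rows(
    t1 |> mutate(variant = label, term = "mets", .before = 1),
    if (!is.null(t2)) t2 |> mutate(variant = label, term = "gi_prs_z",
                                   .before = 1))
}

#' Rerun the headline models under the five sensitivity variants
#'
#' Variants: (i) obesity defined by BMI > 30 instead of waist
#' circumference; (ii) excluding cases in the first two years of follow-up;
#' (iii) complete-case analysis without imputation; (iv) unrelated
#' participants only; (v) composite score rebuilt with each site score
#' mean-standardized to 1. Each reruns the fully adjusted MetS and per-SD
#' models and is reported side by side with the main analysis.
#'
#' @param report A `gi_report` from [run_full_analysis()].
#' @return Tibble: `variant`, `term`, hazard ratio and confidence interval
#'   per rerun model.
#' @export
run_sensitivity_suite <- function(report) {
  stopifnot(inherits(report, "gi_report"))
  analysis <- report$analysis
  out <- list(refit_headline(analysis, "main"))

  # (i) BMI-based obesity
  crit_bmi <- report$criteria
  crit_bmi$obesity_mode <- "bmi30"
  a1 <- classify_cohort(analysis, crit_bmi)
  out <- c(out, list(refit_headline(a1, "i_bmi30")))

  # (ii) censor cases within first 2 years
  a2 <- analysis |> filter(!(.data$event == 1L & .data$time <= 2))
  out <- c(out, list(refit_headline(a2, "ii_exclude_2y")))

  # (iii) unimputed complete cases
  raw <- attr(analysis, "unimputed")
  if (!is.null(raw)) {
    vars <- c("waist", "sbp", "dbp", "tg", "hdl", "hba1c",
              adjustment_covariates("model2"))
    tokens <- c("prefer not to answer", "do not know")
    ok <- complete.cases(raw[, intersect(vars, names(raw))]) &
      !purrr::reduce(purrr::map(intersect(vars, names(raw)),
                                function(v) as.character(raw[[v]]) %in% tokens),
                     `|`)
    a3 <- analysis[analysis$id %in% raw$id[ok], , drop = FALSE]
    raw3 <- raw[match(a3$id, raw$id), ]
    for (v in c("waist", "sbp", "dbp", "tg", "hdl", "hba1c"))
      a3[[v]] <- raw3[[v]]
    a3 <- classify_cohort(a3, report$criteria)
    out <- c(out, list(refit_headline(a3, "iii_unimputed")))
  }

  # (iv) unrelated participants
  if ("has_relative" %in% names(analysis)) {
    a4 <- analysis |> filter(!.data$has_relative)
    out <- c(out, list(refit_headline(a4, "iv_unrelated")))
  }

  # (v) mean-standardized composite
  prs <- report$cohort_prs[match(analysis$id, report$cohort_prs$id), ]
  sc <- combine_gi_prs(prs[, c("id", "ESC", "GC", "CRC")],
                       incidence_weights(mode = "mean_standardized"))
  a5 <- analysis
  a5$gi_prs <- sc$gi_prs
  a5$gi_prs_z <- sc$gi_prs_z
  gc <- assign_genetic_category(a5$gi_prs)
  a5$genetic_category <- gc$genetic_category
  out <- c(out, list(refit_headline(a5, "v_mean_standardized")))

  list_rbind(out)
}

#' Write a report bundle to CSV files
#'
#' Each tabular component of the report is written as
#' `<dir>/<component>.csv`; the eligibility log as tab-separated text; the
#' manifest as YAML.
#'
#' @param report A `gi_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("table1", "mets_models", "trend", "component_models",
            "prs_models", "per_site", "subgroups", "logistic",
            "interaction", "ph")
  for (nm in tabs)
    if (!is.null(report[[nm]]) && nrow(report[[nm]]))
      write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
  write.csv(report$joint$cells, file.path(dir, "joint_cells.csv"),
            row.names = FALSE)
  write.csv(report$joint$table3, file.path(dir, "risk_strata.csv"),
            row.names = FALSE)
  write.csv(report$rcs$curve, file.path(dir, "rcs_curve.csv"),
            row.names = FALSE)
  utils::write.table(report$eligibility_log,
                     file.path(dir, "eligibility_log.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  m <- report$manifest
  m$started <- format(m$started); m$finished <- format(m$finished)
  m$stages <- NULL
  yaml::write_yaml(m, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
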