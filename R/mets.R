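#' NCEP-ATP III metabolic syndrome criteria
#'
#' Cutoffs for the five metabolic syndrome components. Defaults are the
#' standard NCEP-ATP III values with glycated hemoglobin (HbA1c >= 42
#' mmol/mol, i.e. >= 6%) as the surrogate for fasting glucose. Boundary
#' conventions: strictly greater for waist circumference; greater-or-equal
#' for triglycerides, blood pressure, and HbA1c; strictly less for HDL.
#' Medication-based qualification (blood-pressure-, lipid-, or
#' glucose-lowering treatment counting toward the corresponding flag) is
#' supported but off by default. `obesity_mode = "bmi30"` replaces the
#' waist criterion with BMI > 30 kg/m^2 (sensitivity analysis).
#'
#' @param waist_cutoff_male,waist_cutoff_female Waist circumference cutoffs, cm.
#' @param tg_cutoff Triglycerides cutoff, mmol/L.
#' @param hdl_cutoff_male,hdl_cutoff_female HDL cholesterol cutoffs, mmol/L.
#' @param sbp_cutoff,dbp_cutoff Systolic/diastolic blood pressure cutoffs, mmHg.
#' @param hba1c_cutoff HbA1c cutoff, mmol/mol.
#' @param use_medication_flags If `TRUE`, `bp_medication`, `lipid_medication`
#'   and `glucose_medication` columns (when present) also qualify the
#'   corresponding flags.
#' @param obesity_mode `"waist"` (default) or `"bmi30"`.
#' @return An object of class `mets_criteria`.
#' @export
mets_criteria <- function(waist_cutoff_male = 102, waist_cutoff_female = 88,
                          tg_cutoff = 1.7,
                          hdl_cutoff_male = 1.03, hdl_cutoff_female = 1.29,
                          sbp_cutoff = 130, dbp_cutoff = 85,
                          hba1c_cutoff = 42,
                          use_medication_flags = FALSE,
                          obesity_mode = c("waist", "bmi30")) {
  obesity_mode <- match.arg(obesity_mode)
  cuts <- c(waist_cutoff_male, waist_cutoff_female, tg_cutoff,
            hdl_cutoff_male, hdl_cutoff_female, sbp_cutoff, dbp_cutoff,
            hba1c_cutoff)
  if (any(cuts <= 0)) abort("All criteria cutoffs must be strictly positive.")
  structure(list(waist_cutoff_male = waist_cutoff_male,
                 waist_cutoff_female = waist_cutoff_female,
                 tg_cutoff = tg_cutoff,
                 hdl_cutoff_male = hdl_cutoff_male,
                 hdl_cutoff_female = hdl_cutoff_female,
                 sbp_cutoff = sbp_cutoff, dbp_cutoff = dbp_cutoff,
                 hba1c_cutoff = hba1c_cutoff,
                 use_medication_flags = use_medication_flags,
                 obesity_mode = obesity_mode),
            class = "mets_criteria")
}

eligibility_filters <- list(
  prevalent_cancer = list(
    cols = "prevalent_cancer_code",
    keep = function(d) is.na(d$prevalent_cancer_code) |
      startsWith(d$prevalent_cancer_code, "C44")),
  all_components_missing = list(
    cols = c("waist", "sbp", "dbp", "tg", "hdl", "hba1c"),
    keep = function(d) !(is.na(d$waist) & is.na(d$sbp) & is.na(d$dbp) &
                           is.na(d$tg) & is.na(d$hdl) & is.na(d$hba1c))),
  pregnant = list(cols = "pregnant", keep = function(d) !d$pregnant),
  nonwhite = list(cols = "ancestry", keep = function(d) d$ancestry == "white"),
  sex_mismatch = list(cols = "sex_mismatch", keep = function(d) !d$sex_mismatch),
  genotype_unavailable = list(cols = "genotype_available",
                              keep = function(d) d$genotype_available),
  gi_event_first_year = list(
    cols = c("time", "event"),
    keep = function(d) !(d$event == 1L & d$time < 1)),
  other_cancer_first = list(cols = "other_cancer_first",
                            keep = function(d) !d$other_cancer_first)
)

#' Apply the eligibility cascade
#'
#' Removes, in order: prevalent cancer at baseline (except non-melanoma skin
#' cancer, ICD-10 C44); all five metabolic components missing; pregnant at
#' recruitment; non-white ancestry; genetic/reported sex mismatch; genotype
#' unavailable; gastrointestinal cancer diagnosed within the first year of
#' follow-up; and other cancer diagnosed before the gastrointestinal cancer.
#' The per-step removal counts depend on the filter order (each step counts
#' only participants surviving the previous steps); the total retained does
#' not.
#'
#' @param records Participant tibble carrying the flag columns listed above.
#' @return The filtered tibble, with the step-by-step log attached as
#'   attribute `"eligibility_log"` (also retrievable via
#'   [eligibility_log()]): a tibble with columns `filter`, `n_removed`,
#'   `n_remaining`.
#' @export
apply_eligibility <- function(records) {
  log <- tibble(filter = "input", n_removed = 0L, n_remaining = nrow(records))
  for (nm in names(eligibility_filters)) {
    f <- eligibility_filters[[nm]]
    missing_cols <- setdiff(f$cols, names(records))
    if (length(missing_cols))
      abort(paste0("Eligibility filter `", nm, "` needs missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
    keep <- f$keep(records)
    keep[is.na(keep)] <- TRUE
    log <- bind_rows(log, tibble(filter = nm, n_removed = sum(!keep),
                                 n_remaining = sum(keep)))
    records <- records[keep, , drop = FALSE]
  }
  attr(records, "eligibility_log") <- log
  records
}

#' @rdname apply_eligibility
#' @param x A tibble returned by `apply_eligibility()`.
#' @export
eligibility_log <- function(x) attr(x, "eligibility_log")

#' Impute missing covariates
#'
#' Continuous fields: missing values are replaced by the median among
#' non-missing participants of the same sex. Categorical fields: missing
#' values and refusal tokens (`"prefer not to answer"`, `"do not know"`)
#' are mapped to an explicit `"missing"` level. The unimputed table is
#' retained as attribute `"unimputed"` for sensitivity analysis with
#' complete cases only.
#'
#' @param records Participant tibble; `sex` must be non-missing.
#' @param continuous,categorical Column names to treat; defaults cover the
#'   cohort's metabolic measurements and questionnaire covariates (only
#'   columns actually present are used).
#' @return `records` with imputed values; idempotent.
#' @export
impute_covariates <- function(records,
                              continuous = c("waist", "sbp", "dbp", "tg",
                                             "hdl", "hba1c", "bmi", "townsend"),
                              categorical = c("qualification", "family_history",
                                              "smoking", "alcohol",
                                              "physical_activity", "fruit",
                                              "vegetable", "red_processed_meat",
                                              "aspirin_ibuprofen")) {
  if (anyNA(records$sex)) abort("`sex` must be non-missing for imputation.")
  unimputed <- attr(records, "unimputed") %||% records
  continuous <- intersect(continuous, names(records))
  categorical <- intersect(categorical, names(records))
  for (f in continuous) {
    miss <- is.na(records[[f]])
    if (!any(miss)) next
    med <- tapply(records[[f]], records$sex, median, na.rm = TRUE)
    if (anyNA(med))
      abort(paste0("Continuous field `", f,
                   "` is missing for every participant of one sex."))
    records[[f]][miss] <- med[records$sex[miss]]
  }
  tokens <- c("prefer not to answer", "do not know")
  for (f in categorical) {
    v <- as.character(records[[f]])
    v[is.na(v) | v %in% tokens] <- "missing"
    records[[f]] <- v
  }
  attr(records, "unimputed") <- unimputed
  records
}

#' Flag the five metabolic syndrome components
#'
#' Applies the NCEP-ATP III classifier: central obesity (waist > sex-specific
#' cutoff, or BMI > 30 in `bmi30` mode), hypertension (SBP or DBP at/above
#' cutoff), dyslipidemia (HDL below sex-specific cutoff),
#' hypertriglyceridemia (TG at/above cutoff), hyperglycemia (HbA1c at/above
#' cutoff). Metabolic syndrome is three or more flags.
#'
#' @param records Participant tibble with imputed (or complete) metabolic
#'   fields and `sex`.
#' @param criteria A [mets_criteria()].
#' @param allow_missing If `TRUE`, rows with missing measurements yield `NA`
#'   flags instead of an error (used internally by the generator before
#'   eligibility filtering).
#' @return `records` plus logical columns `central_obesity`, `hypertension`,
#'   `dyslipidemia`, `hypertriglyceridemia`, `hyperglycemia`, integer
#'   `n_components` (0-5), and logical `mets`.
#' @export
#' @examples
#' d <- tibble::tibble(sex = "male", waist = 95, sbp = 135, dbp = 80,
#'                     tg = 1.8, hdl = 0.9, hba1c = 40)
#' flag_components(d, mets_criteria())[, c("n_components", "mets")]
flag_components <- function(records, criteria = mets_criteria(),
                            allow_missing = FALSE) {
  need <- c("sex", "sbp", "dbp", "tg", "hdl", "hba1c",
            if (criteria$obesity_mode == "waist") "waist" else "bmi")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    abort(paste0("flag_components needs column(s): ",
                 paste(missing_cols, collapse = ", ")))
  meas <- c("waist", "sbp", "dbp", "tg", "hdl", "hba1c", "bmi")
  for (f in intersect(meas, names(records))) {
    bad <- !is.na(records[[f]]) & records[[f]] < 0
    if (any(bad))
      abort(paste0("Negative measurement in `", f, "`."))
  }
  if (!allow_missing && anyNA(records[need]))
    abort("Missing metabolic measurements; impute first or set `allow_missing = TRUE`.")
  male <- records$sex == "male"
  ob <- if (criteria$obesity_mode == "waist") {
    records$waist > ifelse(male, criteria$waist_cutoff_male,
                           criteria$waist_cutoff_female)
  } else records$bmi > 30
  htn <- records$sbp >= criteria$sbp_cutoff | records$dbp >= criteria$dbp_cutoff
  dys <- records$hdl < ifelse(male, criteria$hdl_cutoff_male,
                              criteria$hdl_cutoff_female)
  tgf <- records$tg >= criteria$tg_cutoff
  glu <- records$hba1c >= criteria$hba1c_cutoff
  if (criteria$use_medication_flags) {
    if ("bp_medication" %in% names(records))
      htn <- htn | records$bp_medication %in% c(TRUE, "yes")
    if ("lipid_medication" %in% names(records))
      dys <- dys | records$lipid_medication %in% c(TRUE, "yes")
    if ("glucose_medication" %in% names(records))
      glu <- glu | records$glucose_medication %in% c(TRUE, "yes")
  }
  records$central_obesity <- ob
  records$hypertension <- htn
  records$dyslipidemia <- dys
  records$hypertriglyceridemia <- tgf
  records$hyperglycemia <- glu
  records$n_components <- as.integer(ob) + as.integer(htn) + as.integer(dys) +
    as.integer(tgf) + as.integer(glu)
  records$mets <- records$n_components >= 3L
  records
}

#' Classify a cohort's metabolic syndrome status
#'
#' Adds the component flags of [flag_components()] plus the component-count
#' band used in the adjusted analyses (`"0"`, `"1-2"`, `">=3"`) and a
#' `mets_factor` with reference level `"no"`.
#'
#' @inheritParams flag_components
#' @return `records` with flags, `mets_band` (factor), and `mets_factor`.
#' @export
classify_cohort <- function(records, criteria = mets_criteria()) {
  records <- flag_components(records, criteria)
  records$mets_band <- factor(
    dplyr::case_when(records$n_components == 0L ~ "0",
                     records$n_components <= 2L ~ "1-2",
                     TRUE ~ ">=3"),
    levels = c("0", "1-2", ">=3"))
  records$mets_factor <- factor(ifelse(records$mets, "yes", "no"),
                                levels = c("no", "yes"))
  records
}
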