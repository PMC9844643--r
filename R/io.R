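#' Read and write variant scoring files
#'
#' Scoring files are tab-separated text with columns `variant_id`, `chr`,
#' `pos`, `effect_allele`, `other_allele`, `beta`, `p`, `maf`, `site`.
#'
#' @param variants Variant tibble.
#' @param path File path.
#' @return `read_scoring_file()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
write_scoring_file <- function(variants, path) {
  cols <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
            "beta", "p", "maf_gwas", "site")
  out <- variants[, intersect(cols, names(variants)), drop = FALSE]
  names(out)[names(out) == "maf_gwas"] <- "maf"
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scoring_file
#' @export
read_scoring_file <- function(path) {
  d <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                   colClasses = c(chr = "character")))
  if ("maf" %in% names(d)) names(d)[names(d) == "maf"] <- "maf_gwas"
  if (!"qc_status" %in% names(d)) d$qc_status <- "pass"
  d
}

#' Read GWAS summary statistics from delimited text
#'
#' Expects named columns including `variant_id`, `chr`, `pos`,
#' `effect_allele`, `other_allele`, `beta`, `p`, and an allele frequency
#' column (`maf`, `maf_gwas`, or `eaf`).
#'
#' @param path File path (tab-separated by default).
#' @param sep Field separator.
#' @return A variant tibble suitable for [harmonize_variants()].
#' @export
read_gwas_sumstats <- function(path, sep = "\t") {
  d <- as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                   colClasses = c(chr = "character")))
  for (alias in c("maf", "eaf"))
    if (alias %in% names(d) && !"maf_gwas" %in% names(d))
      names(d)[names(d) == alias] <- "maf_gwas"
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "p",
            "maf_gwas")
  miss <- setdiff(need, names(d))
  if (length(miss))
    abort(paste0("Summary statistics lack column(s): ",
                 paste(miss, collapse = ", ")))
  d$qc_status <- "pass"
  d
}

#' Read a reference panel table
#'
#' Tab-separated text with `variant_id`, `allele1`, `allele2`, `maf_ref`.
#'
#' @inheritParams read_gwas_sumstats
#' @return A tibble.
#' @export
read_reference_panel <- function(path, sep = "\t")
  as_tibble(utils::read.table(path, header = TRUE, sep = sep))

#' Read a pairwise LD table
#'
#' Tab-separated text with `id1`, `id2`, `r2`.
#'
#' @inheritParams read_gwas_sumstats
#' @return A tibble.
#' @export
read_ld_table <- function(path, sep = "\t")
  as_tibble(utils::read.table(path, header = TRUE, sep = sep))

#' Read and write participant dosage matrices as CSV
#'
#' Rows are participants (first column `id`), remaining columns one per
#' variant.
#'
#' @param dosages Numeric matrix with participant row names and variant
#'   column names.
#' @param path File path.
#' @return `read_dosage_csv()` returns a numeric matrix; the writer
#'   returns `path` invisibly.
#' @export
write_dosage_csv <- function(dosages, path) {
  d <- data.frame(id = rownames(dosages), dosages, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_csv
#' @export
read_dosage_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$id
  storage.mode(m) <- "numeric"
  m
}

#' Extract genotype dosages from a VCF
#'
#' Reads the GT field (or DS when present) of a VCF and returns an
#' effect-allele dosage matrix (participants x variants). Requires the
#' `vcfR` package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return Numeric matrix, participants in rows, variant ids in columns.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("Package `vcfR` is required to read VCF genotypes.")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  if ("DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  m <- t(ds)
  colnames(m) <- ids
  m
}

#' Export a simulated cohort as plain-text files
#'
#' Writes `<dir>/phenotypes.csv` (one row per participant: metabolic
#' measurements, covariates, eligibility flags, outcomes),
#' `<dir>/dosages.csv` (participant x variant dosage matrix), and
#' `<dir>/scoring.tsv` (the variant panel as a scoring file).
#'
#' @param cohort A `gi_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gi_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$participants, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  write_dosage_csv(cohort$genotypes, file.path(dir, "dosages.csv"))
  write_scoring_file(cohort$panel, file.path(dir, "scoring.tsv"))
  invisible(dir)
}
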