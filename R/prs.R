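#' Filter GWAS summary statistics on significance and frequency
#'
#' Keeps variants with `p < 5e-8` and minor allele frequency `>= 0.01`;
#' others are retained in the table with a failure status rather than
#' silently dropped (`fail:p_threshold`, `fail:maf`, or
#' `fail:missing_stats` when p or frequency is absent).
#'
#' @param variants Tibble with at least `variant_id`, `p`, `maf_gwas`.
#' @param p_threshold,maf_threshold Inclusion thresholds.
#' @return `variants` with an updated `qc_status` column.
#' @export
filter_summary_stats <- function(variants, p_threshold = 5e-8,
                                 maf_threshold = 0.01) {
  maf <- pmin(variants$maf_gwas, 1 - variants$maf_gwas)
  status <- dplyr::case_when(
    is.na(variants$p) | is.na(maf) ~ "fail:missing_stats",
    variants$p >= p_threshold ~ "fail:p_threshold",
    maf < maf_threshold ~ "fail:maf",
    TRUE ~ "pass")
  variants$qc_status <- status
  variants
}

# look up r2 between pairs in a (possibly one-directional) LD table
ld_lookup <- function(ld, a, b) {
  hit <- (ld$id1 == a & ld$id2 == b) | (ld$id1 == b & ld$id2 == a)
  if (any(hit)) max(ld$r2[hit]) else NA_real_
}

#' Substitute unavailable variants by their best LD proxy
#'
#' A variant present in the availability set is returned unchanged. An
#' absent variant is replaced by the available proxy with the largest
#' r-squared, provided r-squared is strictly greater than `r2_proxy`; ties
#' are broken by smallest genomic position. With no qualifying proxy the
#' status becomes `fail:no_proxy`.
#'
#' @param variants Variant tibble (rows with `qc_status != "pass"` are
#'   passed through untouched).
#' @param available Tibble of genotyped variants with columns `variant_id`
#'   and `pos` (position used only for tie-breaking).
#' @param ld Tibble with columns `id1`, `id2`, `r2`.
#' @param r2_proxy Strict lower bound for proxy eligibility (default 0.8).
#' @return `variants` with substitutions applied: a substituted row carries
#'   the proxy's id and position, the original effect size, and status
#'   `proxy:<original id>`.
#' @export
proxy_substitute <- function(variants, available, ld, r2_proxy = 0.8) {
  for (i in seq_len(nrow(variants))) {
    if (variants$qc_status[i] != "pass") next
    vid <- variants$variant_id[i]
    if (vid %in% available$variant_id) next
    cand <- available[available$variant_id != vid, , drop = FALSE]
    if (nrow(cand)) {
      cand$r2 <- vapply(cand$variant_id, function(p) ld_lookup(ld, vid, p), 0)
      cand <- cand[!is.na(cand$r2) & cand$r2 > r2_proxy, , drop = FALSE]
    }
    if (!nrow(cand)) {
      variants$qc_status[i] <- "fail:no_proxy"
      next
    }
    cand <- cand[order(-cand$r2, cand$pos), , drop = FALSE]
    variants$variant_id[i] <- cand$variant_id[1]
    if ("pos" %in% names(variants) && "pos" %in% names(cand))
      variants$pos[i] <- cand$pos[1]
    variants$qc_status[i] <- paste0("proxy:", vid)
  }
  variants
}

COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

is_palindromic <- function(a1, a2) {
  p <- paste0(a1, a2)
  p %in% c("AT", "TA", "GC", "CG")
}

#' Harmonize variants against a reference panel
#'
#' Per variant: fails with `fail:not_in_reference` when absent from the
#' reference; reconciles the allele pair with the reference allowing an
#' effect/other swap (effect size sign negated and the `swapped` flag set)
#' and a strand flip (both alleles complemented), else
#' `fail:allele_mismatch`; fails palindromic variants (A/T or G/C) with
#' minor allele frequency `>= 0.45` as `fail:palindromic`; fails variants
#' whose minor allele frequency differs from the reference by more than
#' 0.10 as `fail:maf_discordant`.
#'
#' @param variants Variant tibble (`pass`/`proxy:*` rows are checked).
#' @param reference Tibble with `variant_id`, `allele1`, `allele2`,
#'   `maf_ref`.
#' @param maf_diff_max Maximum tolerated frequency difference (default 0.10).
#' @param palindromic_maf Palindromic exclusion frequency bound (default 0.45).
#' @return `variants` with updated `qc_status`, harmonized alleles/effect
#'   sizes, and a logical `swapped` column.
#' @export
qc_against_reference <- function(variants, reference, maf_diff_max = 0.10,
                                 palindromic_maf = 0.45) {
  if (!"swapped" %in% names(variants)) variants$swapped <- FALSE
  live <- variants$qc_status == "pass" | startsWith(variants$qc_status, "proxy:")
  for (i in which(live)) {
    j <- match(variants$variant_id[i], reference$variant_id)
    if (is.na(j)) {
      variants$qc_status[i] <- "fail:not_in_reference"
      next
    }
    ea <- variants$effect_allele[i]; oa <- variants$other_allele[i]
    a1 <- reference$allele1[j]; a2 <- reference$allele2[j]
    pair_ok <- function(x, y) (x == a1 && y == a2)
    flip <- function(x) unname(COMPLEMENT[x])
    if (pair_ok(ea, oa)) {
      # aligned
    } else if (pair_ok(oa, ea)) {
      variants$effect_allele[i] <- oa; variants$other_allele[i] <- ea
      variants$beta[i] <- -variants$beta[i]
      variants$swapped[i] <- TRUE
    } else if (pair_ok(flip(ea), flip(oa))) {
      variants$effect_allele[i] <- flip(ea)
      variants$other_allele[i] <- flip(oa)
    } else if (pair_ok(flip(oa), flip(ea))) {
      variants$effect_allele[i] <- flip(oa)
      variants$other_allele[i] <- flip(ea)
      variants$beta[i] <- -variants$beta[i]
      variants$swapped[i] <- TRUE
    } else {
      variants$qc_status[i] <- "fail:allele_mismatch"
      next
    }
    maf_g <- min(variants$maf_gwas[i], 1 - variants$maf_gwas[i])
    maf_r <- min(reference$maf_ref[j], 1 - reference$maf_ref[j])
    if (is_palindromic(variants$effect_allele[i], variants$other_allele[i]) &&
        maf_g >= palindromic_maf) {
      variants$qc_status[i] <- "fail:palindromic"
      next
    }
    if (abs(maf_g - maf_r) > maf_diff_max) {
      variants$qc_status[i] <- "fail:maf_discordant"
      next
    }
    variants$maf_ref[i] <- reference$maf_ref[j]
  }
  variants
}

#' Greedy LD clumping
#'
#' Within each cancer site, repeatedly selects the remaining variant with
#' the smallest p-value as the index (p ties broken by genomic position)
#' and removes all other remaining variants with r-squared at or above the
#' threshold to that index. Removed variants get status `fail:clumped`.
#' Variant pairs absent from the LD table are treated as unlinked (r2 = 0)
#' with a warning, unless `strict = TRUE`, which errors instead.
#'
#' @param variants Variant tibble; only `pass`/`proxy:*` rows participate.
#' @param ld Tibble with `id1`, `id2`, `r2`.
#' @param r2_threshold Clumping threshold; variants with `r2 >=` this to an
#'   index are removed (default 0.2).
#' @param strict Error on missing LD entries instead of assuming r2 = 0.
#' @return `variants` with `fail:clumped` statuses applied.
#' @export
ld_clump <- function(variants, ld, r2_threshold = 0.2, strict = FALSE) {
  # an empty LD table declares all variants unlinked; no warning needed
  warned <- nrow(ld) == 0 && !strict
  for (s in unique(variants$site)) {
    live <- which((variants$qc_status == "pass" |
                     startsWith(variants$qc_status, "proxy:")) &
                    variants$site == s)
    remaining <- live[order(variants$p[live], variants$pos[live])]
    while (length(remaining)) {
      idx <- remaining[1]
      remaining <- remaining[-1]
      if (!length(remaining)) break
      r2 <- vapply(variants$variant_id[remaining], function(other) {
        v <- ld_lookup(ld, variants$variant_id[idx], other)
        if (is.na(v)) {
          if (strict) abort(paste0("No LD entry for pair ",
                                   variants$variant_id[idx], " / ", other))
          if (!warned) {
            warn("LD entries missing for some pairs; treating them as r2 = 0.")
            warned <<- TRUE
          }
          v <- 0
        }
        v
      }, 0)
      drop <- remaining[r2 >= r2_threshold]
      variants$qc_status[drop] <- "fail:clumped"
      remaining <- setdiff(remaining, drop)
    }
  }
  variants
}

#' Run the full summary-statistics harmonization chain
#'
#' Significance/frequency filtering, optional proxy substitution,
#' reference QC, and LD clumping, with a per-status accounting report:
#' every input variant ends in exactly one terminal status.
#'
#' @param variants Raw variant tibble.
#' @param reference Reference panel tibble (see [qc_against_reference()]).
#' @param ld LD tibble (`id1`, `id2`, `r2`).
#' @param available Optional availability tibble for [proxy_substitute()];
#'   `NULL` skips proxy search (all variants treated as available).
#' @param r2_proxy,r2_clump Thresholds.
#' @return The harmonized variant tibble with attribute `"report"`, a
#'   tibble of per-status counts (`harmonization_report()` retrieves it).
#' @export
harmonize_variants <- function(variants, reference, ld = tibble(
                                 id1 = character(), id2 = character(),
                                 r2 = numeric()),
                               available = NULL,
                               r2_proxy = 0.8, r2_clump = 0.2) {
  n_in <- nrow(variants)
  variants <- filter_summary_stats(variants)
  if (!is.null(available))
    variants <- proxy_substitute(variants, available, ld, r2_proxy)
  variants <- qc_against_reference(variants, reference)
  variants <- ld_clump(variants, ld, r2_clump)
  report <- variants |>
    count(.data$qc_status, name = "n") |>
    arrange(desc(.data$n))
  stopifnot(sum(report$n) == n_in)
  attr(variants, "report") <- report
  variants
}

#' @rdname harmonize_variants
#' @param x A harmonized variant tibble.
#' @export
harmonization_report <- function(x) attr(x, "report")

#' Score a site-specific polygenic risk score from dosages
#'
#' The score is the dosage-weighted sum of per-allele effect sizes over the
#' site's surviving (pass or proxy) variants, on the effect-allele scale of
#' the harmonized records.
#'
#' @param dosages Numeric matrix (participants x variants) with values in
#'   \[0, 2\] and variant ids as column names; columns count copies of each
#'   variant's stored effect allele.
#' @param variants Harmonized variant tibble for one site.
#' @param orient `"effect"` scores on the stored effect-allele scale
#'   (signed effect sizes as given); `"risk"` re-orients every variant to
#'   its risk allele (for a negative effect size, counts the other allele:
#'   `(2 - dosage) * |beta|`), which shifts each participant's score by the
#'   same constant and guarantees non-negative scores, matching the
#'   risk-allele-summing convention.
#' @return Numeric vector of per-participant scores.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 2), 1, dimnames = list("p1", c("a", "b", "c")))
#' v <- tibble::tibble(variant_id = c("a", "b", "c"), beta = c(0.1, 0.2, 0.3),
#'                     qc_status = "pass")
#' score_site_prs(d, v)  # 0.8
score_site_prs <- function(dosages, variants,
                           orient = c("effect", "risk")) {
  orient <- match.arg(orient)
  keep <- variants$qc_status == "pass" |
    startsWith(variants$qc_status, "proxy:")
  variants <- variants[keep, , drop = FALSE]
  miss <- setdiff(variants$variant_id, colnames(dosages))
  if (length(miss))
    abort(paste0("Dosage column(s) missing for variant(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  D <- dosages[, variants$variant_id, drop = FALSE]
  if (any(D < 0 | D > 2))
    abort("Dosages must lie in [0, 2].")
  score <- drop(D %*% variants$beta)
  if (orient == "risk")
    score <- score + 2 * sum(abs(variants$beta[variants$beta < 0]))
  score
}

#' Age-standardized incidence weights for the composite score
#'
#' Weights used to combine site-specific scores into the composite
#' gastrointestinal score. The shipped default rates are stand-in values on
#' the scale of UK age-standardized incidence (per 100,000 person-years);
#' analyses of real data should supply the rates for their population.
#' `mode = "mean_standardized"` additionally rescales each site score by
#' its cohort mean before weighting (sensitivity variant).
#'
#' @param rates Named positive numeric: `ESC`, `GC`, `CRC`.
#' @param mode `"incidence_weighted"` (default) or `"mean_standardized"`.
#' @return An object of class `incidence_weights`.
#' @export
incidence_weights <- function(rates = c(ESC = 14, GC = 11, CRC = 70),
                              mode = c("incidence_weighted",
                                       "mean_standardized")) {
  mode <- match.arg(mode)
  if (!all(c("ESC", "GC", "CRC") %in% names(rates)))
    abort("`rates` must name ESC, GC, CRC.")
  if (any(rates <= 0)) abort("Incidence rates must be strictly positive.")
  structure(list(rates = rates, mode = mode), class = "incidence_weights")
}

#' Combine site-specific scores into the composite GI score
#'
#' In `incidence_weighted` mode the composite is the incidence-rate-weighted
#' sum of the three site scores. In `mean_standardized` mode each site score
#' is first divided by its cohort mean (so each rescaled site score has mean
#' 1) before weighting. The composite is also standardized to zero mean and
#' unit standard deviation over the supplied cohort (`gi_prs_z`).
#'
#' @param site_scores Tibble with columns `id`, `ESC`, `GC`, `CRC`.
#' @param weights An [incidence_weights()].
#' @return A tibble (`prs_result`): `id`, the (possibly rescaled) site
#'   scores, `gi_prs`, `gi_prs_z`.
#' @export
combine_gi_prs <- function(site_scores, weights = incidence_weights()) {
  stopifnot(all(c("id", "ESC", "GC", "CRC") %in% names(site_scores)))
  s <- site_scores[, c("ESC", "GC", "CRC")]
  if (weights$mode == "mean_standardized") {
    for (k in names(s)) {
      m <- mean(s[[k]])
      if (abs(m) < 1e-12)
        abort(paste0("Site ", k, " score mean is zero; cannot mean-standardize."))
      s[[k]] <- s[[k]] / m
    }
  }
  w <- weights$rates[c("ESC", "GC", "CRC")]
  gi <- as.matrix(s) %*% w
  gi <- drop(gi)
  sdv <- sd(gi)
  z <- if (sdv > 0) (gi - mean(gi)) / sdv else gi * 0
  tibble(id = site_scores$id, ESC = s$ESC, GC = s$GC, CRC = s$CRC,
         gi_prs = gi, gi_prs_z = z)
}

#' Assign quintile-based genetic risk categories
#'
#' Quintile boundaries come from the empirical distribution of the supplied
#' scores (the analysis cohort). Values equal to a cut point go to the
#' lower quintile. Categories: low = quintile 1, intermediate = quintiles
#' 2-4, high = quintile 5.
#'
#' @param gi_prs Numeric vector of composite scores (at least 5 distinct
#'   values).
#' @return A tibble with `quintile` (integer 1-5) and `genetic_category`
#'   (factor low/intermediate/high).
#' @export
assign_genetic_category <- function(gi_prs) {
  if (length(unique(gi_prs)) < 5L)
    abort("Need at least 5 distinct score values to form quintiles.")
  breaks <- quantile(gi_prs, probs = c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  q <- findInterval(gi_prs, breaks, left.open = TRUE) + 1L
  tibble(quintile = q,
         genetic_category = factor(
           dplyr::case_when(q == 1L ~ "low", q == 5L ~ "high",
                            TRUE ~ "intermediate"),
           levels = c("low", "intermediate", "high")))
}
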