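test_that("variant panel has the configured site composition", {
  panel <- make_variant_panel(scenario_config(), seed = 1)
  expect_equal(nrow(panel), 106L)
  expect_equal(as.vector(table(panel$site)[c("ESC", "GC", "CRC")]),
               c(13L, 3L, 90L))
  expect_equal(anyDuplicated(panel$variant_id), 0L)
  expect_true(all(panel$maf_gwas > 0 & panel$maf_gwas < 1))
  expect_true(all(is.finite(panel$beta)))
  expect_true(all(panel$p < 5e-8))
  expect_error(
    make_variant_panel(scenario_config(
      n_snps_per_site = c(ESC = 0L, GC = 0L, CRC = 0L))),
    "empty")
})

test_that("decoy variants carry planted QC defects", {
  cfg <- scenario_config(decoy_fraction = 0.2)
  panel <- make_variant_panel(cfg, seed = 3)
  decoys <- panel[panel$decoy, ]
  expect_gt(nrow(decoys), 0)
  bad <- (decoys$effect_allele == "A" & decoys$other_allele == "T" &
            decoys$maf_gwas >= 0.45) |
    (abs(decoys$maf_gwas - decoys$maf_ref) > 0.10)
  expect_true(all(bad))
})

test_that("panels and cohorts are byte-identical under a fixed seed", {
  cfg <- small_config(n = 400)
  expect_identical(make_variant_panel(cfg, seed = 5),
                   make_variant_panel(cfg, seed = 5))
  c1 <- simulate_cohort(cfg, seed = 9)
  c2 <- simulate_cohort(cfg, seed = 9)
  expect_identical(c1$participants, c2$participants)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_false(identical(simulate_cohort(cfg, seed = 10)$participants,
                         c1$participants))
})

test_that("genotype dosages follow the panel allele frequency", {
  v <- variant_row("v1", maf = 0.5)
  G <- simulate_genotypes(v, n = 100000, seed = 2)
  expect_true(all(G %in% 0:2))
  # binomial standard error sqrt(0.25 / (2n)) ~ 0.0011
  expect_lt(abs(mean(G) / 2 - 0.5), 0.005)
  g1 <- simulate_genotypes(make_variant_panel(scenario_config(), seed = 1),
                           n = 1, seed = 4)
  expect_equal(dim(g1), c(1L, 106L))
  expect_error(simulate_genotypes(v, n = 0, seed = 1), "at least 1")
})

test_that("genotypes satisfy Hardy-Weinberg proportions", {
  panel <- make_variant_panel(scenario_config(), seed = 1)
  fails <- 0L; total <- 0L
  for (s in 1:3) {
    G <- simulate_genotypes(panel, n = 20000, seed = s)
    for (j in seq_len(ncol(G))) {
      obs <- tabulate(G[, j] + 1L, 3L)
      f <- mean(G[, j]) / 2
      expct <- 20000 * c((1 - f)^2, 2 * f * (1 - f), f^2)
      chi <- sum((obs - expct)^2 / expct)
      total <- total + 1L
      if (pchisq(chi, 1, lower.tail = FALSE) < 0.001) fails <- fails + 1L
    }
  }
  expect_lt(fails / total, 0.01)
})

test_that("component thresholds reproduce an exact binomial benchmark", {
  # identity latent correlation, all prevalences 0.5:
  # P(MetS) = P(Binomial(5, 0.5) >= 3) = 0.5 exactly
  cfg <- scenario_config(
    n_participants = 150000,
    component_latent_corr = diag(5),
    component_target_prevalence = c(central_obesity = 0.5, hypertension = 0.5,
                                    dyslipidemia = 0.5,
                                    hypertriglyceridemia = 0.5,
                                    hyperglycemia = 0.5),
    eligibility_rates = modifyList(scenario_config()$eligibility_rates,
                                   list(all_components_missing = 0)))
  ph <- simulate_metabolic_phenotypes(cfg, seed = 11)
  fl <- flag_components(ph, mets_criteria())
  expect_lt(abs(mean(fl$mets) - 0.5), 0.006)
})

test_that("zero target prevalence yields no flags at all", {
  cfg <- scenario_config(
    n_participants = 2000,
    component_target_prevalence = c(central_obesity = 0, hypertension = 0,
                                    dyslipidemia = 0,
                                    hypertriglyceridemia = 0,
                                    hyperglycemia = 0),
    eligibility_rates = modifyList(scenario_config()$eligibility_rates,
                                   list(all_components_missing = 0)))
  ph <- simulate_metabolic_phenotypes(cfg, seed = 2)
  fl <- flag_components(ph, mets_criteria())
  expect_equal(sum(fl$n_components), 0L)
})

test_that("outcome simulation honours planted effects and degenerate cases", {
  cfg <- scenario_config(n_participants = 200000, missing_rate = 0,
                         baseline_hazard = 0.002,
                         planted_loghr = list(mets = log(1.28)),
                         eligibility_rates = modifyList(
                           scenario_config()$eligibility_rates,
                           list(all_components_missing = 0)))
  ph <- simulate_metabolic_phenotypes(cfg, seed = 21)
  out <- simulate_outcomes(ph, rep(0, nrow(ph)), cfg, seed = 22)
  fl <- flag_components(out, mets_criteria(), allow_missing = TRUE)
  mets <- fl$n_components >= 3
  rr <- (sum(out$event[mets]) / sum(out$time[mets])) /
    (sum(out$event[!mets]) / sum(out$time[!mets]))
  # crude rate ratio of the exponential model equals the hazard ratio
  expect_lt(abs(rr - 1.28), 0.12)

  null_cfg <- scenario_config(n_participants = 50000, missing_rate = 0,
                              baseline_hazard = 0.002, planted_loghr = list(),
                              eligibility_rates = modifyList(
                                scenario_config()$eligibility_rates,
                                list(all_components_missing = 0)))
  out0 <- simulate_outcomes(simulate_metabolic_phenotypes(null_cfg, seed = 5),
                            rep(0, 50000), null_cfg, seed = 6)
  fl0 <- flag_components(out0, mets_criteria(), allow_missing = TRUE)
  m0 <- fl0$n_components >= 3
  rr0 <- (sum(out0$event[m0]) / sum(out0$time[m0])) /
    (sum(out0$event[!m0]) / sum(out0$time[!m0]))
  expect_lt(abs(rr0 - 1), 0.25)

  zero_fu <- scenario_config(n_participants = 100, followup_years = 0)
  phz <- simulate_metabolic_phenotypes(zero_fu, seed = 1)
  outz <- simulate_outcomes(phz, rep(0, 100), zero_fu, seed = 2)
  expect_equal(sum(outz$event), 0L)
  expect_equal(max(outz$time), 0)
  expect_error(simulate_outcomes(phz, 1:5, zero_fu, seed = 1),
               "one value per record")
})

test_that("missingness injection matches the configured rate", {
  cfg <- scenario_config(n_participants = 100000, missing_rate = 0.1,
                         eligibility_rates = modifyList(
                           scenario_config()$eligibility_rates,
                           list(all_components_missing = 0)))
  ph <- simulate_metabolic_phenotypes(cfg, seed = 31)
  mi <- inject_missingness(ph, cfg, seed = 32)
  # binomial SE at n = 1e5 is about 0.001
  expect_lt(abs(mean(is.na(mi$waist)) - 0.1), 0.003)
  expect_lt(abs(mean(mi$smoking == "prefer not to answer") - 0.1), 0.003)
  cfg0 <- scenario_config(n_participants = 100, missing_rate = 0)
  ph0 <- simulate_metabolic_phenotypes(cfg0, seed = 1)
  expect_identical(inject_missingness(ph0, cfg0, seed = 1), ph0)
})

test_that("site-specific scores are mutually independent by construction", {
  coh <- simulate_cohort(small_config(n = 30000), seed = 13)
  r <- cor(coh$prs[, c("ESC", "GC", "CRC")])
  expect_lt(max(abs(r[upper.tri(r)])), 0.02)
})
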