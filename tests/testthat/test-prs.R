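test_that("summary-statistic filtering applies both thresholds with reasons", {
  v <- dplyr::bind_rows(
    variant_row("a", p = 1e-7, maf = 0.2),
    variant_row("b", p = 1e-9, maf = 0.005),
    variant_row("c", p = 4.9e-8, maf = 0.01),
    variant_row("d", p = NA_real_, maf = 0.3))
  out <- filter_summary_stats(v)
  expect_equal(out$qc_status,
               c("fail:p_threshold", "fail:maf", "pass", "fail:missing_stats"))
})

test_that("proxy substitution takes the best available proxy above r2 0.8", {
  v <- variant_row("v1", pos = 500)
  avail <- tibble::tibble(variant_id = c("p1", "p2", "p3"),
                          pos = c(900, 100, 400))
  ld <- tibble::tibble(id1 = c("v1", "v1", "v1"),
                       id2 = c("p1", "p2", "p3"),
                       r2 = c(0.85, 0.92, 0.92))
  out <- proxy_substitute(v, avail, ld)
  expect_equal(out$variant_id, "p2")  # r2 tie broken by smaller position
  expect_equal(out$qc_status, "proxy:v1")

  present <- proxy_substitute(variant_row("p1"), avail, ld)
  expect_equal(present$qc_status, "pass")
  expect_equal(present$variant_id, "p1")

  at_bound <- proxy_substitute(variant_row("v2"),
                               avail,
                               tibble::tibble(id1 = "v2", id2 = "p1", r2 = 0.8))
  expect_equal(at_bound$qc_status, "fail:no_proxy")
})

test_that("reference QC fails discordant, mismatched, and palindromic variants", {
  ref <- tibble::tibble(variant_id = c("a", "b", "c", "d", "e"),
                        allele1 = c("A", "A", "A", "A", "A"),
                        allele2 = c("G", "T", "T", "G", "C"),
                        maf_ref = c(0.42, 0.46, 0.30, 0.30, 0.30))
  v <- dplyr::bind_rows(
    variant_row("a", "A", "G", maf = 0.30),   # |0.30 - 0.42| > 0.10
    variant_row("b", "A", "T", maf = 0.46),   # palindromic at high MAF
    variant_row("c", "A", "T", maf = 0.30),   # palindromic but resolvable
    variant_row("d", "A", "G", maf = 0.30),
    variant_row("x", "A", "G", maf = 0.30))   # absent from reference
  out <- qc_against_reference(v, ref)
  expect_equal(out$qc_status,
               c("fail:maf_discordant", "fail:palindromic", "pass", "pass",
                 "fail:not_in_reference"))
  # A/G cannot be reconciled with an A/C reference by any flip/swap
  mism <- qc_against_reference(variant_row("e", "A", "G"), ref)
  expect_equal(mism$qc_status, "fail:allele_mismatch")
})

test_that("effect/other swap negates the effect size; strand flips reconcile", {
  ref <- tibble::tibble(variant_id = c("s", "f"), allele1 = c("G", "T"),
                        allele2 = c("A", "C"), maf_ref = c(0.3, 0.3))
  swapped <- qc_against_reference(variant_row("s", "A", "G", beta = 0.2), ref)
  expect_equal(swapped$qc_status, "pass")
  expect_true(swapped$swapped)
  expect_equal(swapped$beta, -0.2)
  expect_equal(swapped$effect_allele, "G")
  flipped <- qc_against_reference(variant_row("f", "A", "G", beta = 0.2), ref)
  expect_equal(flipped$qc_status, "pass")
  expect_false(flipped$swapped)
  expect_equal(flipped$beta, 0.2)
  expect_equal(flipped$effect_allele, "T")
})

test_that("strand-flipping a non-palindromic variant changes nothing downstream", {
  ref <- tibble::tibble(variant_id = "v", allele1 = "A", allele2 = "G",
                        maf_ref = 0.3)
  plain <- qc_against_reference(variant_row("v", "A", "G", beta = 0.17), ref)
  comp <- qc_against_reference(variant_row("v", "T", "C", beta = 0.17), ref)
  expect_equal(comp$qc_status, plain$qc_status)
  expect_equal(comp$beta, plain$beta)
  expect_equal(comp$effect_allele, plain$effect_allele)
})

test_that("greedy clumping matches its stated examples", {
  ld_of <- function(...) tibble::tibble(...)
  two <- dplyr::bind_rows(variant_row("A", p = 1e-10, pos = 1),
                          variant_row("B", p = 1e-9, pos = 2))
  out <- ld_clump(two, ld_of(id1 = "A", id2 = "B", r2 = 0.1))
  expect_equal(sum(out$qc_status == "pass"), 2L)

  three <- dplyr::bind_rows(variant_row("A", p = 1e-12, pos = 1),
                            variant_row("B", p = 1e-10, pos = 2),
                            variant_row("C", p = 1e-9, pos = 3))
  allhigh <- ld_of(id1 = c("A", "A", "B"), id2 = c("B", "C", "C"),
                   r2 = c(0.5, 0.5, 0.5))
  out3 <- ld_clump(three, allhigh)
  expect_equal(out3$qc_status, c("pass", "fail:clumped", "fail:clumped"))

  chain <- ld_of(id1 = c("A", "B", "A"), id2 = c("B", "C", "C"),
                 r2 = c(0.5, 0.5, 0.05))
  outc <- ld_clump(three, chain)
  expect_equal(outc$qc_status[outc$variant_id %in% c("A", "C")],
               c("pass", "pass"))
  expect_equal(outc$qc_status[outc$variant_id == "B"], "fail:clumped")
})

test_that("greedy clumping agrees with the matrix oracle on small panels", {
  set.seed(77)
  for (rep in 1:25) {
    m <- sample(4:12, 1)
    ids <- paste0("v", seq_len(m))
    R2 <- matrix(0, m, m, dimnames = list(ids, ids))
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      R2[i, j] <- R2[j, i] <- sample(c(0, runif(1)), 1, prob = c(0.5, 0.5))
    p <- 10^runif(m, -20, -8)
    pos <- sample.int(1e6, m)
    v <- variant_row(ids[1])[rep(1, m), ]
    v$variant_id <- ids; v$p <- p; v$pos <- pos
    pairs <- which(upper.tri(R2), arr.ind = TRUE)
    ld <- tibble::tibble(id1 = ids[pairs[, 1]], id2 = ids[pairs[, 2]],
                         r2 = R2[pairs])
    out <- ld_clump(v, ld)
    kept <- which(out$qc_status == "pass")
    expect_equal(kept, oracle_clump(p, pos, R2))
  }
})

test_that("harmonization conserves every variant with one terminal status", {
  cfg <- scenario_config(decoy_fraction = 0.3)
  panel <- make_variant_panel(cfg, seed = 6)
  ref <- tibble::tibble(variant_id = panel$variant_id,
                        allele1 = panel$effect_allele,
                        allele2 = panel$other_allele,
                        maf_ref = panel$maf_ref)
  out <- harmonize_variants(panel, ref)
  rep <- harmonization_report(out)
  expect_equal(sum(rep$n), nrow(panel))
  expect_true(all(out$qc_status == "pass" |
                    startsWith(out$qc_status, "fail:") |
                    startsWith(out$qc_status, "proxy:")))
  # every decoy was caught by QC
  expect_true(all(startsWith(out$qc_status[out$decoy], "fail:")))
  expect_true(all(out$qc_status[!out$decoy] == "pass"))
})

test_that("dosage scoring is the effect-size-weighted sum", {
  d <- matrix(c(0, 1, 2), 1, dimnames = list("p1", c("a", "b", "c")))
  v <- dplyr::bind_rows(variant_row("a", beta = 0.1),
                        variant_row("b", beta = 0.2),
                        variant_row("c", beta = 0.3))
  expect_equal(score_site_prs(d, v), c(p1 = 0.8))
  expect_equal(score_site_prs(d * 0, v), c(p1 = 0))
  bad <- d; bad[1] <- 3
  expect_error(score_site_prs(bad, v), "\\[0, 2\\]")
})

test_that("allele-flipping a variant shifts scores by a constant, ranks intact", {
  set.seed(3)
  v <- dplyr::bind_rows(variant_row("a", beta = 0.1),
                        variant_row("b", beta = -0.2),
                        variant_row("c", beta = 0.3))
  D <- matrix(sample(0:2, 60, TRUE), 20,
              dimnames = list(NULL, c("a", "b", "c")))
  s0 <- score_site_prs(D, v)
  vf <- v
  vf$beta[2] <- -vf$beta[2]
  Df <- D; Df[, 2] <- 2 - Df[, 2]
  s1 <- score_site_prs(Df, vf)
  # shift is the constant 2*|beta_b|; ranks follow up to float ties
  expect_equal(s1 - s0, rep(0.4, 20), tolerance = 1e-12)
  # risk orientation equals that constant shift and is non-negative
  sr <- score_site_prs(D, v, orient = "risk")
  expect_equal(sr, s0 + 2 * 0.2)
  expect_true(all(sr >= 0))
})

test_that("composite score weighting and standardization behave", {
  sc <- tibble::tibble(id = c("p1", "p2", "p3"),
                       ESC = c(0.2, 0.1, 0.4), GC = c(0.3, 0.3, 0.1),
                       CRC = c(0.5, 0.2, 0.9))
  unit <- combine_gi_prs(sc, incidence_weights(c(ESC = 1, GC = 1, CRC = 1)))
  expect_equal(unit$gi_prs[1], 1.0)
  w1 <- combine_gi_prs(sc, incidence_weights(c(ESC = 14, GC = 11, CRC = 70)))
  w2 <- combine_gi_prs(sc, incidence_weights(c(ESC = 28, GC = 22, CRC = 140)))
  expect_equal(w1$gi_prs_z, w2$gi_prs_z)
  ms <- combine_gi_prs(sc, incidence_weights(mode = "mean_standardized"))
  expect_equal(mean(ms$ESC), 1, tolerance = 1e-12)
  expect_equal(mean(ms$GC), 1, tolerance = 1e-12)
  expect_equal(mean(ms$CRC), 1, tolerance = 1e-12)
  zero <- sc; zero$GC <- c(-1, 0, 1)
  expect_error(combine_gi_prs(zero, incidence_weights(mode = "mean_standardized")),
               "mean is zero")
})

test_that("quintile categories are 20/60/20 with the lower-boundary convention", {
  set.seed(12)
  x <- rnorm(100000)
  gc <- assign_genetic_category(x)
  expect_equal(as.vector(table(gc$genetic_category)),
               c(20000L, 60000L, 20000L))
  # a value sitting exactly on a cut point goes to the lower quintile
  y <- 0:10  # 20th percentile is exactly 2
  gy <- assign_genetic_category(y)
  cut1 <- unname(quantile(y, 0.2))
  expect_equal(cut1, 2)
  expect_equal(unique(gy$quintile[y == cut1]), 1L)
  expect_error(assign_genetic_category(rep(1, 10)), "distinct")
  # adding a constant changes neither category nor quintile
  gz <- assign_genetic_category(x + 5)
  expect_identical(gz, gc)
})
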