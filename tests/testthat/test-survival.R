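test_that("fitted coefficient maximizes the brute-force partial likelihood", {
  for (seed in c(2, 5, 8, 13)) {
    d <- surv_data(8, seed, binary = seed %% 2 == 0)
    f <- fit_cox(d, "x", adjustment = "none")
    oracle <- brute_cox_coef(d$time, d$event, d$x)
    expect_equal(unname(coef(f$fit)), oracle, tolerance = 1e-4)
  }
})

test_that("Efron and Breslow agree exactly when no event times are tied", {
  d <- surv_data(60, 21, censor = TRUE)
  fe <- fit_cox(d, "x", adjustment = "none", ties = "efron")
  fb <- fit_cox(d, "x", adjustment = "none", ties = "breslow")
  expect_equal(coef(fe$fit), coef(fb$fit), tolerance = 1e-10)
})

test_that("rescaling follow-up time leaves coefficients unchanged", {
  d <- surv_data(150, 31, censor = TRUE)
  f1 <- fit_cox(d, "x", adjustment = "none")
  d2 <- d; d2$time <- d2$time * 3.7
  f2 <- fit_cox(d2, "x", adjustment = "none")
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-8)
})

test_that("Cox matches the closed-form exponential rate-ratio estimator", {
  d <- surv_data(200, 41)
  mle <- (sum(d$event[d$x == 1]) / sum(d$time[d$x == 1])) /
    (sum(d$event[d$x == 0]) / sum(d$time[d$x == 0]))
  f <- fit_cox(d, "x", adjustment = "none")
  expect_lt(abs(exp(coef(f$fit)) / mle - 1), 0.10)
})

test_that("cox_fit reports HR arithmetic and tidies consistently", {
  d <- surv_data(100, 51, censor = TRUE)
  f <- fit_cox(d, "x", adjustment = "none")
  td <- tidy(f)
  expect_equal(td$hr, exp(td$estimate))
  expect_equal(td$conf.low, exp(td$estimate - 1.96 * td$std.error))
  gl <- glance(f)
  expect_equal(gl$n_events, sum(d$event))
  expect_true(gl$converged)
})

test_that("zero-event exposure strata are rejected by name", {
  d <- surv_data(50, 61)
  d$g <- rep(c("a", "b"), 25)
  d$event[d$g == "b"] <- 0L
  expect_error(fit_cox(d, "g", adjustment = "none"), "zero events: b")
  expect_error(fit_cox(dplyr::mutate(d, event = 0L), "g",
                       adjustment = "none"), "No events")
})

test_that("trend test requires three ordered levels", {
  d <- surv_data(200, 71, censor = TRUE)
  d$band <- factor(sample(c("0", "1-2", ">=3"), 200, TRUE),
                   levels = c("0", "1-2", ">=3"))
  p <- trend_test(d, "band", adjustment = "none")
  expect_true(p$p.value > 0 && p$p.value <= 1)
  d$two <- factor(sample(c("a", "b"), 200, TRUE))
  expect_error(trend_test(d, "two", adjustment = "none"), "3 ordered levels")
})

test_that("Schoenfeld test flags a constructed violation and not a null", {
  set.seed(81)
  n <- 30000
  x <- rbinom(n, 1, 0.5)
  # effect reverses sign at time 5: early hazard up, late hazard down
  t1 <- rexp(n, 0.05 * exp(0.8 * x))
  t2 <- 5 + rexp(n, 0.05 * exp(-0.8 * x))
  t <- ifelse(t1 <= 5, t1, t2)
  d <- tibble::tibble(time = pmin(t, 12), event = as.integer(t <= 12),
                      site = NA_character_, x = x)
  f <- fit_cox(d, "x", adjustment = "none")
  ph <- schoenfeld_ph_test(f)
  expect_lt(ph$p.value[ph$term == "GLOBAL"], 1e-4)

  d0 <- surv_data(5000, 82, censor = TRUE)
  f0 <- fit_cox(d0, "x", adjustment = "none")
  ph0 <- schoenfeld_ph_test(f0)
  expect_gt(ph0$p.value[ph0$term == "GLOBAL"], 0.001)

  one <- tibble::tibble(time = 1, event = 1L, site = NA_character_, x = 1)
  expect_error(schoenfeld_ph_test(
    structure(list(n_events = 1L), class = "cox_fit")), "Too few events")
})

test_that("interaction test names empty joint cells", {
  d <- surv_data(300, 91, censor = TRUE)
  d$mets <- d$x == 1
  d$genetic_category <- factor(sample(c("low", "intermediate", "high"), 300,
                                      TRUE),
                               levels = c("low", "intermediate", "high"))
  d$gi_prs_z <- rnorm(300)
  pc <- interaction_test(d, "category", adjustment = "none", pcs = FALSE)
  expect_equal(pc$df, 2)
  pz <- interaction_test(d, "continuous", adjustment = "none", pcs = FALSE)
  expect_equal(pz$df, 1)
  d2 <- d[!(d$mets & d$genetic_category == "high"), ]
  expect_error(interaction_test(d2, "category", adjustment = "none",
                                pcs = FALSE), "Empty joint cell")
})

test_that("logistic score-on-MetS model flags degenerate outcomes", {
  d <- make_records(400, seed = 14)
  d$mets <- flag_components(d)$mets
  d$gi_prs_z <- rnorm(400)
  out <- logistic_prs_on_mets(d, adjustment = "none", pcs = FALSE)
  expect_true(out$conf.low < out$or & out$or < out$conf.high)
  d$mets <- TRUE
  expect_error(logistic_prs_on_mets(d, adjustment = "none", pcs = FALSE),
               "constant")
})

test_that("spline basis and dose-response respect their reference point", {
  x <- seq(-3, 3, length.out = 500)
  B <- rcs_basis(x, c(-2, 0, 2))
  expect_equal(ncol(B), 2L)
  expect_equal(B[, 1], x)
  expect_error(rcs_basis(x, c(0, 0, 1)), "strictly increasing")

  set.seed(15)
  n <- 4000
  z <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.3 * z))
  d <- tibble::tibble(time = pmin(t, 12), event = as.integer(t <= 12),
                      site = NA_character_, gi_prs_z = z)
  fit <- rcs_dose_response(d, adjustment = "none", pcs = FALSE,
                           grid_length = 201L)
  curve_at_ref <- fit$curve$hr[which.min(abs(fit$curve$score - fit$ref))]
  expect_equal(curve_at_ref, 1, tolerance = 0.05)
  # monotone log-linear truth: curve increases over the bulk of the range
  expect_gt(fit$curve$hr[180], fit$curve$hr[20])
  expect_true(fit$p_nonlinear > 0 && fit$p_nonlinear <= 1)
})

test_that("subgroup analysis reports non-estimable strata and heterogeneity", {
  d <- surv_data(600, 16, censor = TRUE)
  d$mets <- d$x == 1
  d$grp <- sample(c("m", "f"), 600, TRUE)
  out <- subgroup_analysis(d, "grp", exposure = "mets", adjustment = "none")
  expect_equal(nrow(out$strata), 2L)
  expect_true(is.numeric(out$p_heterogeneity))
  d$event[d$grp == "f"] <- 0L
  out2 <- subgroup_analysis(d, "grp", exposure = "mets", adjustment = "none")
  expect_true(is.na(out2$strata$hr[out2$strata$level == "f"]))
  d$grp <- "m"
  expect_error(subgroup_analysis(d, "grp", exposure = "mets",
                                 adjustment = "none"), "fewer than 2")
})
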