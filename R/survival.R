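#' Covariate adjustment sets
#'
#' `model1`: age group, sex, qualification, deprivation index, family
#' history of cancer. `model2`: additionally smoking, alcohol, physical
#' activity, fruit, vegetable, red/processed meat, and regular
#' aspirin/ibuprofen use. Models including genetic exposures additionally
#' adjust the top 10 genetic principal components (`pcs = TRUE`).
#'
#' @param adjustment `"model1"`, `"model2"`, or `"none"`.
#' @param pcs Include the 10 genetic principal components.
#' @return Character vector of covariate column names.
#' @export
adjustment_covariates <- function(adjustment = c("model2", "model1", "none"),
                                  pcs = FALSE) {
  adjustment <- match.arg(adjustment)
  model1 <- c("age_group", "sex", "qualification", "townsend", "family_history")
  model2 <- c(model1, "smoking", "alcohol", "physical_activity", "fruit",
              "vegetable", "red_processed_meat", "aspirin_ibuprofen")
  covars <- switch(adjustment, none = character(), model1 = model1,
                   model2 = model2)
  if (pcs) covars <- c(covars, paste0("pc", 1:10))
  covars
}

# site-specific outcome: events at other GI sites count as censoring
outcome_columns <- function(records, outcome) {
  if (outcome == "GI") {
    ev <- records$event
  } else {
    if (!outcome %in% c("ESC", "GC", "CRC"))
      abort("`outcome` must be one of GI, ESC, GC, CRC.")
    ev <- as.integer(records$event == 1L & !is.na(records$site) &
                       records$site == outcome)
  }
  list(time = records$time, event = ev)
}

build_rhs <- function(records, vars) {
  keep <- vars[vapply(vars, function(v) {
    x <- records[[v]]
    length(unique(x[!is.na(x)])) >= 2L
  }, TRUE)]
  keep
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood (via [survival::coxph()]) for the
#' given exposure terms and adjustment set on follow-up time from baseline.
#' Reference levels are the first factor levels of the exposure columns
#' (no metabolic syndrome; zero components; low genetic risk). Constant
#' covariates are dropped from the design; a factor exposure level with
#' zero events is an error naming the stratum.
#'
#' @param records Analysis tibble with `time`, `event`, `site`, exposures,
#'   and covariates.
#' @param exposure Character vector of exposure column names (factors or
#'   numeric scores).
#' @param adjustment `"model2"` (default), `"model1"`, or `"none"`.
#' @param pcs Adjust the 10 genetic principal components.
#' @param outcome `"GI"` (default) or a single site (`"ESC"`, `"GC"`,
#'   `"CRC"`); other-site events are treated as censoring.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `cox_fit`; see [tidy.cox_fit()].
#' @export
fit_cox <- function(records, exposure, adjustment = "model2", pcs = FALSE,
                    outcome = "GI", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  oc <- outcome_columns(records, outcome)
  if (any(oc$time < 0, na.rm = TRUE)) abort("Negative follow-up times.")
  if (sum(oc$event) < 1L) abort("No events in the analysis data.")
  for (ex in exposure) {
    x <- records[[ex]]
    if (is.character(x) || is.factor(x)) {
      tab <- tapply(oc$event, x, sum)
      empty <- names(tab)[is.na(tab) | tab == 0]
      if (length(empty))
        abort(paste0("Exposure `", ex, "` stratum with zero events: ",
                     paste(empty, collapse = ", ")))
    }
  }
  rhs <- build_rhs(records, c(exposure,
                              adjustment_covariates(adjustment, pcs)))
  dat <- records[, intersect(names(records), rhs), drop = FALSE]
  dat$.time <- oc$time
  dat$.event <- oc$event
  fml <- as.formula(paste("survival::Surv(.time, .event) ~",
                          paste(rhs, collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties, model = FALSE),
    warning = function(w) {
      if (grepl("converge|infinite|singular", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  terms <- tibble(
    term = names(co),
    estimate = unname(co),
    std.error = unname(se),
    hr = exp(unname(co)),
    conf.low = exp(unname(co) - 1.96 * unname(se)),
    conf.high = exp(unname(co) + 1.96 * unname(se)),
    p.value = 2 * pnorm(-abs(unname(co) / unname(se))))
  structure(list(fit = fit, terms = terms, exposure = exposure,
                 adjustment = adjustment, pcs = pcs, outcome = outcome,
                 ties = ties, n = fit$n, n_events = fit$nevent,
                 loglik = fit$loglik[2], converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("<cox_fit> outcome:", x$outcome, " n:", x$n, " events:", x$n_events,
      " ties:", x$ties, if (!x$converged) " [NOT CONVERGED]", "\n")
  print(x$terms, n = Inf)
  invisible(x)
}

#' Broom-style tidiers for fitted Cox models
#'
#' `tidy()` returns one row per model term with the log hazard ratio, its
#' standard error, the hazard ratio with 95% confidence interval, and the
#' Wald p-value. `glance()` returns one-row model-level summaries.
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.cox_fit <- function(x, ...) x$terms

#' @rdname tidy.cox_fit
#' @exportS3Method generics::glance
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, loglik = x$loglik,
         ties = x$ties, converged = x$converged)
}

# joint Wald chi-square test of a set of coefficients
wald_joint <- function(fit, term_idx) {
  b <- coef(fit)[term_idx]
  V <- vcov(fit)[term_idx, term_idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V) %*% b)
  list(statistic = stat, df = length(b),
       p.value = pchisq(stat, length(b), lower.tail = FALSE))
}

#' Wald trend test across an ordinal exposure
#'
#' Enters the exposure as a single ordinal score (0, 1, 2, ...) in the
#' adjusted Cox model and returns the Wald p-value.
#'
#' @inheritParams fit_cox
#' @param exposure Name of an ordered factor/character column with at least
#'   three levels.
#' @return A one-row tibble: `estimate` (log hazard ratio per band),
#'   `p.value`.
#' @export
trend_test <- function(records, exposure = "mets_band",
                       adjustment = "model2", pcs = FALSE, outcome = "GI") {
  x <- records[[exposure]]
  lv <- if (is.factor(x)) levels(x) else sort(unique(x))
  if (length(lv) < 3L) abort("Trend test needs at least 3 ordered levels.")
  records$.trend <- as.numeric(factor(x, levels = lv)) - 1
  f <- fit_cox(records, ".trend", adjustment, pcs, outcome)
  t1 <- f$terms[f$terms$term == ".trend", ]
  tibble(estimate = t1$estimate, std.error = t1$std.error,
         p.value = t1$p.value)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Correlation-with-time test on scaled Schoenfeld residuals (identity time
#' transform by default), per model term plus a global test.
#'
#' @param fit A `cox_fit`.
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return Tibble with `term`, `chisq`, `df`, `p.value`; the last row is
#'   `GLOBAL`.
#' @export
schoenfeld_ph_test <- function(fit, transform = "identity") {
  if (fit$n_events < 2L) abort("Too few events for a proportional-hazards test.")
  z <- survival::cox.zph(fit$fit, transform = transform)
  tb <- z$table
  tibble(term = rownames(tb), chisq = tb[, "chisq"], df = tb[, "df"],
         p.value = tb[, "p"])
}

#' Build the 6-level joint genetic-by-metabolic exposure
#'
#' Crosses `genetic_category` (low/intermediate/high) with metabolic
#' syndrome status; the reference level is `low & no MetS`.
#'
#' @param records Tibble with `genetic_category` and `mets`.
#' @return `records` with a `joint_category` factor.
#' @export
add_joint_exposure <- function(records) {
  m <- ifelse(records$mets, "mets", "no_mets")
  g <- as.character(records$genetic_category)
  lev <- c(t(outer(c("low", "intermediate", "high"),
                   c("no_mets", "mets"), paste, sep = ".")))
  records$joint_category <- factor(paste(g, m, sep = "."), levels = lev)
  records
}

#' Multiplicative interaction test between MetS and genetic risk
#'
#' Adds the product term(s) to the fully adjusted model (model 2 plus
#' principal components) and reports the joint Wald test. `type =
#' "category"` crosses binary MetS with the 3-level genetic category (2
#' product terms, df 2); `type = "continuous"` uses MetS times the
#' standardized composite score (1 df).
#'
#' @inheritParams fit_cox
#' @param type `"category"` or `"continuous"`.
#' @return One-row tibble: `statistic`, `df`, `p.value`.
#' @export
interaction_test <- function(records, type = c("category", "continuous"),
                             adjustment = "model2", pcs = TRUE,
                             outcome = "GI") {
  type <- match.arg(type)
  oc <- outcome_columns(records, outcome)
  if (type == "category") {
    cells <- table(records$mets, records$genetic_category)
    if (any(cells == 0)) {
      bad <- which(cells == 0, arr.ind = TRUE)[1, ]
      abort(paste0("Empty joint cell: mets=", rownames(cells)[bad[1]],
                   " x genetic_category=", colnames(cells)[bad[2]]))
    }
    records$.m <- as.numeric(records$mets)
    records$.i1 <- records$.m * (records$genetic_category == "intermediate")
    records$.i2 <- records$.m * (records$genetic_category == "high")
    f <- fit_cox(records, c(".m", "genetic_category", ".i1", ".i2"),
                 adjustment, pcs, outcome)
    idx <- grep("^\\.i[12]$", names(coef(f$fit)))
  } else {
    records$.m <- as.numeric(records$mets)
    records$.mi <- records$.m * records$gi_prs_z
    f <- fit_cox(records, c(".m", "gi_prs_z", ".mi"), adjustment, pcs, outcome)
    idx <- which(names(coef(f$fit)) == ".mi")
  }
  w <- wald_joint(f$fit, idx)
  tibble(statistic = w$statistic, df = w$df, p.value = w$p.value)
}

#' Logistic regression of metabolic syndrome on the composite score
#'
#' Multivariable logistic model of MetS status on the standardized
#' composite polygenic score, adjusted for the model-2 covariates and the
#' 10 genetic principal components. On a cohort where genotypes are
#' independent of metabolic traits the odds ratio should be compatible
#' with 1.
#'
#' @inheritParams fit_cox
#' @return One-row tibble: `or` (per SD), `conf.low`, `conf.high`,
#'   `p.value`, `separation` flag.
#' @export
logistic_prs_on_mets <- function(records, adjustment = "model2", pcs = TRUE) {
  y <- as.numeric(records$mets)
  if (all(y == 0) || all(y == 1))
    abort("MetS status is constant; logistic model is degenerate.")
  rhs <- build_rhs(records, c("gi_prs_z",
                              adjustment_covariates(adjustment, pcs)))
  dat <- records[, rhs, drop = FALSE]
  dat$.y <- y
  fit <- suppressWarnings(
    glm(as.formula(paste(".y ~", paste(rhs, collapse = " + "))),
        data = dat, family = binomial()))
  b <- coef(fit)["gi_prs_z"]
  se <- sqrt(vcov(fit)["gi_prs_z", "gi_prs_z"])
  tibble(or = exp(unname(b)),
         conf.low = exp(unname(b) - 1.96 * se),
         conf.high = exp(unname(b) + 1.96 * se),
         p.value = 2 * pnorm(-abs(unname(b) / se)),
         separation = !fit$converged || abs(unname(b)) > 10)
}

#' Restricted cubic spline basis (truncated power form)
#'
#' Harrell's parameterization: the first column is the raw value; columns
#' 2 .. k-1 are the normalized truncated cubic terms, linear beyond the
#' boundary knots.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing knot locations (length >= 3).
#' @return Matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3L || any(diff(knots) <= 0))
    abort("`knots` must be strictly increasing with at least 3 values.")
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm <- (tk - t1)^2
  pp <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    B[, j + 1] <- (pp(x - tj) - pp(x - tk1) * (tk - tj) / (tk - tk1) +
                     pp(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(B) <- paste0("rcs", seq_len(k - 1))
  B
}

#' Dose-response of the composite score by restricted cubic spline
#'
#' Models the continuous standardized score with a restricted cubic spline
#' (default 4 knots at the 5th/35th/65th/95th percentiles) in the adjusted
#' Cox model, reports the pointwise hazard-ratio curve referenced at the
#' cohort median score (HR = 1 there exactly), and the joint Wald test of
#' the nonlinear terms.
#'
#' @inheritParams fit_cox
#' @param score Column name of the continuous score.
#' @param knots Knot locations; `NULL` uses the percentile defaults.
#' @param grid_length Number of curve evaluation points.
#' @return An object of class `rcs_fit`: list with `curve` (tibble `score`,
#'   `hr`, `conf.low`, `conf.high`), `p_nonlinear`, `knots`, `ref`.
#' @export
rcs_dose_response <- function(records, score = "gi_prs_z", knots = NULL,
                              adjustment = "model2", pcs = TRUE,
                              outcome = "GI", grid_length = 100L) {
  x <- records[[score]]
  if (is.null(knots))
    knots <- unname(quantile(x, c(0.05, 0.35, 0.65, 0.95)))
  if (any(diff(knots) <= 0)) abort("`knots` must be strictly increasing.")
  B <- rcs_basis(x, knots)
  records <- bind_cols(records, as_tibble(B))
  f <- fit_cox(records, colnames(B), adjustment, pcs, outcome)
  idx <- match(colnames(B), names(coef(f$fit)))
  b <- coef(f$fit)[idx]
  V <- vcov(f$fit)[idx, idx, drop = FALSE]
  ref <- median(x)
  gx <- seq(quantile(x, 0.01), quantile(x, 0.99), length.out = grid_length)
  D <- rcs_basis(gx, knots) -
    matrix(rcs_basis(ref, knots), grid_length, ncol(B), byrow = TRUE)
  lhr <- drop(D %*% b)
  se <- sqrt(rowSums((D %*% V) * D))
  nl <- wald_joint(f$fit, idx[-1])
  structure(list(curve = tibble(score = gx, hr = exp(lhr),
                                conf.low = exp(lhr - 1.96 * se),
                                conf.high = exp(lhr + 1.96 * se)),
                 p_nonlinear = nl$p.value, knots = knots, ref = ref,
                 fit = f),
            class = "rcs_fit")
}

#' @export
print.rcs_fit <- function(x, ...) {
  cat("<rcs_fit>", length(x$knots), "knots; nonlinearity p =",
      format.pval(x$p_nonlinear), "\n")
  invisible(x)
}

#' @rdname tidy.cox_fit
#' @exportS3Method generics::tidy
tidy.rcs_fit <- function(x, ...) x$curve

#' @rdname tidy.cox_fit
#' @exportS3Method generics::glance
glance.rcs_fit <- function(x, ...)
  tibble(p_nonlinear = x$p_nonlinear, n_knots = length(x$knots), ref = x$ref)

#' Subgroup analysis with heterogeneity test
#'
#' Fits the adjusted model within each level of a stratifier and summarizes
#' effect heterogeneity by the joint Wald test of the exposure-by-stratifier
#' interaction. Strata with zero events (or too few to fit) are reported as
#' non-estimable rather than failing the whole analysis.
#'
#' @inheritParams fit_cox
#' @param stratifier Column name with at least 2 non-empty levels.
#' @param exposure A single binary/numeric exposure column (default MetS).
#' @return List with `strata` (tibble: level, n, events, hr, conf.low,
#'   conf.high, p.value) and `p_heterogeneity`.
#' @export
subgroup_analysis <- function(records, stratifier, exposure = "mets",
                              adjustment = "model2", pcs = FALSE,
                              outcome = "GI") {
  s <- records[[stratifier]]
  lv <- if (is.factor(s)) levels(droplevels(s)) else sort(unique(s))
  if (length(lv) < 2L)
    abort(paste0("Stratifier `", stratifier, "` has fewer than 2 levels."))
  records$.x <- as.numeric(records[[exposure]])
  rows <- purrr::map(lv, function(l) {
    d <- records[s == l, , drop = FALSE]
    res <- tryCatch({
      f <- fit_cox(d, ".x", adjustment, pcs, outcome)
      t1 <- f$terms[f$terms$term == ".x", ]
      tibble(level = as.character(l), n = f$n, events = f$n_events,
             hr = t1$hr, conf.low = t1$conf.low, conf.high = t1$conf.high,
             p.value = t1$p.value)
    }, error = function(e)
      tibble(level = as.character(l), n = nrow(d),
             events = sum(outcome_columns(d, outcome)$event),
             hr = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
             p.value = NA_real_))
    res
  }) |> list_rbind()
  het <- tryCatch({
    records$.s <- factor(s, levels = lv)
    ints <- paste0(".int", seq_len(length(lv) - 1))
    M <- vapply(lv[-1], function(l) records$.x * (records$.s == l),
                numeric(nrow(records)))
    if (is.null(dim(M))) M <- matrix(M, nrow = nrow(records))
    colnames(M) <- ints
    records <- bind_cols(records, as_tibble(M))
    f <- fit_cox(records, c(".x", ".s", ints), adjustment, pcs, outcome)
    wald_joint(f$fit, match(ints, names(coef(f$fit))))$p.value
  }, error = function(e) NA_real_)
  list(strata = rows, p_heterogeneity = het)
}
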