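# Shared fixtures and independent oracles used across test files.

small_config <- function(n = 5000, hazard = 0.003, ...) {
  scenario_config(n_participants = n, baseline_hazard = hazard, ...)
}

# a minimal participant table with complete metabolic fields
make_records <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("p%05d", seq_len(n)),
    sex = sample(c("male", "female"), n, TRUE),
    waist = runif(n, 60, 130),
    bmi = runif(n, 18, 40),
    sbp = runif(n, 100, 180),
    dbp = runif(n, 60, 110),
    tg = runif(n, 0.5, 4),
    hdl = runif(n, 0.6, 2.5),
    hba1c = runif(n, 25, 60)
  )
}

# Exact Cox partial likelihood (Breslow form; valid with distinct event
# times) evaluated by direct enumeration of risk sets -- the brute-force
# oracle for small datasets.
brute_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1L)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

brute_cox_coef <- function(time, event, x) {
  stats::optimize(function(b) -brute_partial_loglik(b, time, event, x),
                  c(-8, 8), tol = 1e-9)$minimum
}

# Independent (matrix-based) implementation of greedy lowest-p clumping,
# used as the reference for panels of up to a dozen variants.
oracle_clump <- function(p, pos, R2, threshold = 0.2) {
  remaining <- order(p, pos)
  kept <- integer()
  while (length(remaining)) {
    idx <- remaining[1]
    kept <- c(kept, idx)
    remaining <- remaining[-1]
    remaining <- remaining[R2[idx, remaining] < threshold]
  }
  sort(kept)
}

# variant tibble builder for PRS tests
variant_row <- function(id, ea = "A", oa = "G", beta = 0.1, p = 1e-10,
                        maf = 0.3, site = "CRC", pos = 1000,
                        status = "pass") {
  tibble::tibble(variant_id = id, chr = "1", pos = pos,
                 effect_allele = ea, other_allele = oa, beta = beta, p = p,
                 maf_gwas = maf, maf_ref = maf, site = site,
                 qc_status = status)
}

# small survival datasets for oracle checks
surv_data <- function(n, seed, binary = TRUE, censor = FALSE) {
  set.seed(seed)
  x <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
  t <- rexp(n, 0.2 * exp(0.5 * x))
  ev <- rep(1L, n)
  if (censor) {
    cens <- runif(n, 0, 8)
    ev <- as.integer(t <= cens)
    t <- pmin(t, cens)
  }
  tibble::tibble(time = t, event = ev, site = NA_character_, x = x)
}
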