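# hand-written Cox partial log-likelihood for untied data (oracle)
partial_loglik <- function(b, times, events, x) {
  o <- order(times)
  times <- times[o]; events <- events[o]; x <- x[o]
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- which(times >= times[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
  }
  ll
}

test_that("per-SNP Cox matches a brute-force partial-likelihood maximizer", {
  toy <- toy_survival(times = c(1, 2, 3, 4), events = rep(1L, 4),
                      dosages = c(1, 0, 1, 0))
  est <- fit_cox_per_snp(toy$cohort, toy$genotypes, "rs001", stage = 1L,
                         ph_check = FALSE)
  oracle <- optimize(function(b) partial_loglik(b, toy$cohort$followup_years,
                                                toy$cohort$event,
                                                toy$genotypes[, 1]),
                     c(-5, 5), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(est$log_hr, oracle, tolerance = 1e-4)
})

test_that("null dosages give nominal type-I error for the Cox z-test", {
  hits <- vapply(1:150, function(i) {
    d <- with_seed_test(1000L + i, {
      n <- 800
      data.frame(followup_years = rexp(n, 0.1), event = rbinom(n, 1, 0.4),
                 dosage = rbinom(n, 2, 0.3))
    })
    g <- matrix(d$dosage, ncol = 1, dimnames = list(NULL, "rs001"))
    abs(fit_cox_per_snp(d, g, "rs001", ph_check = FALSE)$z) < 1.96
  }, logical(1))
  expect_true(mean(hits) > 0.90 && mean(hits) <= 1)
})

test_that("the Cox CI covers a true per-allele log hazard ratio", {
  covered <- vapply(1:120, function(i) {
    d <- with_seed_test(2000L + i, {
      n <- 2000
      dos <- rbinom(n, 2, 0.3)
      t_ev <- rexp(n, 0.05 * exp(0.2 * dos))
      cens <- runif(n, 5, 15)
      data.frame(followup_years = pmin(t_ev, cens),
                 event = as.integer(t_ev <= cens), dosage = dos)
    })
    g <- matrix(d$dosage, ncol = 1, dimnames = list(NULL, "rs001"))
    est <- fit_cox_per_snp(d, g, "rs001", ph_check = FALSE)
    est$log_hr - 1.96 * est$se <= 0.2 && est$log_hr + 1.96 * est$se >= 0.2
  }, logical(1))
  expect_gt(mean(covered), 0.89)
})

test_that("stage-2 adjustment with pure-noise covariates agrees with stage 1", {
  sim <- simulate_cohort(sim_config(n_individuals = 4000L, n_variants = 6L,
                                    n_binary_variants = 0L,
                                    baseline_hazard = 0.012, seed = 23L))
  s1 <- snp_outcome_scan(sim$cohort, sim$genotypes, sim$variants, stage = 1,
                         by_substudy = FALSE)
  s2 <- snp_outcome_scan(sim$cohort, sim$genotypes, sim$variants, stage = 2,
                         by_substudy = FALSE)
  expect_equal(s1$log_hr, s2$log_hr, tolerance = 0.25)
  expect_lt(max(abs(s1$log_hr - s2$log_hr) / s1$se), 0.8)
})

test_that("separation is flagged with an infinite-SE sentinel, not an error", {
  # dosage perfectly separates events from censorings
  d <- data.frame(followup_years = c(1:5, 6:10),
                  event = c(rep(1L, 5), rep(0L, 5)))
  g <- matrix(c(rep(2, 5), rep(0, 5)), ncol = 1,
              dimnames = list(NULL, "rs001"))
  est <- fit_cox_per_snp(d, g, "rs001", ph_check = FALSE)
  expect_true(est$flagged)
  expect_true(is.infinite(est$se))
  expect_error(fit_cox_per_snp(d[d$event == 0, ], g[d$event == 0, , drop = FALSE],
                               "rs001"), "no events")
})

test_that("Schoenfeld diagnostic is the Pearson correlation with time rank", {
  d <- toy_survival(times = c(1, 2, 3, 4, 5, 6),
                    events = c(1L, 1L, 1L, 0L, 1L, 0L),
                    dosages = c(2, 0, 1, 1, 0, 2))
  fit <- survival::coxph(survival::Surv(followup_years, event) ~ dosage,
                         data = transform(d$cohort, dosage = d$genotypes[, 1]))
  ph <- check_proportional_hazards(fit, term = "dosage")
  res <- as.matrix(residuals(fit, type = "scaledsch"))
  tt <- as.numeric(rownames(res))
  r <- as.numeric(res[, 1])
  # hand-computed Pearson correlation against the rank of event times
  x <- rank(tt); y <- r
  rho_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(ph["rho"]), rho_hand, tolerance = 1e-12)
})

test_that("the PH diagnostic has correct size under proportional hazards", {
  pvals <- vapply(1:200, function(i) {
    d <- with_seed_test(3000L + i, {
      n <- 300
      dos <- rbinom(n, 2, 0.3)
      t_ev <- rexp(n, 0.08 * exp(0.3 * dos))
      data.frame(followup_years = pmin(t_ev, 12),
                 event = as.integer(t_ev <= 12), dosage = dos)
    })
    g <- matrix(d$dosage, ncol = 1, dimnames = list(NULL, "rs001"))
    fit_cox_per_snp(d, g, "rs001")$schoenfeld_p
  }, numeric(1))
  frac <- mean(pvals < 0.05, na.rm = TRUE)
  expect_true(frac >= 0.02 && frac <= 0.09)
})

test_that("the PH diagnostic detects a sign-reversing effect", {
  d <- simulate_nonph_cohort(2000L, beta = 0.5, seed = 71L)
  g <- matrix(d$x, ncol = 1, dimnames = list(NULL, "rs001"))
  d$x <- NULL
  est <- fit_cox_per_snp(d, g, "rs001")
  expect_lt(est$schoenfeld_p, 0.05)
})

test_that("fixed-effect pooling follows inverse-variance algebra", {
  one <- data.frame(log_hr = 0.12, se = 0.3)
  expect_equal(fixed_effect_meta(one)$log_hr, 0.12)
  expect_equal(fixed_effect_meta(one)$se, 0.3)
  two <- data.frame(log_hr = c(0.1, 0.3), se = c(0.1, 0.1))
  pooled <- fixed_effect_meta(two)
  expect_equal(pooled$log_hr, 0.2)
  expect_equal(pooled$se, sqrt(1 / 200), tolerance = 1e-12)
  expect_lte(pooled$se, min(two$se))
  # permutation invariance and scale equivariance
  expect_equal(fixed_effect_meta(two[2:1, ]), pooled)
  scaled <- fixed_effect_meta(transform(two, log_hr = 3 * log_hr, se = 3 * se))
  expect_equal(scaled$log_hr, 3 * pooled$log_hr)
  expect_equal(scaled$se, 3 * pooled$se)
  # flagged estimates are excluded; empty input errors
  fl <- rbind(two, data.frame(log_hr = 5, se = Inf))
  expect_equal(fixed_effect_meta(fl)$log_hr, 0.2)
  expect_error(fixed_effect_meta(two[0, ]), "no usable")
})

test_that("sub-study pooling skips unusable strata and pools the rest", {
  sim <- simulate_cohort(sim_config(n_individuals = 2500L, n_variants = 3L,
                                    n_binary_variants = 0L, n_substudies = 3L,
                                    baseline_hazard = 0.012, seed = 29L))
  scan <- snp_outcome_scan(sim$cohort, sim$genotypes, sim$variants, stage = 1)
  expect_equal(nrow(scan), 3L)
  expect_true(all(scan$n_studies >= 1 & scan$n_studies <= 3))
  expect_true(all(scan$se > 0))
})
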