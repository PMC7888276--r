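test_that("Wald ratios follow their closed forms", {
  r <- wald_ratio(0.25, 0.01, 0.05, 0.02)
  expect_equal(r$ratio, 0.2)
  expect_equal(r$se_ratio, 0.08)
  expect_equal(r$weight, 1 / 0.08^2)
  expect_equal(wald_ratio(0.25, 0.01, 0, 0.02)$ratio, 0)
  r1 <- wald_ratio(c(0.2, -0.3), c(0.02, 0.02), c(0.1, 0.1), c(0.05, 0.05))
  r2 <- wald_ratio(c(0.2, -0.3), c(0.02, 0.02), c(0.1, 0.1), c(0.05, 0.05),
                   order = "second")
  expect_true(all(r2$se_ratio >= r1$se_ratio))
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "zeros")
})

test_that("IVW equals the hand-computed weighted mean and is scale stable", {
  single <- wald_ratio(0.2, 0.01, 0.04, 0.03)
  expect_equal(mr_ivw(single)$estimate, single$ratio)
  expect_equal(mr_ivw(single)$se, single$se_ratio)
  two <- data.frame(variant_id = c("a", "b"), ratio = c(0.2, 0.4),
                    se_ratio = c(0.1, 0.1), weight = c(100, 100))
  fit <- mr_ivw(two)
  expect_equal(fit$estimate, 0.3)
  expect_equal(fit$se, sqrt(1 / 200), tolerance = 1e-12)
  # common rescaling of the weights leaves the estimate unchanged
  two_scaled <- transform(two, weight = weight * 7)
  expect_equal(mr_ivw(two_scaled)$estimate, fit$estimate)
})

test_that("IVW equals weighted least squares through the origin on any input", {
  set.seed(41)
  for (i in 1:5) {
    J <- sample(3:30, 1)
    g <- runif(J, 0.05, 0.5)
    G <- rnorm(J, 0.2 * g, 0.05)
    seG <- runif(J, 0.02, 0.1)
    ratios <- wald_ratio(g, rep(0.01, J), G, seG)
    wls <- lm(G ~ g - 1, weights = 1 / seG^2)
    expect_equal(mr_ivw(ratios)$estimate, unname(coef(wls)), tolerance = 1e-10)
  }
})

test_that("the weighted median interpolates cumulative weight at one half", {
  eq <- data.frame(ratio = c(0.1, 0.2, 0.3), se_ratio = rep(0.1, 3),
                   weight = rep(1, 3))
  expect_equal(mr_weighted_median(eq, boot_reps = 0)$estimate, 0.2)
  same <- data.frame(ratio = rep(0.25, 4), se_ratio = rep(0.05, 4),
                     weight = c(1, 2, 3, 4))
  expect_equal(mr_weighted_median(same, boot_reps = 0)$estimate, 0.25)
  # unequal weights against the independent cumulative-weight walk
  set.seed(43)
  for (i in 1:20) {
    J <- sample(2:12, 1)
    r <- data.frame(ratio = rnorm(J), se_ratio = runif(J, 0.01, 0.2))
    r$weight <- 1 / r$se_ratio^2
    expect_equal(mr_weighted_median(r, boot_reps = 0)$estimate,
                 wm_walk_oracle(r$ratio, r$weight), tolerance = 1e-12)
  }
  expect_error(mr_weighted_median(eq[1, , drop = FALSE]), ">= 2")
})

test_that("weighted-median results are order invariant and seed reproducible", {
  set.seed(44)
  r <- data.frame(ratio = rnorm(8, 0.2, 0.1), se_ratio = runif(8, 0.05, 0.2))
  r$weight <- 1 / r$se_ratio^2
  a <- mr_weighted_median(r, boot_reps = 300, seed = 5)
  b <- mr_weighted_median(r[sample(8), ], boot_reps = 300, seed = 5)
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$se, b$se)
  c2 <- mr_weighted_median(r, boot_reps = 300, seed = 5)
  expect_identical(a$se, c2$se)
})

test_that("penalization leaves homogeneous ratios untouched and tames outliers", {
  # homogeneous: every q_j tiny, penalty inactive -> PWM == WM exactly
  hom <- data.frame(ratio = c(0.19, 0.2, 0.21, 0.2), se_ratio = rep(0.1, 4))
  hom$weight <- 1 / hom$se_ratio^2
  expect_equal(mr_penalized_weighted_median(hom, boot_reps = 0)$estimate,
               mr_weighted_median(hom, boot_reps = 0)$estimate)
  # penalty constant -> infinity reduces PWM to WM on any input
  set.seed(45)
  r <- data.frame(ratio = rnorm(10, 0.2, 0.3), se_ratio = runif(10, 0.02, 0.1))
  r$weight <- 1 / r$se_ratio^2
  expect_equal(mr_penalized_weighted_median(r, penalty_constant = Inf,
                                            boot_reps = 0)$estimate,
               mr_weighted_median(r, boot_reps = 0)$estimate)
  # one extreme outlier among concordant ratios: PWM beats IVW
  err_pwm <- err_ivw <- numeric(30)
  for (i in 1:30) {
    rr <- with_seed_test(500L + i, {
      d <- data.frame(ratio = rnorm(10, 0.2, 0.02),
                      se_ratio = rep(0.02, 10))
      d$ratio[1] <- 1.5
      d$weight <- 1 / d$se_ratio^2
      d
    })
    err_pwm[i] <- abs(mr_penalized_weighted_median(rr, boot_reps = 0)$estimate - 0.2)
    err_ivw[i] <- abs(mr_ivw(rr)$estimate - 0.2)
  }
  expect_true(all(err_pwm < err_ivw))
})

test_that("MR-Egger recovers an exact line and collapses to IVW through origin", {
  g <- c(0.2, 0.4, 0.6); G <- c(0.1, 0.2, 0.3)
  fit <- mr_egger(g, G, rep(0.05, 3))
  expect_equal(fit$slope$estimate, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept$estimate, 0, tolerance = 1e-12)
  # through-origin check mode equals IVW with the same weights
  set.seed(46)
  g2 <- runif(8, 0.1, 0.5); G2 <- rnorm(8, 0.2 * g2, 0.03)
  seG <- runif(8, 0.02, 0.08)
  no_int <- mr_egger(g2, G2, seG, intercept = FALSE)
  ivw <- mr_ivw(wald_ratio(g2, rep(0.01, 8), G2, seG))
  expect_equal(no_int$slope$estimate, ivw$estimate, tolerance = 1e-10)
  expect_error(mr_egger(g[1:2], G[1:2], rep(0.05, 2)), ">= 3")
})

test_that("the Egger intercept test has uniform p-values under balanced pleiotropy", {
  pvals <- vapply(1:200, function(i) {
    with_seed_test(6000L + i, {
      J <- 30
      g <- runif(J, 0.1, 0.5)
      alpha <- rnorm(J, 0, 0.02)          # balanced: mean-zero pleiotropy
      seG <- rep(0.03, J)
      G <- rnorm(J, 0.2 * g + alpha, seG)
      mr_egger(g, G, sqrt(seG^2 + 0.02^2))$intercept$p
    })
  }, numeric(1))
  expect_true(mean(pvals < 0.05) >= 0.01 && mean(pvals < 0.05) <= 0.10)
  expect_true(abs(mean(pvals) - 0.5) < 0.08)
})

test_that("Cochran's Q matches hand arithmetic and is permutation invariant", {
  eq <- data.frame(ratio = rep(0.3, 5), se_ratio = runif(5, 0.01, 0.1))
  eq$weight <- 1 / eq$se_ratio^2
  q <- cochran_q(eq)
  expect_equal(q$Q, 0)
  expect_equal(q$p, 1)
  two <- data.frame(ratio = c(0.2, 0.4), se_ratio = c(0.1, 0.1),
                    weight = c(100, 100))
  expect_equal(cochran_q(two)$Q, 2)
  set.seed(47)
  r <- data.frame(ratio = rnorm(9), se_ratio = runif(9, 0.05, 0.2))
  r$weight <- 1 / r$se_ratio^2
  expect_equal(cochran_q(r)$Q, cochran_q(r[sample(9), ])$Q)
  expect_error(cochran_q(two[1, , drop = FALSE]), ">= 2")
})

test_that("hazard-ratio reporting is the exponential map with 1.96-SE bounds", {
  expect_equal(report_hr(0, 0.1)$hr, 1)
  round_trip <- report_hr(-0.248, 0.203)
  expect_equal(round(round_trip$hr, 2), 0.78)
  expect_equal(round(round_trip$hr_low, 2), 0.52)
  expect_equal(round(round_trip$hr_high, 2), 1.16)
  wide <- report_hr(0.1, 0.3); narrow <- report_hr(0.1, 0.1)
  expect_gt(wide$hr_high / wide$hr_low, narrow$hr_high / narrow$hr_low)
})

test_that("mr_fit exposes the modelling interface consistently", {
  set.seed(48)
  g <- runif(10, 0.1, 0.4); seG <- rep(0.04, 10)
  G <- rnorm(10, 0.25 * g, seG)
  fit <- mr_fit(g, rep(0.01, 10), G, seG, boot_reps = 200, seed = 3)
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit),
               c("ivw", "wm", "pwm", "egger_slope", "egger_intercept"))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  expect_equal(unname(coef(fit)["ivw"]), fit$results$ivw$estimate)
  expect_equal(fit$results$ivw$hr, exp(fit$results$ivw$estimate))
  fit2 <- mr_fit(g, rep(0.01, 10), G, seG, boot_reps = 200, seed = 3)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$results$wm$se, fit2$results$wm$se)
  out <- capture.output(print(fit))
  expect_true(any(grepl("IVW", out)))
  s <- summary(fit)
  expect_s3_class(s$table, "data.frame")
})
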