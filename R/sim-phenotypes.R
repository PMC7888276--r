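#' Simulate phenotypes, lifestyle covariates and sub-study labels
#'
#' Builds the individual-level table the downstream Cox models expect.
#' log CRP is the additive genetic value `sum_j beta_j g_ij` plus Gaussian
#' noise whose SD is chosen so the variance fraction explained by the
#' instruments equals `target_r2` (override with `config$noise_sd`); CRP in
#' mg/L is its exponential and the binary chronic-inflammation indicator is
#' `crp_mgL > 3.0` exactly. Lifestyle covariates are drawn from documented
#' marginal distributions chosen for plausibility in a postmenopausal
#' cohort (see the methods vignette); none of them depends on genotype, so
#' by construction they are pure noise with respect to the exposure.
#'
#' @param genotypes dosage matrix from [simulate_genotypes()].
#' @param truth ground-truth list from [simulate_variants()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data.frame with one row per individual: identifiers, substudy,
#'   age, pc1..pc10, the 15 lifestyle/demographic covariates, log_crp,
#'   crp_mgL and the inflammation indicator.
#' @export
simulate_phenotypes <- function(genotypes, truth, config,
                                seed = config$seed + 1L) {
  beta <- truth$per_variant_exposure_betas
  if (!all(names(beta) %in% colnames(genotypes)))
    stop_bad_arg("genotype matrix does not cover all variants in truth")
  n <- nrow(genotypes)
  gvalue <- as.numeric(genotypes[, names(beta), drop = FALSE] %*% beta)
  noise_sd <- config$noise_sd %||%
    sqrt(config$sd_log_crp^2 * (1 - config$target_r2))
  with_seed(seed, {
    log_crp <- config$mean_log_crp + (gvalue - mean(gvalue)) +
      rnorm(n, 0, noise_sd)
    pcs <- matrix(rnorm(n * 10L), n, 10L,
                  dimnames = list(NULL, paste0("pc", 1:10)))
    bmi <- exp(rnorm(n, log(28) - 0.18^2 / 2, 0.18))
    hip <- rnorm(n, 105, 8)
    whr <- pmax(0.6, pmin(1.1, rnorm(n, 0.84, 0.07)))
    height <- rnorm(n, 162, 6)
    drinks <- runif(n) < 0.60
    smokes <- runif(n) < 0.12
    uses_e <- runif(n) < 0.35
    uses_ep <- runif(n) < 0.30
    uses_oc <- runif(n) < 0.45
    cohort <- data.frame(
      individual_id = sprintf("id%06d", seq_len(n)),
      substudy = paste0("S", sample.int(config$n_substudies, n, replace = TRUE)),
      age = runif(n, 50, 79),
      pcs,
      education = sample.int(5L, n, replace = TRUE),
      income = sample.int(8L, n, replace = TRUE),
      family_history = as.integer(runif(n) < 0.12),
      cesd = rbeta(n, 1.2, 18),                       # mean ~0.062 on 0-1 scale
      cigarettes_day = ifelse(smokes, pmax(1, round(rnorm(n, 15, 8))), 0),
      met_hr_wk = rgamma(n, shape = 1.4, scale = 9),
      alcohol_g_day = ifelse(drinks, rexp(n, 1 / 8), 0),
      sfa_pct = pmax(2, rnorm(n, 9.5, 2.5)),
      age_menopause = rnorm(n, 50, 3.5),
      oc_yrs = ifelse(uses_oc, rexp(n, 1 / 5), 0),
      e_only_yrs = ifelse(uses_e, rexp(n, 1 / 6), 0),
      e_p_yrs = ifelse(uses_ep, rexp(n, 1 / 6), 0),
      height = height,
      weight = bmi * (height / 100)^2,
      hip = hip,
      waist = whr * hip,
      bmi = bmi,
      whr = whr,
      log_crp = log_crp,
      crp_mgL = exp(log_crp),
      stringsAsFactors = FALSE
    )
    cohort$inflammation <- as.integer(cohort$crp_mgL > 3.0)
    cohort
  })
}

# exponential loss-to-follow-up rate implied by the configured probability
# that loss happens after the administrative horizon C ~ U(a, b):
# P(L > C) = E[exp(-r C)] = (exp(-a r) - exp(-b r)) / ((b - a) r)
loss_rate_from_fraction <- function(frac, a, b) {
  if (frac >= 1) return(0)
  f <- function(r) {
    if (r < 1e-12) return(1 - frac)
    if (b > a) (exp(-a * r) - exp(-b * r)) / ((b - a) * r) - frac
    else exp(-a * r) - frac
  }
  uniroot(f, c(1e-10, 5), tol = 1e-10)$root
}

#' Simulate time-to-event outcomes and molecular subtype labels
#'
#' Event times follow a cause-specific proportional-hazards model with
#' exponential baseline: the linear predictor is `theta * (log_crp - mean)`
#' where `theta` is optionally modified multiplicatively within bins of a
#' configured covariate (`config$modifier_effects`) and may differ between
#' the ER/PR-positive and ER/PR-negative cause-specific hazards
#' (`config$subtype$theta_erpr`). Follow-up is the minimum of the event
#' time, an administrative censoring time Uniform(horizon - entry spread,
#' horizon) reflecting staggered enrolment, and an exponential
#' loss-to-follow-up time whose rate is solved from
#' `admin_censor_fraction`. Events receive ER/PR labels from the generating
#' cause and independent HER2 labels; non-events carry missing labels.
#'
#' @param cohort data.frame from [simulate_phenotypes()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return `cohort` with columns followup_years, event, erpr_status,
#'   her2_status appended.
#' @export
simulate_outcomes <- function(cohort, config, seed = config$seed + 2L) {
  if (config$baseline_hazard < 0) stop_bad_arg("baseline_hazard must be >= 0")
  n <- nrow(cohort)
  z <- cohort$log_crp - mean(cohort$log_crp)
  theta <- rep(config$causal_effect_theta, n)
  me <- config$modifier_effects
  if (!is.null(me)) {
    bin <- cut(cohort[[me$variable]], c(-Inf, me$breaks, Inf), right = FALSE)
    theta <- theta * me$multipliers[as.integer(bin)]
  }
  st <- config$subtype
  with_seed(seed, {
    h_pos <- config$baseline_hazard * st$erpr_pos_prob *
      exp(theta * st$theta_erpr[["pos"]] * z)
    h_neg <- config$baseline_hazard * (1 - st$erpr_pos_prob) *
      exp(theta * st$theta_erpr[["neg"]] * z)
    h_tot <- h_pos + h_neg
    t_event <- ifelse(h_tot > 0, rexp(n, pmax(h_tot, 1e-300)), Inf)
    a <- config$max_followup_years - config$entry_spread_years
    c_admin <- runif(n, a, config$max_followup_years)
    r_loss <- loss_rate_from_fraction(config$admin_censor_fraction,
                                      a, config$max_followup_years)
    t_loss <- if (r_loss > 0) rexp(n, r_loss) else rep(Inf, n)
    followup <- pmin(t_event, c_admin, t_loss)
    event <- as.integer(t_event <= pmin(c_admin, t_loss))
    erpr <- rep(NA_character_, n)
    her2 <- rep(NA_character_, n)
    is_ev <- event == 1L
    if (any(is_ev)) {
      p_pos <- h_pos[is_ev] / h_tot[is_ev]
      erpr[is_ev] <- ifelse(runif(sum(is_ev)) < p_pos, "positive", "negative")
      her2[is_ev] <- ifelse(runif(sum(is_ev)) < st$her2_pos_prob,
                            "positive", "negative")
    }
    cohort$followup_years <- followup
    cohort$event <- event
    cohort$erpr_status <- erpr
    cohort$her2_status <- her2
    cohort
  })
}

#' Simulate a complete analysis-ready cohort
#'
#' Convenience wrapper chaining [simulate_variants()],
#' [simulate_genotypes()], [simulate_phenotypes()] and
#' [simulate_outcomes()] under seeds derived from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `variants`, `truth`, `genotypes`, `cohort`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  v <- simulate_variants(config)
  g <- simulate_genotypes(v$variants, config$n_individuals,
                          seed = config$seed + 10L)
  ph <- simulate_phenotypes(g, v$truth, config, seed = config$seed + 20L)
  ph <- simulate_outcomes(ph, config, seed = config$seed + 30L)
  list(variants = v$variants, truth = v$truth, genotypes = g,
       cohort = ph, config = config)
}

#' Simulate a cohort violating proportional hazards
#'
#' A single standard-normal covariate whose log hazard ratio is `+beta`
#' before `t_change` and `-beta` after it (two-piece exponential via
#' inversion). Used to check the power of the Schoenfeld diagnostic.
#'
#' @param n sample size.
#' @param beta covariate log hazard ratio before the change point.
#' @param t_change time at which the effect reverses sign.
#' @param baseline_hazard events per unit time at x = 0.
#' @param censor_time administrative censoring time.
#' @param seed RNG seed.
#' @return data.frame with x, followup_years, event.
#' @export
simulate_nonph_cohort <- function(n, beta = 0.5, t_change = NULL,
                                  baseline_hazard = 0.1,
                                  censor_time = 20, seed = 1L) {
  t_change <- t_change %||% (censor_time / 2)
  with_seed(seed, {
    x <- rnorm(n)
    u <- -log(runif(n))                      # target cumulative hazard
    h1 <- baseline_hazard * exp(beta * x)
    h2 <- baseline_hazard * exp(-beta * x)
    t1 <- u / h1
    t <- ifelse(t1 <= t_change, t1, t_change + (u - h1 * t_change) / h2)
    data.frame(x = x,
               followup_years = pmin(t, censor_time),
               event = as.integer(t <= censor_time))
  })
}
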