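#' Configuration of the synthetic survival-cohort simulator
#'
#' Collects every tunable of the cohort generator in one validated list.
#' The defaults emulate the cohort the analysis is designed for: a large
#' postmenopausal cohort (n = 10,179) with 61 independent CRP-raising
#' variants jointly explaining ~6% of the variance of log CRP, five
#' genotyping sub-studies, ~5% cumulative incidence of invasive breast
#' cancer over a mean 16 years of follow-up, and effect modification /
#' pleiotropy structure switched off unless requested.
#'
#' @param n_individuals cohort size.
#' @param n_variants number of genetic instruments.
#' @param n_binary_variants how many instruments are reported on the
#'   binary (log-odds of CRP > 3 mg/L) exposure scale; the remainder are on
#'   the natural-log continuous scale. Capped at `n_variants`.
#' @param maf_range range of effect-allele frequencies, inside (0, 1).
#' @param target_r2 fraction of log-CRP variance jointly explained by the
#'   instruments, in [0, 1).
#' @param causal_effect_theta true causal log hazard ratio per unit log CRP
#'   (the estimand every MR estimator must recover).
#' @param baseline_hazard events per person-year at the mean exposure
#'   (exponential baseline). Default calibrated so that, with the other
#'   defaults, cumulative incidence is ~5%.
#' @param max_followup_years administrative horizon from first enrolment.
#' @param entry_spread_years enrolment is uniform over this many years, so
#'   administrative censoring times are
#'   Uniform(max_followup_years - entry_spread_years, max_followup_years).
#' @param admin_censor_fraction probability that a subject's random
#'   loss-to-follow-up time exceeds the administrative horizon; the implied
#'   exponential loss rate is solved internally. Default calibrated so the
#'   mean follow-up is ~16 years.
#' @param n_substudies number of genotyping sub-studies (>= 1).
#' @param modifier_effects optional effect modification: a list with
#'   elements `variable` (cohort column), `breaks` (cut points, strictly
#'   increasing) and `multipliers` (one per bin) multiplying theta within
#'   each bin of the variable.
#' @param subtype list with `erpr_pos_prob`, `her2_pos_prob` (marginal
#'   probabilities of an event being ER/PR-positive resp. HER2-positive)
#'   and `theta_erpr` = c(pos =, neg =) multipliers of theta for the two
#'   cause-specific ER/PR hazards (both 1 by default, i.e. subtype labels
#'   independent of the exposure).
#' @param invalid_fraction share of total inverse-variance weight carried
#'   by directionally pleiotropic instruments in the two-sample generator.
#' @param pleiotropy_shift additive shift on the SNP-outcome effect of an
#'   invalid instrument.
#' @param mean_log_crp,sd_log_crp marginal mean and SD of log CRP (mg/L);
#'   defaults give ~30% prevalence of CRP > 3 mg/L.
#' @param noise_sd optional override of the environmental SD of log CRP;
#'   default `NULL` means `sqrt(sd_log_crp^2 - genetic variance)` so the
#'   realized variance fraction equals `target_r2`.
#' @param sumstats_exposure_n,sumstats_outcome_events effective sample
#'   sizes behind the simulated two-sample summary statistics (exposure
#'   GWAS individuals; outcome study effective events).
#' @param seed integer RNG seed.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 10179L,
                       n_variants = 61L,
                       n_binary_variants = 5L,
                       maf_range = c(0.05, 0.5),
                       target_r2 = 0.06,
                       causal_effect_theta = 0.2,
                       baseline_hazard = 0.0031,
                       max_followup_years = 21,
                       entry_spread_years = 5,
                       admin_censor_fraction = 0.786,
                       n_substudies = 5L,
                       modifier_effects = NULL,
                       subtype = list(),
                       invalid_fraction = 0,
                       pleiotropy_shift = 0.1,
                       mean_log_crp = 0.574,
                       sd_log_crp = 1,
                       noise_sd = NULL,
                       sumstats_exposure_n = 2e5,
                       sumstats_outcome_events = 5e4,
                       seed = 42L) {
  subtype_def <- list(erpr_pos_prob = 0.75, her2_pos_prob = 0.2,
                      theta_erpr = c(pos = 1, neg = 1))
  subtype <- utils::modifyList(subtype_def, as.list(subtype))
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    n_binary_variants = min(as.integer(n_binary_variants), as.integer(n_variants)),
    maf_range = as.numeric(maf_range),
    target_r2 = target_r2,
    causal_effect_theta = causal_effect_theta,
    baseline_hazard = baseline_hazard,
    max_followup_years = max_followup_years,
    entry_spread_years = entry_spread_years,
    admin_censor_fraction = admin_censor_fraction,
    n_substudies = as.integer(n_substudies),
    modifier_effects = modifier_effects,
    subtype = subtype,
    invalid_fraction = invalid_fraction,
    pleiotropy_shift = pleiotropy_shift,
    mean_log_crp = mean_log_crp,
    sd_log_crp = sd_log_crp,
    noise_sd = noise_sd,
    sumstats_exposure_n = sumstats_exposure_n,
    sumstats_outcome_events = sumstats_outcome_events,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_individuals <= 0L || n_variants <= 0L)
      stop_bad_arg("n_individuals and n_variants must be positive")
    if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range >= 1) ||
        maf_range[1] > maf_range[2])
      stop_bad_arg("maf_range must be an increasing pair inside (0, 1)")
    if (target_r2 < 0 || target_r2 >= 1)
      stop_bad_arg("target_r2 must lie in [0, 1)")
    if (invalid_fraction < 0 || invalid_fraction > 1)
      stop_bad_arg("invalid_fraction must lie in [0, 1]")
    if (n_substudies < 1L) stop_bad_arg("n_substudies must be >= 1")
    if (baseline_hazard < 0) stop_bad_arg("baseline_hazard must be >= 0")
    if (admin_censor_fraction <= 0 || admin_censor_fraction > 1)
      stop_bad_arg("admin_censor_fraction must lie in (0, 1]")
    if (entry_spread_years < 0 || entry_spread_years >= max_followup_years)
      stop_bad_arg("entry_spread_years must lie in [0, max_followup_years)")
    if (!is.null(modifier_effects)) {
      me <- modifier_effects
      if (!all(c("variable", "breaks", "multipliers") %in% names(me)))
        stop_bad_arg("modifier_effects needs variable, breaks, multipliers")
      if (is.unsorted(me$breaks, strictly = TRUE))
        stop_bad_arg("modifier_effects$breaks must be strictly increasing")
      if (length(me$multipliers) != length(me$breaks) + 1L)
        stop_bad_arg("need one multiplier per bin (length(breaks) + 1)")
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, variants = %d (%d binary-scale), substudies = %d\n",
              x$n_individuals, x$n_variants, x$n_binary_variants, x$n_substudies))
  cat(sprintf("  target R2 = %.3f, theta = %.3f, baseline hazard = %.2e/yr\n",
              x$target_r2, x$causal_effect_theta, x$baseline_hazard))
  cat(sprintf("  horizon = %.1f yr (entry spread %.1f), admin censor fraction = %.2f\n",
              x$max_followup_years, x$entry_spread_years, x$admin_censor_fraction))
  if (x$invalid_fraction > 0)
    cat(sprintf("  invalid weight fraction = %.2f, pleiotropy shift = %.3f\n",
                x$invalid_fraction, x$pleiotropy_shift))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
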