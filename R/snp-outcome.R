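stage1_covariates <- function() c("age", paste0("pc", 1:10))

stage2_covariates <- function() {
  c(stage1_covariates(),
    "education", "income", "family_history", "cesd", "cigarettes_day",
    "met_hr_wk", "alcohol_g_day", "sfa_pct", "age_menopause",
    "oc_yrs", "e_only_yrs", "e_p_yrs", "height", "weight", "whr")
}

adjustment_covariates <- function(stage, cohort) {
  want <- if (stage == 1L) stage1_covariates() else stage2_covariates()
  intersect(want, names(cohort))
}

#' Cox regression of the outcome on a single variant's dosage
#'
#' Fits `Surv(followup_years, event) ~ dosage + covariates` by partial
#' likelihood (Efron ties by default). Stage 1 adjusts age and the 10
#' genetic principal components; stage 2 additionally adjusts the 15
#' lifestyle/demographic covariates. Complete cases only; the number of
#' dropped rows is recorded. Non-convergence or monotone likelihood
#' (separation, detected as an exploding coefficient or standard error) is
#' returned as a flagged estimate with `se = Inf` rather than an error, so
#' that pooling can skip it; zero events is an error.
#'
#' @param cohort data.frame with followup_years, event and the adjustment
#'   covariates (see [simulate_phenotypes()] for column names).
#' @param genotypes dosage matrix.
#' @param variant_id column of `genotypes` to test.
#' @param stage 1 or 2.
#' @param substudy optional sub-study label: restricts `cohort` to
#'   `cohort$substudy == substudy`.
#' @param ties "efron" (default) or "breslow".
#' @param ph_check also compute the Schoenfeld diagnostic (default TRUE).
#' @return one-row data.frame: variant_id, stage, substudy, log_hr, se,
#'   z, p, n, events, n_dropped, schoenfeld_rho, schoenfeld_p, flagged.
#' @export
fit_cox_per_snp <- function(cohort, genotypes, variant_id, stage = 1L,
                            substudy = NULL, ties = c("efron", "breslow"),
                            ph_check = TRUE) {
  ties <- match.arg(ties)
  if (!variant_id %in% colnames(genotypes))
    stop_bad_arg("variant %s not in genotype matrix", variant_id)
  rows <- if (is.null(substudy)) seq_len(nrow(cohort))
          else which(cohort$substudy == substudy)
  dat <- cohort[rows, , drop = FALSE]
  dat$dosage <- genotypes[rows, variant_id]
  covs <- adjustment_covariates(stage, dat)
  use <- complete.cases(dat[, c("followup_years", "event", "dosage", covs)])
  n_dropped <- sum(!use)
  dat <- dat[use, , drop = FALSE]
  if (sum(dat$event) == 0L)
    stop_bad_arg("no events for variant %s%s", variant_id,
                 if (is.null(substudy)) "" else paste0(" in ", substudy))
  if (sd(dat$dosage) == 0)
    stop_bad_arg("constant dosage for variant %s", variant_id)
  fml <- as.formula(paste("Surv(followup_years, event) ~ dosage",
                          if (length(covs)) paste("+", paste(covs, collapse = " + "))
                          else ""))
  flagged <- FALSE
  fit <- tryCatch(
    withCallingHandlers(
      coxph(fml, data = dat, ties = ties,
            control = coxph.control(iter.max = 50)),
      warning = function(w) {
        if (grepl("converge|infinite|Loglik", conditionMessage(w)))
          flagged <<- TRUE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) {
    est <- c(log_hr = NA_real_, se = Inf)
    flagged <- TRUE
  } else {
    b <- coef(fit)[["dosage"]]
    se <- sqrt(vcov(fit)["dosage", "dosage"])
    if (!is.finite(b) || !is.finite(se) || abs(b) > 15 || se > 50)
      flagged <- TRUE
    est <- c(log_hr = b, se = if (flagged) Inf else se)
  }
  ph <- c(rho = NA_real_, p = NA_real_)
  if (ph_check && !flagged && !is.null(fit))
    ph <- check_proportional_hazards(fit, term = "dosage")
  data.frame(variant_id = variant_id, stage = stage,
             substudy = substudy %||% "all",
             log_hr = unname(est["log_hr"]), se = unname(est["se"]),
             z = unname(est["log_hr"] / est["se"]),
             p = 2 * pnorm(-abs(unname(est["log_hr"] / est["se"]))),
             n = nrow(dat), events = sum(dat$event), n_dropped = n_dropped,
             schoenfeld_rho = unname(ph["rho"]),
             schoenfeld_p = unname(ph["p"]),
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Schoenfeld-residual check of proportional hazards
#'
#' Pearson correlation between the scaled Schoenfeld residuals of one
#' model term and the rank of the event times, with the correlation-test
#' p-value. A non-zero correlation indicates a time-varying hazard ratio.
#'
#' @param fit a [survival::coxph] fit.
#' @param term model term to check (default "dosage").
#' @return named vector `c(rho =, p =)`; NAs with a warning when fewer
#'   than 3 events make the correlation test undefined.
#' @export
check_proportional_hazards <- function(fit, term = "dosage") {
  res <- tryCatch(residuals(fit, type = "scaledsch"), error = function(e) NULL)
  if (is.null(res)) {
    warning("Schoenfeld residuals unavailable", call. = FALSE)
    return(c(rho = NA_real_, p = NA_real_))
  }
  res <- as.matrix(res)
  cn <- colnames(res) %||% names(coef(fit))
  j <- if (term %in% cn) which(cn == term) else 1L
  r <- res[, j]
  if (length(r) < 3L) {
    warning("fewer than 3 events: PH correlation undefined", call. = FALSE)
    return(c(rho = NA_real_, p = NA_real_))
  }
  tt <- as.numeric(rownames(res))
  ct <- cor.test(rank(tt), r)
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Fixed-effect (inverse-variance) meta-analysis of per-study estimates
#'
#' Pooled log HR `sum(b_i / se_i^2) / sum(1 / se_i^2)` with standard error
#' `sqrt(1 / sum(1 / se_i^2))`. Flagged estimates (non-finite or infinite
#' SE) are excluded before pooling.
#'
#' @param estimates data.frame with log_hr, se and (optionally) flagged.
#' @return one-row data.frame: log_hr, se, z, p, n_studies.
#' @export
fixed_effect_meta <- function(estimates) {
  ok <- is.finite(estimates$log_hr) & is.finite(estimates$se) &
    estimates$se > 0
  if ("flagged" %in% names(estimates)) ok <- ok & !estimates$flagged
  est <- estimates[ok, , drop = FALSE]
  if (!nrow(est)) stop_bad_arg("no usable estimates to pool")
  w <- 1 / est$se^2
  b <- sum(w * est$log_hr) / sum(w)
  se <- sqrt(1 / sum(w))
  data.frame(log_hr = b, se = se, z = b / se,
             p = 2 * pnorm(-abs(b / se)), n_studies = nrow(est))
}

#' Per-variant Cox scan with cross-study pooling
#'
#' Runs [fit_cox_per_snp()] for every variant, either on the whole cohort
#' or separately within each sub-study followed by [fixed_effect_meta()]
#' pooling (the latter mirrors a multi-GWAS design). Sub-studies in which
#' a variant has no events or constant dosage are skipped with a warning
#' and the remaining studies are pooled.
#'
#' @param cohort,genotypes,stage,ties as in [fit_cox_per_snp()].
#' @param variants instrument data.frame (variant ids to scan).
#' @param by_substudy pool across `cohort$substudy` (default TRUE when the
#'   column has > 1 level).
#' @return data.frame, one row per variant: variant_id, stage, log_hr, se,
#'   z, p, n_studies, schoenfeld_rho, schoenfeld_p (whole-cohort
#'   diagnostics are NA when pooling by sub-study).
#' @export
snp_outcome_scan <- function(cohort, genotypes, variants, stage = 1L,
                             by_substudy = NULL, ties = "efron") {
  ids <- intersect(variants$variant_id, colnames(genotypes))
  by_substudy <- by_substudy %||%
    ("substudy" %in% names(cohort) && length(unique(cohort$substudy)) > 1L)
  rows <- lapply(ids, function(id) {
    if (by_substudy) {
      per <- lapply(unique(cohort$substudy), function(s) {
        tryCatch(fit_cox_per_snp(cohort, genotypes, id, stage, substudy = s,
                                 ties = ties, ph_check = FALSE),
                 error = function(e) NULL)
      })
      per <- do.call(rbind, per[!vapply(per, is.null, logical(1))])
      if (is.null(per) || !nrow(per)) {
        warning(sprintf("variant %s unusable in every sub-study", id),
                call. = FALSE)
        return(NULL)
      }
      pooled <- tryCatch(fixed_effect_meta(per), error = function(e) NULL)
      if (is.null(pooled)) return(NULL)
      data.frame(variant_id = id, stage = stage, pooled,
                 schoenfeld_rho = NA_real_, schoenfeld_p = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      one <- tryCatch(fit_cox_per_snp(cohort, genotypes, id, stage,
                                      ties = ties),
                      error = function(e) NULL)
      if (is.null(one) || one$flagged) return(NULL)
      data.frame(variant_id = id, stage = stage, log_hr = one$log_hr,
                 se = one$se, z = one$z, p = one$p, n_studies = 1L,
                 schoenfeld_rho = one$schoenfeld_rho,
                 schoenfeld_p = one$schoenfeld_p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop_bad_arg("no variant produced a usable estimate")
  rownames(out) <- NULL
  out
}
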