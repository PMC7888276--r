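#' Genetic-score associations within environment strata
#'
#' For each stratum of an environmental variable, estimates the score's
#' association with the exposure (OLS of log CRP on the score, `gamma_s`)
#' and with the outcome (Cox log HR of the score with the stage's
#' adjustment covariates, `Gamma_s`). Strata with zero events or a
#' constant score are dropped with a warning; fewer than two usable strata
#' is an error, because the gene-environment identification strategy
#' needs heterogeneity of instrument strength across at least two strata.
#'
#' @param cohort data.frame with log_crp, followup_years, event and the
#'   adjustment covariates.
#' @param gs a `genetic_score` (or bare numeric score vector, one per row
#'   of `cohort`).
#' @param stratum factor/character vector assigning each row to a stratum
#'   (NA rows are excluded).
#' @param stage Cox adjustment stage (1 or 2).
#' @return data.frame, one row per usable stratum: stratum, n, events,
#'   gamma (score-exposure slope), se_gamma, big_gamma (score-outcome log
#'   HR), se_big_gamma.
#' @export
stratum_associations <- function(cohort, gs, stratum, stage = 1L) {
  score <- if (inherits(gs, "genetic_score")) gs$score else as.numeric(gs)
  if (length(score) != nrow(cohort))
    stop_bad_arg("score length must match the cohort")
  stratum <- as.character(stratum)
  levels_ <- unique(stratum[!is.na(stratum)])
  covs <- adjustment_covariates(stage, cohort)
  rows <- lapply(levels_, function(s) {
    idx <- which(!is.na(stratum) & stratum == s)
    dat <- cohort[idx, , drop = FALSE]
    dat$gs_ <- score[idx]
    if (sum(dat$event) == 0L || sd(dat$gs_) == 0) {
      warning(sprintf("stratum '%s' dropped (no events or constant score)", s),
              call. = FALSE)
      return(NULL)
    }
    ols <- summary(lm(log_crp ~ gs_, data = dat))$coefficients
    fml <- as.formula(paste("Surv(followup_years, event) ~ gs_",
                            if (length(covs))
                              paste("+", paste(covs, collapse = " + "))
                            else ""))
    cox <- coxph(fml, data = dat)
    data.frame(stratum = s, n = nrow(dat), events = sum(dat$event),
               gamma = ols["gs_", "Estimate"],
               se_gamma = ols["gs_", "Std. Error"],
               big_gamma = coef(cox)[["gs_"]],
               se_big_gamma = sqrt(vcov(cox)["gs_", "gs_"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) < 2L)
    stop_bad_arg("fewer than 2 usable strata: G x E estimate unidentified")
  rownames(out) <- NULL
  out
}

#' Gene-environment-interaction corrected causal estimate
#'
#' Regresses the per-stratum score-outcome associations `Gamma_s` on the
#' score-exposure associations `gamma_s` by weighted least squares
#' (weights `1 / se_Gamma_s^2`, known-variance standard errors). Under
#' pleiotropy that is constant across strata, the slope is the corrected
#' causal effect of the exposure and the intercept estimates the constant
#' pleiotropic effect. With exactly two strata this reduces to the
#' closed form `slope = (Gamma_2 - Gamma_1) / (gamma_2 - gamma_1)`,
#' `intercept = Gamma_1 - slope * gamma_1`. Strata whose exposure
#' associations do not vary leave the slope unidentified and raise an
#' error.
#'
#' @param associations data.frame from [stratum_associations()] (needs
#'   gamma, big_gamma, se_big_gamma).
#' @param boot use a nonparametric stratum bootstrap (resample strata with
#'   replacement) for the standard errors instead of normal theory;
#'   crude below ~10 strata and off by default.
#' @param boot_reps,seed bootstrap settings when `boot = TRUE`.
#' @return list of class `gxe_estimate`: slope, se_slope, p_slope,
#'   intercept, se_intercept, p_intercept, n_strata.
#' @export
gxe_estimate <- function(associations, boot = FALSE, boot_reps = 1000L,
                         seed = 1L) {
  a <- associations
  if (nrow(a) < 2L) stop_bad_arg("need >= 2 strata")
  if (diff(range(a$gamma)) < 1e-12 * max(1, max(abs(a$gamma))))
    stop_bad_arg("score-exposure associations identical across strata: slope unidentified")
  w <- 1 / a$se_big_gamma^2
  X <- cbind(1, a$gamma)
  XtWX <- crossprod(X, w * X)
  bhat <- solve(XtWX, crossprod(X, w * a$big_gamma))
  V <- solve(XtWX)
  out <- list(slope = bhat[2], se_slope = sqrt(V[2, 2]),
              intercept = bhat[1], se_intercept = sqrt(V[1, 1]),
              n_strata = nrow(a))
  if (boot) {
    bs <- with_seed(seed, {
      draws <- vapply(seq_len(boot_reps), function(r) {
        idx <- sample.int(nrow(a), replace = TRUE)
        if (diff(range(a$gamma[idx])) < 1e-12) return(c(NA_real_, NA_real_))
        wr <- 1 / a$se_big_gamma[idx]^2
        Xr <- cbind(1, a$gamma[idx])
        as.numeric(solve(crossprod(Xr, wr * Xr),
                         crossprod(Xr, wr * a$big_gamma[idx])))
      }, numeric(2))
      apply(draws, 1, sd, na.rm = TRUE)
    })
    out$se_intercept <- bs[1]
    out$se_slope <- bs[2]
  }
  out$p_slope <- 2 * pnorm(-abs(out$slope / out$se_slope))
  out$p_intercept <- 2 * pnorm(-abs(out$intercept / out$se_intercept))
  out$ci_slope <- out$slope + c(-1.96, 1.96) * out$se_slope
  out$ci_intercept <- out$intercept + c(-1.96, 1.96) * out$se_intercept
  class(out) <- "gxe_estimate"
  out
}

#' @export
print.gxe_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("G x E corrected MR estimate (%d strata)\n", x$n_strata))
  cat(sprintf("  slope (causal effect): %.*f (SE %.*f), HR %.*f, p = %.3g\n",
              digits, x$slope, digits, x$se_slope, digits, exp(x$slope),
              x$p_slope))
  cat(sprintf("  intercept (constant pleiotropy): %.*f (SE %.*f), p = %.3g\n",
              digits, x$intercept, digits, x$se_intercept, x$p_intercept))
  invisible(x)
}
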