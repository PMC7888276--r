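#' Fit the full set of summary-statistic MR estimators
#'
#' The central fitting function: given per-instrument exposure effects
#' (`gamma_hat`, `se_gamma`) and outcome effects on the log-hazard scale
#' (`big_gamma_hat`, `se_big_gamma`), computes Wald ratios and the
#' requested estimators — inverse-variance weighted (IVW), weighted median
#' (WM), penalized weighted median (PWM) and MR-Egger (slope + intercept)
#' — together with Cochran's Q. Results are reported as hazard ratios per
#' unit increase of the exposure on its stated scale (log-odds of chronic
#' inflammation, or natural-log mg/L). Instruments on different exposure
#' scales must never be pooled in one fit; pass the `exposure_scale` label
#' and filter beforehand (the pipeline functions do this for you).
#'
#' @param gamma_hat,se_gamma exposure effects and SEs (oriented so
#'   `gamma_hat >= 0`).
#' @param big_gamma_hat,se_big_gamma outcome effects (log HR) and SEs.
#' @param variant_id optional instrument ids.
#' @param methods subset of `c("ivw", "wm", "pwm", "egger")`.
#' @param boot_reps,seed parametric-bootstrap settings for the WM/PWM SEs.
#' @param penalty_constant PWM penalization constant.
#' @param se_order Wald-ratio SE order, "first" or "second".
#' @param cov_gamma_big one-sample exposure/outcome estimate covariance
#'   passed to [wald_ratio()] (second-order SEs only).
#' @param exposure_scale label propagated into results.
#' @param random_effects multiplicative random-effects IVW SE.
#' @return object of class `mr_fit`: list with `ratios`, `results` (named
#'   list of `mr_result`s), `egger`, `Q`, and the call settings. Methods:
#'   `print`, `summary`, `coef`, `confint`, `plot`.
#' @examples
#' ratios_from <- data.frame(g = c(0.2, 0.4, 0.6), G = c(0.1, 0.21, 0.29))
#' fit <- mr_fit(ratios_from$g, rep(0.01, 3), ratios_from$G, rep(0.05, 3),
#'               boot_reps = 200, seed = 7)
#' coef(fit)
#' @export
mr_fit <- function(gamma_hat, se_gamma, big_gamma_hat, se_big_gamma,
                   variant_id = NULL,
                   methods = c("ivw", "wm", "pwm", "egger"),
                   boot_reps = 1000L, seed = 1L, penalty_constant = 20,
                   se_order = "first", cov_gamma_big = 0,
                   exposure_scale = NA_character_,
                   random_effects = FALSE) {
  methods <- match.arg(methods, c("ivw", "wm", "pwm", "egger"),
                       several.ok = TRUE)
  ratios <- wald_ratio(gamma_hat, se_gamma, big_gamma_hat, se_big_gamma,
                       order = se_order, cov_gamma_big = cov_gamma_big,
                       variant_id = variant_id)
  J <- nrow(ratios)
  results <- list()
  if ("ivw" %in% methods)
    results$ivw <- mr_ivw(ratios, random_effects = random_effects)
  if ("wm" %in% methods && J >= 2L)
    results$wm <- mr_weighted_median(ratios, boot_reps, seed)
  if ("pwm" %in% methods && J >= 2L)
    results$pwm <- mr_penalized_weighted_median(ratios, penalty_constant,
                                                boot_reps, seed)
  egger <- if ("egger" %in% methods && J >= 3L)
    mr_egger(gamma_hat, big_gamma_hat, se_big_gamma) else NULL
  if (!is.null(egger)) {
    results$egger_slope <- egger$slope
    results$egger_intercept <- egger$intercept
  }
  results <- lapply(results, function(r) {
    r$exposure_scale <- exposure_scale
    r
  })
  structure(list(ratios = ratios, results = results, egger = egger,
                 Q = if (J >= 2L) cochran_q(ratios) else NULL,
                 n_instruments = J, boot_reps = boot_reps, seed = seed,
                 exposure_scale = exposure_scale),
            class = "mr_fit")
}

mr_fit_table <- function(x) {
  do.call(rbind, lapply(x$results, function(r) {
    data.frame(method = r$method, n_snps = r$n_instruments,
               estimate = r$estimate, se = r$se,
               ci_low = r$ci_low, ci_high = r$ci_high,
               hr = r$hr, hr_low = r$hr_low, hr_high = r$hr_high,
               p = r$p, Q = r$Q, Q_p = r$Q_p,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Mendelian randomization fit: %d instruments%s\n",
              x$n_instruments,
              if (!is.na(x$exposure_scale))
                paste0(" (", x$exposure_scale, " exposure)") else ""))
  tab <- mr_fit_table(x)
  if (!is.null(tab)) {
    fmt <- data.frame(method = tab$method,
                      `HR (95% CI)` = sprintf("%.*f (%.*f-%.*f)", digits,
                                              tab$hr, digits, tab$hr_low,
                                              digits, tab$hr_high),
                      p = signif(tab$p, 3), check.names = FALSE)
    print(fmt, row.names = FALSE)
  }
  if (!is.null(x$Q))
    cat(sprintf("Cochran's Q = %.*f on %d df (p = %.3g)\n",
                digits, x$Q$Q, x$Q$df, x$Q$p))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  tab <- mr_fit_table(object)
  rownames(tab) <- NULL
  structure(list(table = tab, Q = object$Q,
                 n_instruments = object$n_instruments), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$results, function(r) r$estimate, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  m <- t(vapply(object$results, function(r)
    c(r$estimate - z * r$se, r$estimate + z * r$se), numeric(2)))
  colnames(m) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
plot.mr_fit <- function(x, ...) {
  r <- x$ratios
  o <- order(r$ratio)
  ci_lo <- r$ratio - 1.96 * r$se_ratio
  ci_hi <- r$ratio + 1.96 * r$se_ratio
  plot(r$ratio[o], seq_len(nrow(r)), xlim = range(ci_lo, ci_hi),
       pch = 19, xlab = "per-instrument causal estimate (log HR)",
       ylab = "instrument rank", ...)
  segments(ci_lo[o], seq_len(nrow(r)), ci_hi[o], seq_len(nrow(r)))
  if (!is.null(x$results$ivw))
    abline(v = x$results$ivw$estimate, lty = 2)
  if (!is.null(x$results$pwm))
    abline(v = x$results$pwm$estimate, lty = 3)
  invisible(x)
}
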