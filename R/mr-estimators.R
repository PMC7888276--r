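#' Per-variant Wald ratio estimates
#'
#' The causal effect identified by one instrument is the ratio of its
#' outcome effect to its exposure effect, `beta_j = Gamma_j / gamma_j`.
#' First-order standard error `se_Gamma / |gamma|` treats the exposure
#' effect as known; the second-order form adds its sampling noise,
#' `sqrt(se_Gamma^2 / gamma^2 + Gamma^2 * se_gamma^2 / gamma^4)`. An
#' optional covariance term between the two effects (one-sample overlap)
#' enters the second-order variance as `- 2 * Gamma * cov / gamma^3`.
#'
#' @param gamma_hat,se_gamma per-variant exposure effect and SE.
#' @param big_gamma_hat,se_big_gamma per-variant outcome effect (log HR)
#'   and SE.
#' @param order "first" (default) or "second" order standard errors.
#' @param cov_gamma_big covariance between the exposure- and outcome-effect
#'   estimates (default 0; only used for second-order SEs).
#' @param variant_id optional ids carried through.
#' @return data.frame of class `ratio_estimates`: variant_id, ratio,
#'   se_ratio, weight (`1/se_ratio^2`).
#' @export
wald_ratio <- function(gamma_hat, se_gamma, big_gamma_hat, se_big_gamma,
                       order = c("first", "second"), cov_gamma_big = 0,
                       variant_id = NULL) {
  order <- match.arg(order)
  if (any(gamma_hat == 0))
    stop_bad_arg("undefined Wald ratio: gamma_hat contains zeros")
  ratio <- big_gamma_hat / gamma_hat
  se <- if (order == "first") {
    se_big_gamma / abs(gamma_hat)
  } else {
    v <- se_big_gamma^2 / gamma_hat^2 +
      big_gamma_hat^2 * se_gamma^2 / gamma_hat^4 -
      2 * big_gamma_hat * cov_gamma_big / gamma_hat^3
    sqrt(pmax(v, 0))
  }
  out <- data.frame(
    variant_id = variant_id %||% sprintf("v%d", seq_along(ratio)),
    ratio = ratio, se_ratio = se, weight = 1 / se^2,
    stringsAsFactors = FALSE)
  class(out) <- c("ratio_estimates", "data.frame")
  out
}

new_mr_result <- function(method, estimate, se, n_instruments,
                          Q = NA_real_, Q_df = NA_real_, Q_p = NA_real_,
                          boot_reps = NA_integer_, seed = NA_integer_,
                          exposure_scale = NA_character_) {
  res <- list(method = method, estimate = estimate, se = se,
              ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
              p = 2 * pnorm(-abs(estimate / se)),
              n_instruments = n_instruments,
              Q = Q, Q_df = Q_df, Q_p = Q_p,
              boot_reps = boot_reps, seed = seed,
              exposure_scale = exposure_scale)
  class(res) <- "mr_result"
  report_hr(res)
}

#' Inverse-variance weighted estimate
#'
#' Fixed-effect pooled causal estimate `sum(w_j b_j) / sum(w_j)` with
#' `SE = sqrt(1 / sum(w_j))`, equal to the weighted least-squares slope of
#' the outcome effects on the exposure effects through the origin. A
#' multiplicative random-effects variant inflates the SE by the residual
#' scale `sqrt(Q / (J - 1))` when it exceeds 1.
#'
#' @param ratios a `ratio_estimates` data.frame (from [wald_ratio()]).
#' @param random_effects multiplicative random-effects SE (default FALSE,
#'   the traditional fixed-effect form).
#' @return an `mr_result` (includes Cochran's Q fields).
#' @export
mr_ivw <- function(ratios, random_effects = FALSE) {
  if (!nrow(ratios)) stop_bad_arg("no instruments supplied")
  w <- ratios$weight
  est <- sum(w * ratios$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- sum(w * (ratios$ratio - est)^2)
  J <- nrow(ratios)
  if (random_effects && J > 1L) se <- se * max(1, sqrt(Q / (J - 1)))
  new_mr_result("IVW", est, se, J,
                Q = Q, Q_df = J - 1,
                Q_p = if (J > 1L) pchisq(Q, J - 1, lower.tail = FALSE)
                      else NA_real_)
}

# cumulative-weight interpolation at probability 0.5 (the estimator core,
# shared by the weighted and penalized weighted median)
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]; w <- w[o]
  pw <- (cumsum(w) - 0.5 * w) / sum(w)
  if (pw[1] >= 0.5) return(b[1])
  if (pw[length(pw)] <= 0.5) return(b[length(b)])
  below <- max(which(pw < 0.5))
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - pw[below]) / (pw[below + 1] - pw[below])
}

wm_bootstrap_se <- function(ratios, weights, boot_reps, seed) {
  if (is.na(boot_reps) || boot_reps < 2L) return(NA_real_)
  # sort instruments first so the seeded draw stream (and hence the SE)
  # does not depend on the input ordering
  o <- order(ratios$ratio, ratios$se_ratio, weights)
  b <- ratios$ratio[o]; se <- ratios$se_ratio[o]; w <- weights[o]
  with_seed(seed, {
    J <- length(b)
    draws <- matrix(rnorm(J * boot_reps, b, se), J, boot_reps)
    sd(apply(draws, 2, weighted_median_point, w = w))
  })
}

#' Weighted median estimate
#'
#' Consistent when valid instruments carry a majority (> 50%) of the
#' inverse-variance weight. Ratio estimates are ordered; the estimate is
#' the linear interpolation of the ordered ratios at cumulative normalized
#' weight 1/2, i.e. at `p_j = (S_j - w_j/2) / S_total`. The standard error
#' is the standard deviation of the estimate across `boot_reps` parametric
#' bootstrap draws `b_j* ~ N(b_j, se_j)` under a fixed seed.
#'
#' @param ratios a `ratio_estimates` data.frame (>= 2 rows).
#' @param boot_reps parametric bootstrap draws for the SE (default 1000;
#'   0 skips the bootstrap and leaves the SE as NA).
#' @param seed bootstrap seed.
#' @return an `mr_result`.
#' @export
mr_weighted_median <- function(ratios, boot_reps = 1000L, seed = 1L) {
  if (nrow(ratios) < 2L)
    stop_bad_arg("weighted median needs >= 2 instruments")
  est <- weighted_median_point(ratios$ratio, ratios$weight)
  se <- wm_bootstrap_se(ratios, ratios$weight, boot_reps, seed)
  new_mr_result("WM", est, se, nrow(ratios),
                boot_reps = as.integer(boot_reps), seed = as.integer(seed))
}

#' Penalized weighted median estimate
#'
#' Down-weights instruments whose ratio estimates are heterogeneous:
#' each instrument's contribution to Cochran's Q relative to the IVW
#' estimate, `q_j = w_j (b_j - IVW)^2`, is converted to a one-sided
#' chi-square(1) upper-tail probability `p_j` and the weight is penalized
#' to `w_j * min(1, penalty_constant * p_j)`. The weighted median is then
#' recomputed with the penalized weights (identical to the plain weighted
#' median when no `p_j < 1/penalty_constant`).
#'
#' @inheritParams mr_weighted_median
#' @param penalty_constant penalization constant (default 20).
#' @return an `mr_result`.
#' @export
mr_penalized_weighted_median <- function(ratios, penalty_constant = 20,
                                         boot_reps = 1000L, seed = 1L) {
  if (nrow(ratios) < 2L)
    stop_bad_arg("penalized weighted median needs >= 2 instruments")
  ivw <- mr_ivw(ratios)$estimate
  q_j <- ratios$weight * (ratios$ratio - ivw)^2
  p_j <- pchisq(q_j, df = 1, lower.tail = FALSE)
  w_pen <- ratios$weight * pmin(1, penalty_constant * p_j)
  est <- weighted_median_point(ratios$ratio, w_pen)
  se <- wm_bootstrap_se(ratios, w_pen, boot_reps, seed)
  res <- new_mr_result("PWM", est, se, nrow(ratios),
                       boot_reps = as.integer(boot_reps),
                       seed = as.integer(seed))
  res$penalty_constant <- penalty_constant
  res
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the (non-negative,
#' oriented) exposure effects with a free intercept, weights
#' `1 / se_Gamma^2`. The slope is the pleiotropy-adjusted causal estimate;
#' the intercept estimates the average directional pleiotropic effect, and
#' its test against zero is the directional-pleiotropy diagnostic. With
#' `intercept = FALSE` the regression runs through the origin, in which
#' case the slope coincides with the IVW estimate computed with the same
#' weights.
#'
#' @param gamma_hat oriented exposure effects (all >= 0).
#' @param big_gamma_hat outcome effects (log HR).
#' @param se_big_gamma outcome-effect standard errors.
#' @param intercept fit the intercept (default TRUE; >= 3 instruments).
#' @return list of class `mr_egger` with `slope` and (if fitted)
#'   `intercept`, both `mr_result` objects.
#' @export
mr_egger <- function(gamma_hat, big_gamma_hat, se_big_gamma,
                     intercept = TRUE) {
  J <- length(gamma_hat)
  if (intercept && J < 3L) stop_bad_arg("MR-Egger needs >= 3 instruments")
  if (!intercept && J < 1L) stop_bad_arg("no instruments supplied")
  w <- 1 / se_big_gamma^2
  X <- if (intercept) cbind(1, gamma_hat) else cbind(gamma_hat)
  XtWX <- crossprod(X, w * X)
  bhat <- solve(XtWX, crossprod(X, w * big_gamma_hat))
  V <- solve(XtWX)   # known-variance (fixed-effect) weighting
  k <- ncol(X)
  slope <- new_mr_result("Egger-slope", bhat[k], sqrt(V[k, k]), J)
  out <- list(slope = slope)
  if (intercept)
    out$intercept <- new_mr_result("Egger-intercept", bhat[1],
                                   sqrt(V[1, 1]), J)
  class(out) <- "mr_egger"
  out
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (b_j - IVW)^2)` on `J - 1` degrees of freedom with an
#' upper-tail chi-square p-value; excess heterogeneity among the per-
#' instrument ratios is additional evidence of pleiotropy.
#'
#' @param ratios a `ratio_estimates` data.frame (>= 2 rows).
#' @return list with Q, df, p.
#' @export
cochran_q <- function(ratios) {
  if (nrow(ratios) < 2L) stop_bad_arg("Cochran's Q needs >= 2 instruments")
  ivw <- sum(ratios$weight * ratios$ratio) / sum(ratios$weight)
  Q <- sum(ratios$weight * (ratios$ratio - ivw)^2)
  df <- nrow(ratios) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Attach hazard-ratio-scale fields to an estimate
#'
#' `HR = exp(estimate)` with 95% CI `exp(estimate +/- 1.96 SE)`. Works on
#' an `mr_result` (returned updated) or on bare `estimate`/`se` numbers
#' (returns a named list). Idempotent.
#'
#' @param result an `mr_result`, or a numeric log-scale estimate.
#' @param se standard error (only when `result` is numeric).
#' @return the updated `mr_result`, or list(hr, hr_low, hr_high).
#' @export
report_hr <- function(result, se = NULL) {
  if (is.numeric(result)) {
    stopifnot(!is.null(se))
    return(list(hr = exp(result),
                hr_low = exp(result - 1.96 * se),
                hr_high = exp(result + 1.96 * se)))
  }
  stopifnot(inherits(result, "mr_result"))
  result$hr <- exp(result$estimate)
  result$hr_low <- exp(result$ci_low)
  result$hr_high <- exp(result$ci_high)
  result
}

#' @export
print.mr_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s estimate (%d instruments%s)\n", x$method, x$n_instruments,
              if (!is.na(x$exposure_scale))
                paste0(", ", x$exposure_scale, " exposure") else ""))
  cat(sprintf("  log scale: %.*f (SE %.*f), p = %.3g\n",
              digits, x$estimate, digits, x$se, x$p))
  cat(sprintf("  HR %.*f (95%% CI %.*f-%.*f)\n",
              digits, x$hr, digits, x$hr_low, digits, x$hr_high))
  if (!is.na(x$Q))
    cat(sprintf("  Cochran's Q = %.*f on %d df, p = %.3g\n",
                digits, x$Q, x$Q_df, x$Q_p))
  invisible(x)
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope, ...)
  if (!is.null(x$intercept)) print(x$intercept, ...)
  invisible(x)
}
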