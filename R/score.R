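#' Weighted polygenic score for the exposure
#'
#' Per-individual additive score `GS_i = sum_j gamma_hat_j * dosage_ij`
#' over the instruments reported on the continuous (natural-log CRP)
#' exposure scale; binary-log-odds instruments are excluded from the score
#' by construction because their weights are not on the exposure unit.
#' Missing dosages are mean-imputed at `2 * eaf` and the imputation count
#' is recorded.
#'
#' @param genotypes dosage matrix (columns named by variant_id), oriented
#'   to the effect alleles of `variants`.
#' @param variants instrument data.frame (needs variant_id, gamma_hat, eaf
#'   and, if present, exposure_scale).
#' @param continuous_only drop binary-log-odds-scale instruments (default
#'   TRUE).
#' @return object of class `genetic_score`: list with `score` (numeric,
#'   one per individual), `weights`, `variant_ids`, `n_imputed`,
#'   `rescaled` flag and `rescale` coefficients (NA until [rescale_gs()]).
#' @export
build_genetic_score <- function(genotypes, variants, continuous_only = TRUE) {
  if (continuous_only && "exposure_scale" %in% names(variants))
    variants <- variants[variants$exposure_scale != "binary-logodds", ,
                         drop = FALSE]
  ids <- intersect(variants$variant_id, colnames(genotypes))
  if (!length(ids))
    stop_bad_arg("no overlap between genotype columns and instrument weights")
  v <- variants[match(ids, variants$variant_id), ]
  g <- genotypes[, ids, drop = FALSE]
  n_imp <- sum(is.na(g))
  if (n_imp > 0L) {
    for (j in seq_along(ids)) {
      nas <- is.na(g[, j])
      if (any(nas)) g[nas, j] <- 2 * v$eaf[j]
    }
  }
  structure(list(score = as.numeric(g %*% v$gamma_hat),
                 weights = setNames(v$gamma_hat, ids),
                 variant_ids = ids,
                 n_imputed = n_imp,
                 rescaled = FALSE,
                 rescale = c(intercept = NA_real_, slope = NA_real_)),
            class = "genetic_score")
}

#' Rescale the genetic score to the exposure unit
#'
#' Ordinary least squares of the measured exposure (log CRP) on the raw
#' score among unaffected individuals gives `(beta0, beta1)`; the scaled
#' score `beta0 + beta1 * GS`, applied to everyone, is on the exposure
#' unit and perfectly correlated with the raw score (r = 1 whenever
#' `beta1 > 0`; a non-positive slope is flagged).
#'
#' @param gs a `genetic_score`.
#' @param exposure numeric exposure values (same individuals, same order).
#' @param non_case_mask logical; TRUE for individuals free of the outcome.
#'   The regression uses only these (>= 3 required).
#' @return the `genetic_score` with `score` replaced by the rescaled
#'   values, `rescaled = TRUE`, coefficients in `$rescale`, and the raw
#'   score kept in `$raw_score`.
#' @export
rescale_gs <- function(gs, exposure, non_case_mask) {
  stopifnot(inherits(gs, "genetic_score"))
  if (length(exposure) != length(gs$score) ||
      length(non_case_mask) != length(gs$score))
    stop_bad_arg("exposure / mask length must match the score")
  x <- gs$score[non_case_mask]
  y <- exposure[non_case_mask]
  if (length(x) < 3L) stop_bad_arg("need >= 3 non-case individuals")
  if (var(x) == 0)
    stop_bad_arg("degenerate regression: zero score variance among non-cases")
  fit <- lm(y ~ x)
  b <- unname(coef(fit))
  if (b[2] <= 0)
    warning("rescaling slope beta1 <= 0: scaled score is anti-correlated",
            call. = FALSE)
  gs$raw_score <- gs$score
  gs$score <- b[1] + b[2] * gs$raw_score
  gs$rescale <- c(intercept = b[1], slope = b[2])
  gs$rescaled <- TRUE
  gs
}

#' @export
print.genetic_score <- function(x, ...) {
  cat(sprintf("Weighted genetic score: %d individuals, %d variants%s\n",
              length(x$score), length(x$variant_ids),
              if (x$n_imputed) sprintf(" (%d dosages mean-imputed)", x$n_imputed)
              else ""))
  if (x$rescaled)
    cat(sprintf("  rescaled to exposure unit: %.4g + %.4g * GS\n",
                x$rescale["intercept"], x$rescale["slope"]))
  invisible(x)
}
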