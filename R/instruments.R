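#' Variant quality control: missingness, Hardy-Weinberg, imputation quality
#'
#' A variant is retained iff its missing-call rate is `< max_missing`, the
#' 1-df chi-square Hardy-Weinberg test on (rounded) genotype counts has
#' `p >= hwe_p_min`, and its imputation quality is `>= min_impute_r2`.
#' Variants with no imputation quality recorded are treated as directly
#' genotyped and pass that filter. Dropping every variant is legal (a
#' warning, not an error).
#'
#' @param genotypes dosage matrix (possibly with NAs), columns named by
#'   variant_id. Dosages are rounded to the nearest hard call for the HWE
#'   test.
#' @param metadata optional data.frame with `variant_id` and `impute_r2`.
#' @param max_missing,hwe_p_min,min_impute_r2 the three thresholds.
#' @return list with `retained` (character vector of variant ids, input
#'   order) and `report` (per-variant missing rate, HWE chi-square and p,
#'   imputation R2, retained flag with reason).
#' @export
qc_filter <- function(genotypes, metadata = NULL,
                      max_missing = 0.02, hwe_p_min = 1e-4,
                      min_impute_r2 = 0.6) {
  ids <- colnames(genotypes)
  if (is.null(ids)) stop_bad_arg("genotype matrix must have variant_id colnames")
  r2 <- rep(NA_real_, length(ids))
  if (!is.null(metadata) && "impute_r2" %in% names(metadata))
    r2 <- metadata$impute_r2[match(ids, metadata$variant_id)]
  rep_list <- lapply(seq_along(ids), function(j) {
    x <- genotypes[, j]
    miss <- mean(is.na(x))
    hw <- hwe_test(x[!is.na(x)])
    c(miss = miss, chisq = hw[["chisq"]], p = hw[["p"]])
  })
  m <- do.call(rbind, rep_list)
  pass_miss <- m[, "miss"] < max_missing
  pass_hwe <- !is.na(m[, "p"]) & m[, "p"] >= hwe_p_min
  pass_r2 <- is.na(r2) | r2 >= min_impute_r2
  keep <- pass_miss & pass_hwe & pass_r2
  report <- data.frame(variant_id = ids,
                       missing_rate = m[, "miss"],
                       hwe_chisq = m[, "chisq"],
                       hwe_p = m[, "p"],
                       impute_r2 = r2,
                       pass_missing = pass_miss,
                       pass_hwe = pass_hwe,
                       pass_impute = pass_r2,
                       retained = keep,
                       row.names = NULL,
                       stringsAsFactors = FALSE)
  if (!any(keep)) warning("qc_filter removed every variant", call. = FALSE)
  list(retained = ids[keep], report = report)
}

#' One-degree-of-freedom Hardy-Weinberg chi-square test
#'
#' Pearson chi-square of observed hard-call genotype counts against the
#' p^2 : 2pq : q^2 expectation at the estimated allele frequency; no
#' continuity correction.
#'
#' @param dosages numeric vector of dosages in `[0, 2]` (rounded to hard
#'   calls), NAs removed by the caller.
#' @return named vector `c(chisq =, p =)`; both NA for empty or
#'   monomorphic input (a monomorphic variant is in exact HWE: chisq 0, p 1).
#' @export
hwe_test <- function(dosages) {
  g <- round(dosages)
  g <- g[!is.na(g) & g >= 0 & g <= 2]
  n <- length(g)
  if (n == 0L) return(c(chisq = NA_real_, p = NA_real_))
  obs <- tabulate(g + 1L, nbins = 3L)
  p_hat <- (2 * obs[3] + obs[2]) / (2 * n)
  exp_cnt <- n * c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  if (p_hat == 0 || p_hat == 1) return(c(chisq = 0, p = 1))
  chisq <- sum((obs - exp_cnt)^2 / exp_cnt)
  c(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Greedy LD pruning to an independent index-variant set
#'
#' Variants are ranked by exposure-association strength
#' `|gamma_hat / se_gamma|` (ties broken by variant_id) and accepted in
#' that order iff the squared dosage correlation with every
#' already-accepted variant is below `threshold`. Constant dosage columns
#' have undefined correlation and are excluded with a warning.
#'
#' @param variants data.frame with variant_id, gamma_hat, se_gamma.
#' @param genotypes dosage matrix, or a pre-computed correlation matrix via
#'   `cor_matrix`.
#' @param threshold squared-correlation cutoff (default 0.3).
#' @param cor_matrix optional pairwise dosage correlation matrix
#'   (dimnames = variant ids); overrides `genotypes`.
#' @return character vector of retained variant ids, in acceptance
#'   (rank) order.
#' @export
prune_ld <- function(variants, genotypes = NULL, threshold = 0.3,
                     cor_matrix = NULL) {
  if (is.null(cor_matrix)) {
    if (is.null(genotypes)) stop_bad_arg("need genotypes or cor_matrix")
    keep_ids <- intersect(variants$variant_id, colnames(genotypes))
    sds <- apply(genotypes[, keep_ids, drop = FALSE], 2, sd)
    if (any(sds == 0)) {
      warning(sprintf("excluding %d constant-dosage variant(s): %s",
                      sum(sds == 0),
                      paste(keep_ids[sds == 0], collapse = ", ")),
              call. = FALSE)
      keep_ids <- keep_ids[sds > 0]
    }
    cor_matrix <- stats::cor(genotypes[, keep_ids, drop = FALSE])
  }
  v <- variants[variants$variant_id %in% rownames(cor_matrix), , drop = FALSE]
  strength <- abs(v$gamma_hat / v$se_gamma)
  ord <- order(-strength, v$variant_id)
  accepted <- character(0)
  for (id in v$variant_id[ord]) {
    if (!length(accepted) ||
        all(cor_matrix[id, accepted]^2 < threshold))
      accepted <- c(accepted, id)
  }
  accepted
}

#' Collapse duplicate instruments across source studies
#'
#' Records sharing a `variant_id` are first harmonised to a common allele
#' orientation (a record whose effect/other alleles are swapped relative to
#' the group's first record has its alleles swapped, `eaf` replaced by
#' `1 - eaf` and `gamma_hat` negated); duplicates whose allele pairs cannot
#' be reconciled by that flip raise a harmonisation error. The surviving
#' record is the one with the most recent `publication_year`, ties broken
#' by smallest `se_gamma`. Discarded records are logged in the `"dropped"`
#' attribute.
#'
#' @param variants data.frame of instrument records (possibly duplicated).
#' @return de-duplicated data.frame, original first-occurrence order, with
#'   attribute `dropped` (data.frame of discarded records).
#' @export
merge_studies <- function(variants) {
  split_idx <- split(seq_len(nrow(variants)), variants$variant_id)
  keep <- integer(0)
  dropped <- integer(0)
  for (idx in split_idx) {
    if (length(idx) == 1L) { keep <- c(keep, idx); next }
    ref <- variants[idx[1], ]
    for (i in idx[-1]) {
      same <- variants$effect_allele[i] == ref$effect_allele &&
        variants$other_allele[i] == ref$other_allele
      swapped <- variants$effect_allele[i] == ref$other_allele &&
        variants$other_allele[i] == ref$effect_allele
      if (swapped) {
        ea <- variants$effect_allele[i]
        variants$effect_allele[i] <- variants$other_allele[i]
        variants$other_allele[i] <- ea
        variants$eaf[i] <- 1 - variants$eaf[i]
        variants$gamma_hat[i] <- -variants$gamma_hat[i]
      } else if (!same) {
        stop_bad_arg("cannot harmonise alleles for duplicate variant %s (%s/%s vs %s/%s)",
                     ref$variant_id, ref$effect_allele, ref$other_allele,
                     variants$effect_allele[i], variants$other_allele[i])
      }
    }
    ord <- order(-variants$publication_year[idx], variants$se_gamma[idx])
    keep <- c(keep, idx[ord[1]])
    dropped <- c(dropped, idx[ord[-1]])
  }
  out <- variants[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- variants[dropped, , drop = FALSE]
  out
}

#' Remove instruments with pleiotropy annotations
#'
#' Drops any record whose `pleiotropy_tags` (semicolon-separated trait
#' labels) intersect `excluded_traits`. The default exclusion list covers
#' the obesity, glycaemic and lipid traits that plausibly open pathways to
#' the outcome other than through CRP.
#'
#' @param variants instrument data.frame.
#' @param excluded_traits character vector of trait labels.
#' @return filtered data.frame; dropped ids in attribute `excluded`.
#' @export
exclude_pleiotropic <- function(variants,
                                excluded_traits = default_pleiotropy_traits()) {
  if (!length(excluded_traits) || !nrow(variants)) {
    attr(variants, "excluded") <- character(0)
    return(variants)
  }
  tags <- strsplit(variants$pleiotropy_tags %||% "", ";", fixed = TRUE)
  hit <- vapply(tags, function(t) any(trimws(t) %in% excluded_traits), logical(1))
  out <- variants[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- variants$variant_id[hit]
  out
}

#' @rdname exclude_pleiotropic
#' @export
default_pleiotropy_traits <- function() {
  c("BMI", "WHR", "fasting glucose", "fasting insulin", "2-h glucose",
    "T2DM", "LDL", "HDL", "total cholesterol", "triglycerides")
}

#' Orient every instrument to its exposure-raising allele
#'
#' Records with a negative exposure effect have effect/other alleles
#' swapped, `eaf` replaced by `1 - eaf` and `gamma_hat` negated, so that
#' after orientation all `gamma_hat >= 0` and the effect allele is the
#' CRP-raising allele. Idempotent. Dosage matrices counted on the old
#' allele must be recoded with [flip_dosages()] using the `"flipped"`
#' attribute.
#'
#' @param variants instrument data.frame.
#' @return oriented data.frame with attribute `flipped` (ids whose alleles
#'   were swapped).
#' @export
orient_effect_alleles <- function(variants) {
  neg <- !is.na(variants$gamma_hat) & variants$gamma_hat < 0
  if (any(neg)) {
    ea <- variants$effect_allele[neg]
    variants$effect_allele[neg] <- variants$other_allele[neg]
    variants$other_allele[neg] <- ea
    variants$eaf[neg] <- 1 - variants$eaf[neg]
    variants$gamma_hat[neg] <- -variants$gamma_hat[neg]
  }
  attr(variants, "flipped") <- variants$variant_id[neg]
  variants
}

#' Instrument-strength F-statistic
#'
#' `F = (r2 / (1 - r2)) * ((n - k - 1) / k)` for `k` instruments jointly
#' explaining a fraction `r2` of the exposure variance in a sample of `n`;
#' instruments with `F < 10` are conventionally flagged weak.
#'
#' @param r2 variance fraction in `[0, 1)`.
#' @param n sample size, `n > k + 1`.
#' @param k number of instruments, `>= 1`.
#' @return list with `F` and logical `weak` (`F < 10`).
#' @export
f_statistic <- function(r2, n, k) {
  if (r2 < 0 || r2 >= 1) stop_bad_arg("r2 must lie in [0, 1)")
  if (k < 1) stop_bad_arg("k must be >= 1")
  if (n <= k + 1) stop_bad_arg("need n > k + 1")
  F <- (r2 / (1 - r2)) * ((n - k - 1) / k)
  list(F = F, weak = F < 10)
}
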