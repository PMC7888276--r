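#' Default effect-modifier stratification specs
#'
#' The hypothesis-driven modifier set with its conventional cutoffs:
#' obesity (BMI >= 30 kg/m2; WHR > 0.85), physical activity
#' (MET >= 10 h/wk), diet (>= 9% of calories from saturated fat;
#' alcohol >= 14 g/day, one drink), smoking (>= 15 cigarettes/day),
#' depressive symptoms (CES-D scale >= 0.06), family history of breast
#' cancer, and exogenous-hormone durations: estrogen-only and
#' estrogen+progestin in 5-year bins from non-use to >= 15 years, oral
#' contraceptives split at the 5-year median. Duration bins are half-open
#' `[a, b)`; 0 years is its own "non-use" category.
#'
#' @return named list of stratum specs (variable, kind, cutoffs, labels).
#' @export
default_strata <- function() {
  bin <- function(variable, cutoff, side, labels)
    list(variable = variable, kind = "binary-cut", cutoffs = cutoff,
         side = side, labels = labels)
  dur <- function(variable, breaks, labels)
    list(variable = variable, kind = "duration-bins", cutoffs = breaks,
         labels = labels)
  e_breaks <- c(5, 10, 15)
  e_labels <- c("non-use", "<5 years", "5-<10 years", "10-<15 years",
                ">=15 years")
  list(
    bmi = bin("bmi", 30, "ge", c("BMI <30", "BMI >=30")),
    whr = bin("whr", 0.85, "gt", c("WHR <=0.85", "WHR >0.85")),
    met = bin("met_hr_wk", 10, "ge", c("MET <10", "MET >=10")),
    sfa = bin("sfa_pct", 9, "ge", c("SFA <9%", "SFA >=9%")),
    cesd = bin("cesd", 0.06, "ge", c("CES-D <0.06", "CES-D >=0.06")),
    smoking = bin("cigarettes_day", 15, "ge",
                  c("<15 cigarettes/day", ">=15 cigarettes/day")),
    alcohol = bin("alcohol_g_day", 14, "ge",
                  c("alcohol <14 g/day", "alcohol >=14 g/day")),
    family_history = list(variable = "family_history", kind = "category",
                          cutoffs = NULL, labels = c("no", "yes")),
    e_only = dur("e_only_yrs", e_breaks, e_labels),
    e_p = dur("e_p_yrs", e_breaks, e_labels),
    oc = dur("oc_yrs", 5, c("non-use", "<5 years", ">=5 years"))
  )
}

#' Assign cohort rows to the strata of one spec
#'
#' @param cohort data.frame.
#' @param spec one element of [default_strata()] (or the same shape).
#' @return factor of stratum labels (NA where the variable is missing).
#' @export
apply_stratum <- function(cohort, spec) {
  x <- cohort[[spec$variable]]
  if (is.null(x)) stop_bad_arg("cohort lacks column '%s'", spec$variable)
  lab <- switch(spec$kind,
    "binary-cut" = {
      hit <- if (identical(spec$side, "gt")) x > spec$cutoffs else x >= spec$cutoffs
      ifelse(hit, spec$labels[2], spec$labels[1])
    },
    "duration-bins" = {
      bins <- cut(x, c(0, spec$cutoffs, Inf), right = FALSE,
                  labels = spec$labels[-1])
      out <- as.character(bins)
      out[!is.na(x) & x == 0] <- spec$labels[1]
      out
    },
    "category" = spec$labels[as.integer(factor(x))],
    stop_bad_arg("unknown stratum kind '%s'", spec$kind))
  factor(lab, levels = spec$labels)
}

#' One-sample MR on a cohort subset
#'
#' The per-scale analysis chain: per-variant Cox scan (with sub-study
#' pooling), Wald ratios against the instruments' published exposure
#' effects, and the summary-statistic estimators — run separately for
#' each exposure scale present among the instruments (binary-log-odds and
#' log-continuous instruments are never pooled in one estimator run).
#'
#' @param cohort,genotypes,variants as elsewhere.
#' @param stage adjustment stage (1 or 2).
#' @param methods estimators to run (see [mr_fit()]).
#' @param exclude_pleiotropy drop tagged instruments first (default FALSE).
#' @param boot_reps,seed WM/PWM bootstrap settings.
#' @param by_substudy passed to [snp_outcome_scan()].
#' @return named list of `mr_fit` objects, one per exposure scale present.
#' @export
mr_onesample <- function(cohort, genotypes, variants, stage = 1L,
                         methods = c("ivw", "wm", "pwm", "egger"),
                         exclude_pleiotropy = FALSE,
                         boot_reps = 1000L, seed = 1L, by_substudy = NULL) {
  if (exclude_pleiotropy) variants <- exclude_pleiotropic(variants)
  scan <- snp_outcome_scan(cohort, genotypes, variants, stage = stage,
                           by_substudy = by_substudy)
  fits <- list()
  scales <- unique(variants$exposure_scale %||% "log-continuous")
  for (sc in scales) {
    v <- if ("exposure_scale" %in% names(variants))
      variants[variants$exposure_scale == sc, , drop = FALSE] else variants
    m <- merge(v[, c("variant_id", "gamma_hat", "se_gamma")],
               scan[, c("variant_id", "log_hr", "se")], by = "variant_id")
    if (nrow(m) < 1L) next
    fits[[sc]] <- mr_fit(m$gamma_hat, m$se_gamma, m$log_hr, m$se,
                         variant_id = m$variant_id, methods = methods,
                         boot_reps = boot_reps, seed = seed,
                         exposure_scale = sc)
  }
  attr(fits, "scan") <- scan
  fits
}

fits_to_rows <- function(fits, stratum, stage, pleio_excluded) {
  do.call(rbind, lapply(names(fits), function(sc) {
    tab <- mr_fit_table(fits[[sc]])
    if (is.null(tab)) return(NULL)
    cbind(data.frame(stratum = stratum, stage = stage,
                     exposure_scale = sc,
                     pleiotropy_excluded = pleio_excluded,
                     stringsAsFactors = FALSE),
          tab)
  }))
}

#' Stratified one-sample MR across effect-modifier specs
#'
#' Partitions the cohort by each stratification spec and reruns the whole
#' per-SNP Cox + MR chain inside every stratum, for each requested
#' adjustment stage and pleiotropy-exclusion setting. Strata with fewer
#' events than `min_events` are skipped and reported in the `skipped`
#' attribute; rows with a missing modifier are excluded and counted.
#'
#' @param cohort,genotypes,variants as elsewhere.
#' @param specs list of stratum specs (default [default_strata()] filtered
#'   to variables present in `cohort`).
#' @param stages adjustment stages to run (default 1).
#' @param methods estimators (see [mr_fit()]).
#' @param pleiotropy_exclusion logical vector of settings to run
#'   (default FALSE only).
#' @param min_events minimum events per stratum (default 10).
#' @param boot_reps,seed WM/PWM bootstrap settings.
#' @return data.frame of results, one row per (stratum level, stage,
#'   exposure scale, method, exclusion flag); attributes `skipped`
#'   (data.frame of skipped strata with reasons) and `missing_counts`.
#' @export
run_stratified_mr <- function(cohort, genotypes, variants, specs = NULL,
                              stages = 1L,
                              methods = c("ivw", "wm", "pwm", "egger"),
                              pleiotropy_exclusion = FALSE,
                              min_events = 10L, boot_reps = 1000L,
                              seed = 1L) {
  specs <- specs %||%
    Filter(function(s) s$variable %in% names(cohort), default_strata())
  out <- list(); skipped <- list(); missing_counts <- integer(0)
  for (spec_name in names(specs)) {
    spec <- specs[[spec_name]]
    f <- apply_stratum(cohort, spec)
    missing_counts[spec_name] <- sum(is.na(f))
    for (lev in levels(f)) {
      idx <- which(!is.na(f) & f == lev)
      lev_lab <- paste0(spec$variable, ": ", lev)
      n_ev <- sum(cohort$event[idx])
      if (n_ev < min_events) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(stratum = lev_lab, n = length(idx), events = n_ev,
                     reason = sprintf("fewer than %d events", min_events),
                     stringsAsFactors = FALSE)
        next
      }
      for (stage in stages) for (px in pleiotropy_exclusion) {
        fits <- tryCatch(
          mr_onesample(cohort[idx, , drop = FALSE],
                       genotypes[idx, , drop = FALSE], variants,
                       stage = stage, methods = methods,
                       exclude_pleiotropy = px,
                       boot_reps = boot_reps, seed = seed),
          error = function(e) {
            skipped[[length(skipped) + 1L]] <<-
              data.frame(stratum = lev_lab, n = length(idx), events = n_ev,
                         reason = conditionMessage(e),
                         stringsAsFactors = FALSE)
            NULL
          })
        if (is.null(fits)) next
        out[[length(out) + 1L]] <- fits_to_rows(fits, lev_lab, stage, px)
      }
    }
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else NULL
  attr(res, "missing_counts") <- missing_counts
  res
}

#' Cause-specific subtype analysis
#'
#' Restricts the outcome to events of one molecular subtype: events of the
#' target subtype keep `event = 1`; events of any other subtype are
#' treated as censored at their diagnosis time (cause-specific hazards);
#' then the standard per-SNP Cox + MR chain runs.
#'
#' @param cohort,genotypes,variants as elsewhere.
#' @param subtype one of "ERPR-positive", "ERPR-negative",
#'   "HER2-positive", "HER2-negative".
#' @param ... passed to [mr_onesample()].
#' @return named list of `mr_fit` objects (one per exposure scale), with
#'   the recoded event count in attribute `n_target_events`.
#' @export
subtype_analysis <- function(cohort, genotypes, variants,
                             subtype = c("ERPR-positive", "ERPR-negative",
                                         "HER2-positive", "HER2-negative"),
                             ...) {
  subtype <- match.arg(subtype)
  col <- if (startsWith(subtype, "ERPR")) "erpr_status" else "her2_status"
  want <- if (endsWith(subtype, "positive")) "positive" else "negative"
  is_target <- cohort$event == 1L & !is.na(cohort[[col]]) &
    cohort[[col]] == want
  if (!any(is_target))
    stop_bad_arg("no events of subtype %s", subtype)
  cohort$event <- as.integer(is_target)
  fits <- mr_onesample(cohort, genotypes, variants, ...)
  attr(fits, "n_target_events") <- sum(is_target)
  fits
}

#' Benjamini-Hochberg adjustment within analysis families
#'
#' Step-up false-discovery-rate correction applied separately within each
#' family (e.g. all strata of one modifier shown in one figure), with the
#' original order restored.
#'
#' @param p p-values in `[0, 1]`.
#' @param family optional grouping vector (same length as `p`); `NULL`
#'   treats all p-values as one family.
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p, family = NULL) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop_bad_arg("p-values must lie in [0, 1]")
  if (is.null(family)) return(p.adjust(p, method = "BH"))
  out <- p
  for (g in split(seq_along(p), family))
    out[g] <- p.adjust(p[g], method = "BH")
  out
}

#' Write a tidy results table and a machine-readable manifest
#'
#' Formats a stratified-results data.frame (as from
#' [run_stratified_mr()]) with an `HR (95% CI)` display column, writes it
#' as TSV, and writes a JSON manifest recording the configuration, seeds
#' and package version for reproducibility.
#'
#' @param results results data.frame.
#' @param file TSV path (NULL returns the formatted table invisibly).
#' @param manifest list of run metadata (config, seeds, ...); written to
#'   `<file>.manifest.json` when `file` is given.
#' @return the formatted table, invisibly.
#' @export
render_results <- function(results, file = NULL, manifest = list()) {
  tab <- results
  tab$hr_ci <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$hr_low, tab$hr_high)
  if (!is.null(file)) {
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$package_version <- as.character(utils::packageVersion("crpmr"))
    manifest$written <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, paste0(file, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(tab)
}
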