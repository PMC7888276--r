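#' Simulate a set of genetic instruments with known ground truth
#'
#' Draws `n_variants` independent variants with effect-allele frequencies in
#' `maf_range` and per-allele effects on log CRP scaled so that the expected
#' variance explained, `sum(2*p*(1-p)*beta^2) / sd_log_crp^2`, equals
#' `target_r2` exactly. Effects are drawn with random sign and then oriented
#' through [orient_effect_alleles()] so every record reports the CRP-raising
#' allele as the effect allele (all `gamma_hat >= 0` on output).
#'
#' The first `n_binary_variants` records are labelled as coming from a
#' binary-exposure GWAS (log-odds of CRP > 3 mg/L per allele, reported as
#' 1.7 times the latent log-CRP effect, the usual probit-to-logit factor at
#' unit residual SD); the rest carry the natural-log continuous scale and are
#' attributed to three continuous-CRP source studies. Reported standard
#' errors are the usual GWAS approximation `sqrt(var_y / (2p(1-p) n))`.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return list with `variants` (a data.frame, one row per instrument, with
#'   columns variant_id, chrom, pos, effect_allele, other_allele, eaf,
#'   gamma_hat, se_gamma, exposure_scale, source_study, publication_year,
#'   pleiotropy_tags, ld_cluster) and `truth` (theta,
#'   per_variant_exposure_betas on the log-CRP scale, invalid_variant_ids,
#'   realized_r2).
#' @export
simulate_variants <- function(config, seed = config$seed) {
  validate_sim_config(config)
  J <- config$n_variants
  with_seed(seed, {
    eaf <- runif(J, config$maf_range[1], config$maf_range[2])
    raw <- rnorm(J) * (0.2 + rexp(J))          # heterogeneous effect sizes
    het <- 2 * eaf * (1 - eaf)
    denom <- sum(het * raw^2)
    if (config$target_r2 > 0 && denom <= 0)
      stop_bad_arg("target_r2 = %g is unreachable: instruments carry no variance",
                   config$target_r2)
    scale_c <- if (config$target_r2 > 0)
      sqrt(config$target_r2 * config$sd_log_crp^2 / denom) else 0
    beta <- raw * scale_c
    alleles <- t(vapply(seq_len(J), function(i) sample(c("A", "C", "G", "T"), 2L),
                        character(2L)))
    n_bin <- config$n_binary_variants
    scale_lab <- rep("log-continuous", J)
    study <- rep(c("CONT-GWAS-A", "CONT-GWAS-B", "CONT-GWAS-C"), length.out = J)
    year <- c("CONT-GWAS-A" = 2011L, "CONT-GWAS-B" = 2016L,
              "CONT-GWAS-C" = 2018L)[study]
    if (n_bin > 0L) {
      scale_lab[seq_len(n_bin)] <- "binary-logodds"
      study[seq_len(n_bin)] <- "COHORT-GWAS"
      year[seq_len(n_bin)] <- 2019L
    }
    resid_var <- config$sd_log_crp^2 * (1 - config$target_r2)
    gamma_hat <- ifelse(scale_lab == "binary-logodds", 1.7 * beta, beta)
    n_gwas <- ifelse(scale_lab == "binary-logodds", 1e4, config$sumstats_exposure_n)
    var_y <- ifelse(scale_lab == "binary-logodds", pi^2 / 3, config$sd_log_crp^2)
    se_gamma <- sqrt(var_y / (het * n_gwas))
    variants <- data.frame(
      variant_id = sprintf("rs%06d", seq_len(J)),
      chrom = sample(1:22, J, replace = TRUE),
      pos = sample.int(1e8, J),
      effect_allele = alleles[, 1],
      other_allele = alleles[, 2],
      eaf = eaf,
      gamma_hat = gamma_hat,
      se_gamma = se_gamma,
      exposure_scale = scale_lab,
      source_study = study,
      publication_year = as.integer(year),
      pleiotropy_tags = "",
      ld_cluster = NA_integer_,
      stringsAsFactors = FALSE
    )
    oriented <- orient_effect_alleles(variants)
    flipped <- attr(oriented, "flipped")
    beta[variants$variant_id %in% flipped] <- -beta[variants$variant_id %in% flipped]
    truth <- list(theta = config$causal_effect_theta,
                  per_variant_exposure_betas =
                    setNames(beta, variants$variant_id),
                  invalid_variant_ids = character(0),
                  realized_r2 = config$target_r2)
    list(variants = oriented, truth = truth)
  })
}

#' Simulate genotype dosages under Hardy-Weinberg proportions
#'
#' Dosages are Binomial(2, eaf) counts of the (oriented) effect allele,
#' independent across variants by default. An optional block structure
#' induces linkage disequilibrium through a Gaussian copula: variants are
#' grouped into consecutive blocks of `ld_block_size` sharing a latent
#' pairwise correlation `ld_r` (used to exercise LD pruning).
#'
#' @param variants data.frame from [simulate_variants()] (needs
#'   `variant_id` and `eaf`).
#' @param n number of individuals (> 0).
#' @param seed RNG seed.
#' @param ld_r,ld_block_size optional LD block generator (see above).
#' @return integer dosage matrix, n x variants, columns named by variant_id.
#' @export
simulate_genotypes <- function(variants, n, seed = 1L,
                               ld_r = 0, ld_block_size = 1L) {
  if (nrow(variants) == 0L) stop_bad_arg("variants must be non-empty")
  if (n <= 0) stop_bad_arg("n must be positive")
  J <- nrow(variants)
  with_seed(seed, {
    if (ld_r == 0 || ld_block_size <= 1L) {
      g <- vapply(variants$eaf, function(p) rbinom(n, 2L, p), integer(n))
    } else {
      block <- (seq_len(J) - 1L) %/% ld_block_size
      g <- matrix(0L, n, J)
      for (b in unique(block)) {
        idx <- which(block == b)
        shared <- rnorm(n)
        for (j in idx) {
          z <- sqrt(ld_r) * shared + sqrt(1 - ld_r) * rnorm(n)
          # two latent draws per chromosome copy would be exact; one shared
          # draw per genotype is enough to create prunable correlation
          g[, j] <- as.integer(stats::qbinom(pnorm(z), 2L, variants$eaf[j]))
        }
      }
    }
    dimnames(g) <- list(NULL, variants$variant_id)
    g
  })
}

#' Flip dosages to the opposite allele
#'
#' After [orient_effect_alleles()] swaps a record's alleles, dosages counted
#' on the old effect allele must be recounted on the new one: `2 - dosage`.
#'
#' @param genotypes dosage matrix with variant_id column names.
#' @param variant_ids variants to flip (e.g. `attr(oriented, "flipped")`).
#' @return the matrix with the named columns flipped.
#' @export
flip_dosages <- function(genotypes, variant_ids) {
  hit <- intersect(colnames(genotypes), variant_ids)
  if (length(hit)) genotypes[, hit] <- 2 - genotypes[, hit, drop = FALSE]
  genotypes
}
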