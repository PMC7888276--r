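#' Simulate two-sample GWAS summary statistics with known invalidity
#'
#' Generates, per variant, a noisy exposure effect `gamma_hat ~
#' N(beta_j, se_gamma)` and a noisy outcome effect `big_gamma_hat ~
#' N(theta * beta_j + pleiotropy_shift * invalid_j, se_big_gamma)`.
#' The invalid set is chosen (given the seed) so that it carries as close
#' as possible to `invalid_fraction` of the total inverse-variance weight
#' `beta_j^2 / se_big_gamma^2` — the weight fraction that matters for the
#' breakdown behaviour of median-based estimators. Standard errors follow
#' the usual GWAS approximations at the configured effective sample sizes.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data.frame with variant_id, beta_true, invalid, gamma_hat,
#'   se_gamma, big_gamma_hat, se_big_gamma; the true theta and invalid ids
#'   are attached as attributes `truth`.
#' @export
simulate_summary_stats <- function(config, seed = config$seed) {
  validate_sim_config(config)
  v <- simulate_variants(config, seed = seed)
  beta <- unname(v$truth$per_variant_exposure_betas)
  het <- 2 * v$variants$eaf * (1 - v$variants$eaf)
  se_gamma <- sqrt(config$sd_log_crp^2 / (het * config$sumstats_exposure_n))
  se_big_gamma <- sqrt(1 / (het * config$sumstats_outcome_events))
  J <- config$n_variants
  with_seed(seed + 1L, {
    invalid <- rep(FALSE, J)
    if (config$invalid_fraction > 0) {
      w <- beta^2 / se_big_gamma^2
      ord <- sample.int(J)
      cumfrac <- cumsum(w[ord]) / sum(w)
      k <- which.min(abs(cumfrac - config$invalid_fraction))
      if (cumfrac[k] > 0 || config$invalid_fraction > 0)
        invalid[ord[seq_len(k)]] <- TRUE
      # degenerate request: fraction ~0 rounds to the single closest subset
      if (abs(cumfrac[k] - config$invalid_fraction) >
          abs(0 - config$invalid_fraction)) invalid[] <- FALSE
    }
    gamma_hat <- rnorm(J, beta, se_gamma)
    big_gamma_hat <- rnorm(J, config$causal_effect_theta * beta +
                             config$pleiotropy_shift * invalid, se_big_gamma)
    out <- data.frame(variant_id = v$variants$variant_id,
                      beta_true = beta,
                      invalid = invalid,
                      gamma_hat = gamma_hat,
                      se_gamma = se_gamma,
                      big_gamma_hat = big_gamma_hat,
                      se_big_gamma = se_big_gamma,
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- list(theta = config$causal_effect_theta,
                               invalid_variant_ids =
                                 v$variants$variant_id[invalid])
    out
  })
}
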