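# Shared fixtures, built in code. The default cohort is expensive enough
# to be worth caching across test files.

small_config <- function(...) {
  sim_config(n_individuals = 1500L, n_variants = 8L, n_binary_variants = 0L,
             seed = 11L, ...)
}

.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_env$default))
    .fixture_env$default <- simulate_cohort(sim_config(seed = 42L))
  .fixture_env$default
}

# a bare instruments table for curation tests
toy_variants <- function(n = 5, gamma = seq(0.1, by = 0.05, length.out = n),
                         se = rep(0.02, n)) {
  data.frame(
    variant_id = sprintf("rs%03d", seq_len(n)),
    chrom = 1L, pos = seq_len(n) * 1000L,
    effect_allele = rep("A", n), other_allele = rep("G", n),
    eaf = seq(0.2, 0.4, length.out = n),
    gamma_hat = gamma, se_gamma = se,
    exposure_scale = "log-continuous", source_study = "STUDY-X",
    publication_year = 2018L, pleiotropy_tags = "",
    ld_cluster = NA_integer_, stringsAsFactors = FALSE)
}

# minimal survival data with no adjustment covariates
toy_survival <- function(times, events, dosages, substudy = NULL) {
  d <- data.frame(followup_years = times, event = events,
                  stringsAsFactors = FALSE)
  if (!is.null(substudy)) d$substudy <- substudy
  g <- matrix(dosages, ncol = 1, dimnames = list(NULL, "rs001"))
  list(cohort = d, genotypes = g)
}

# evaluate code under a local seed without touching the global stream
with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# independent step-up BH implementation (oracle; intentionally naive)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    adj[o[i]] <- min(1, min(cands))
  }
  adj
}

# independent cumulative-weight walk for the weighted median (oracle)
wm_walk_oracle <- function(b, w) {
  o <- order(b); b <- b[o]; w <- w[o] / sum(w)
  s <- 0
  p_prev <- NA_real_; b_prev <- NA_real_
  for (j in seq_along(b)) {
    p_j <- s + w[j] / 2
    if (p_j >= 0.5) {
      if (j == 1L) return(b[1])
      return(b_prev + (b[j] - b_prev) * (0.5 - p_prev) / (p_j - p_prev))
    }
    p_prev <- p_j; b_prev <- b[j]
    s <- s + w[j]
  }
  b[length(b)]
}
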