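make_dosage <- function(n0, n1, n2, id = "rs001") {
  matrix(rep(c(0, 1, 2), c(n0, n1, n2)), ncol = 1,
         dimnames = list(NULL, id))
}

test_that("HWE chi-square matches the closed form on exact and extreme counts", {
  hw <- hwe_test(make_dosage(25, 50, 25)[, 1])
  expect_equal(unname(hw["chisq"]), 0)
  expect_equal(unname(hw["p"]), 1)
  hw2 <- hwe_test(make_dosage(50, 0, 50)[, 1])
  expect_equal(unname(hw2["chisq"]), 100)   # equals n for no hets at p = 0.5
  expect_lt(unname(hw2["p"]), 1e-4)
})

test_that("qc_filter applies all three thresholds as documented", {
  g_ok <- make_dosage(25, 50, 25)
  expect_true("rs001" %in% qc_filter(g_ok)$retained)
  expect_false("rs001" %in% qc_filter(make_dosage(50, 0, 50))$retained)
  g_miss <- g_ok
  g_miss[1:3, 1] <- NA      # 3% missing
  expect_false("rs001" %in% qc_filter(g_miss)$retained)
  meta <- data.frame(variant_id = "rs001", impute_r2 = 0.5)
  expect_false("rs001" %in% qc_filter(g_ok, meta)$retained)
  meta$impute_r2 <- NA      # treated as genotyped: passes
  expect_true("rs001" %in% qc_filter(g_ok, meta)$retained)
  expect_warning(qc_filter(make_dosage(50, 0, 50)), "every variant")
})

test_that("qc decisions are monotone in the thresholds", {
  set.seed(31)
  g <- sapply(runif(12, 0.1, 0.5), function(p) rbinom(300, 2, p))
  colnames(g) <- sprintf("v%02d", 1:12)
  g[sample(length(g), 40)] <- NA
  meta <- data.frame(variant_id = colnames(g), impute_r2 = runif(12, 0.4, 1))
  strict <- qc_filter(g, meta, max_missing = 0.01, hwe_p_min = 0.05,
                      min_impute_r2 = 0.8)$retained
  loose <- qc_filter(g, meta, max_missing = 0.05, hwe_p_min = 1e-6,
                     min_impute_r2 = 0.5)$retained
  expect_true(all(strict %in% loose))
})

test_that("LD pruning keeps independent variants and drops correlated ones", {
  v <- toy_variants(3, gamma = c(0.3, 0.2, 0.1))
  cm <- diag(3); dimnames(cm) <- list(v$variant_id, v$variant_id)
  expect_setequal(prune_ld(v, cor_matrix = cm), v$variant_id)
  # two perfectly correlated variants: only the stronger-association one kept
  cm2 <- matrix(c(1, 1, 1, 1), 2, 2,
                dimnames = list(v$variant_id[1:2], v$variant_id[1:2]))
  expect_identical(prune_ld(v[1:2, ], cor_matrix = cm2), "rs001")
})

test_that("greedy pruning equals the rank-order oracle on 5-variant problems", {
  oracle <- function(v, cm, thr) {
    ord <- order(-abs(v$gamma_hat / v$se_gamma), v$variant_id)
    ids <- v$variant_id[ord]
    best <- NULL
    for (mask in 0:(2^length(ids) - 1)) {        # enumerate every subset
      sel <- ids[bitwAnd(mask, 2^(seq_along(ids) - 1)) > 0]
      ok <- TRUE
      for (id in ids) {                          # greedy-consistency check
        earlier <- intersect(sel, ids[seq_len(match(id, ids) - 1)])
        should_take <- !length(earlier) || all(cm[id, earlier]^2 < thr)
        if (should_take != (id %in% sel)) { ok <- FALSE; break }
      }
      if (ok) best <- sel
    }
    best
  }
  set.seed(51)
  for (rep in 1:10) {
    v <- toy_variants(5, gamma = runif(5, 0.05, 0.4))
    L <- matrix(rnorm(25), 5)
    cm <- cov2cor(crossprod(L) + diag(5) * 0.5)
    dimnames(cm) <- list(v$variant_id, v$variant_id)
    expect_setequal(prune_ld(v, cor_matrix = cm, threshold = 0.3),
                    oracle(v, cm, 0.3))
  }
})

test_that("pruned output is maximal under its greedy order", {
  set.seed(52)
  v <- toy_variants(8, gamma = runif(8, 0.05, 0.4))
  g <- simulate_genotypes(v, 1500L, seed = 5L, ld_r = 0.8, ld_block_size = 2L)
  kept <- prune_ld(v, g, threshold = 0.3)
  cm <- cor(g)
  for (id in setdiff(v$variant_id, kept))
    expect_true(any(cm[id, kept]^2 >= 0.3))
})

test_that("constant dosage columns are excluded from pruning with a warning", {
  v <- toy_variants(2)
  g <- cbind(rs001 = rbinom(100, 2, 0.3), rs002 = rep(1L, 100))
  expect_warning(kept <- prune_ld(v, g), "constant")
  expect_identical(kept, "rs001")
})

test_that("cross-study merge keeps the most recent record and logs the rest", {
  v <- toy_variants(1)
  dup <- v; dup$publication_year <- 2011L; dup$gamma_hat <- 0.4
  merged <- merge_studies(rbind(v, dup))
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$publication_year, 2018L)
  expect_equal(attr(merged, "dropped")$publication_year, 2011L)
  # no duplicates: identity
  v5 <- toy_variants(5)
  expect_equal(merge_studies(v5), v5, ignore_attr = TRUE)
})

test_that("swapped-allele duplicates are harmonised by an allele flip", {
  v <- toy_variants(1)                      # A/G, gamma 0.1, eaf 0.2
  dup <- v
  dup$effect_allele <- "G"; dup$other_allele <- "A"
  dup$eaf <- 0.8; dup$gamma_hat <- -0.1; dup$publication_year <- 2020L
  merged <- merge_studies(rbind(v, dup))
  expect_equal(nrow(merged), 1L)
  # the 2020 record wins and is reported in the 2018 record's orientation
  expect_equal(merged$effect_allele, "A")
  expect_equal(merged$gamma_hat, 0.1)
  expect_equal(merged$eaf, 0.2)
  bad <- v; bad$effect_allele <- "T"; bad$other_allele <- "C"
  bad$publication_year <- 2020L
  expect_error(merge_studies(rbind(v, bad)), "harmonise")
})

test_that("pleiotropy-tagged instruments are excluded by trait list", {
  v <- toy_variants(60, gamma = runif(60, 0.02, 0.3))
  v$pleiotropy_tags[c(3, 10, 25, 41)] <- c("T2DM", "BMI", "LDL",
                                           "2-h glucose;triglycerides")
  kept <- exclude_pleiotropic(v)
  expect_equal(nrow(kept), 56L)
  expect_setequal(attr(kept, "excluded"), v$variant_id[c(3, 10, 25, 41)])
  expect_equal(nrow(exclude_pleiotropic(v, character(0))), 60L)
})

test_that("allele orientation flips negative effects and is idempotent", {
  v <- toy_variants(2, gamma = c(-0.1, 0.2))
  v$eaf <- c(0.3, 0.4)
  o <- orient_effect_alleles(v)
  expect_equal(o$gamma_hat, c(0.1, 0.2))
  expect_equal(o$eaf, c(0.7, 0.4))
  expect_equal(o$effect_allele[1], "G")
  expect_identical(attr(o, "flipped"), "rs001")
  o2 <- orient_effect_alleles(o)
  expect_equal(o2, o, ignore_attr = TRUE)
  expect_length(attr(o2, "flipped"), 0)
})

test_that("the F-statistic follows its closed form and flags weak sets", {
  expect_equal(f_statistic(0, 100, 5)$F, 0)
  expect_true(f_statistic(0, 100, 5)$weak)
  expect_equal(f_statistic(0.06, 10179, 6)$F, 108.2, tolerance = 1e-3)
  expect_equal(f_statistic(0.5, 12, 1)$F, 10)
  expect_false(f_statistic(0.5, 12, 1)$weak)
  # monotone: increasing in r2 and n, decreasing in k
  expect_gt(f_statistic(0.10, 500, 5)$F, f_statistic(0.05, 500, 5)$F)
  expect_gt(f_statistic(0.05, 1000, 5)$F, f_statistic(0.05, 500, 5)$F)
  expect_lt(f_statistic(0.05, 500, 10)$F, f_statistic(0.05, 500, 5)$F)
  expect_error(f_statistic(1, 100, 5), "r2")
  expect_error(f_statistic(0.05, 6, 5), "n >")
})
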