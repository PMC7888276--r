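#' Read and write instrument summary-statistics tables
#'
#' The interchange format is a TSV with header columns variant_id, chrom,
#' pos, effect_allele, other_allele, eaf, beta, se, scale, study, year,
#' pleiotropy_tags (semicolon-separated trait labels, may be empty).
#' Internally beta/se/scale/study/year map to gamma_hat / se_gamma /
#' exposure_scale / source_study / publication_year.
#'
#' @param path file path.
#' @return `read_instruments`: the instruments data.frame.
#' @export
read_instruments <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(d$pleiotropy_tags))
    d$pleiotropy_tags <- ifelse(is.na(d$pleiotropy_tags), "",
                                as.character(d$pleiotropy_tags))
  need <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta",
            "se", "scale", "study", "year")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_bad_arg("instruments file lacks column(s): %s",
                 paste(miss, collapse = ", "))
  out <- data.frame(
    variant_id = d$variant_id,
    chrom = d$chrom %||% NA, pos = d$pos %||% NA,
    effect_allele = d$effect_allele, other_allele = d$other_allele,
    eaf = d$eaf, gamma_hat = d$beta, se_gamma = d$se,
    exposure_scale = d$scale, source_study = d$study,
    publication_year = as.integer(d$year),
    pleiotropy_tags = d$pleiotropy_tags %||% "",
    ld_cluster = d$ld_cluster %||% NA_integer_,
    stringsAsFactors = FALSE)
  if (any(!is.finite(out$se_gamma)) || any(out$se_gamma <= 0))
    stop_bad_arg("se must be positive")
  out
}

#' @rdname read_instruments
#' @param variants instruments data.frame (internal column names).
#' @export
write_instruments <- function(variants, path) {
  d <- data.frame(
    variant_id = variants$variant_id,
    chrom = variants$chrom, pos = variants$pos,
    effect_allele = variants$effect_allele,
    other_allele = variants$other_allele,
    eaf = variants$eaf, beta = variants$gamma_hat, se = variants$se_gamma,
    scale = variants$exposure_scale, study = variants$source_study,
    year = variants$publication_year,
    pleiotropy_tags = variants$pleiotropy_tags %||% "",
    stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write genotype dosage matrices as TSV
#'
#' Rows are individuals, columns are variants; the first column is
#' `individual_id`.
#'
#' @param genotypes dosage matrix with variant_id colnames.
#' @param path file path.
#' @param individual_id optional ids (default `id000001`, ...).
#' @export
write_dosage_tsv <- function(genotypes, path, individual_id = NULL) {
  ids <- individual_id %||% sprintf("id%06d", seq_len(nrow(genotypes)))
  d <- data.frame(individual_id = ids, genotypes, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- NULL
  storage.mode(m) <- "numeric"
  attr(m, "individual_id") <- d[[1]]
  m
}

#' Write genotype dosages as a minimal dosage VCF
#'
#' VCFv4.2 with a single FORMAT field `DS` (expected alternate-allele
#' dosage); one sample column per individual. The effect allele is written
#' as ALT, the other allele as REF, matching the convention that dosages
#' count the (CRP-raising) effect allele.
#'
#' @param genotypes dosage matrix (columns = variants).
#' @param variants instruments data.frame supplying CHROM/POS/alleles.
#' @param path output path (plain text).
#' @param individual_id optional sample names.
#' @export
write_dosage_vcf <- function(genotypes, variants, path,
                             individual_id = NULL) {
  ids <- individual_id %||% sprintf("id%06d", seq_len(nrow(genotypes)))
  v <- variants[match(colnames(genotypes), variants$variant_id), ]
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT (effect) allele\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$other_allele[j],
            v$effect_allele[j], ".", "PASS", ".", "DS",
            format(genotypes[, j], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a dosage VCF back into a matrix (requires vcfR)
#'
#' @param path VCF path (plain text or gz).
#' @return dosage matrix, individuals x variants.
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_bad_arg("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  m <- t(ds)
  rownames(m) <- NULL
  m
}

#' Write a JSON run manifest
#'
#' Records the simulation configuration, seed and ground-truth parameters
#' alongside generated data files so a run can be reproduced and audited.
#'
#' @param config a [sim_config()].
#' @param truth optional ground-truth list from [simulate_variants()].
#' @param path output path.
#' @export
write_manifest <- function(config, truth = NULL, path) {
  payload <- list(config = unclass(config), seed = config$seed,
                  truth = truth,
                  package_version =
                    as.character(utils::packageVersion("crpmr")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}

#' Write the phenotype/covariate table as CSV
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
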