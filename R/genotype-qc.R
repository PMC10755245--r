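#' Genotype QC thresholds
#'
#' Defaults follow standard array QC: exclude SNPs with minor-allele
#' frequency below 1%, call rate below 95% or Hardy-Weinberg equilibrium
#' p below 1e-5, and samples with more than 5% missing calls. All
#' comparisons are strict (`<` / `>`).
#'
#' @param maf_min Minimum minor-allele frequency.
#' @param call_rate_min Minimum per-SNP call rate.
#' @param hwe_p_min Minimum HWE p-value.
#' @param sample_missing_max Maximum per-sample missingness.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(maf_min = 0.01, call_rate_min = 0.95,
                          hwe_p_min = 1e-5, sample_missing_max = 0.05) {
  for (v in c("maf_min", "call_rate_min", "hwe_p_min", "sample_missing_max")) {
    check_number(get(v), v, 0, 1)
  }
  structure(
    list(
      maf_min = maf_min, call_rate_min = call_rate_min,
      hwe_p_min = hwe_p_min, sample_missing_max = sample_missing_max
    ),
    class = "qc_thresholds"
  )
}

#' Hardy-Weinberg equilibrium test
#'
#' Pearson chi-square goodness-of-fit (1 df, no continuity correction)
#' of observed genotype counts against the Hardy-Weinberg proportions
#' implied by the sample allele frequency. Monomorphic SNPs return p = 1
#' by convention. Vectorized over count triples.
#'
#' @param n_AA,n_Aa,n_aa Genotype-class counts (homozygote, heterozygote,
#'   other homozygote), each >= 0 with a positive total.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == length(n_Aa), length(n_Aa) == length(n_aa))
  if (any(n_AA < 0 | n_Aa < 0 | n_aa < 0)) {
    stop_bagprs("genotype counts must be non-negative.", "bagprs_invalid_counts")
  }
  n <- n_AA + n_Aa + n_aa
  if (any(n == 0)) {
    stop_bagprs("total genotype count must be positive.", "bagprs_invalid_counts")
  }
  p <- (2 * n_AA + n_Aa) / (2 * n)
  e_AA <- n * p^2
  e_Aa <- n * 2 * p * (1 - p)
  e_aa <- n * (1 - p)^2
  chi2 <- ifelse(
    p == 0 | p == 1,
    0,
    (n_AA - e_AA)^2 / e_AA + (n_Aa - e_Aa)^2 / e_Aa + (n_aa - e_aa)^2 / e_aa
  )
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Apply SNP- and sample-level QC filters
#'
#' Samples with missingness above `sample_missing_max` are dropped first;
#' MAF, call rate and HWE are then computed on the retained samples and SNPs
#' failing any filter are removed. A SNP failing several filters is
#' attributed to its first failure in the order MAF, call rate, HWE.
#'
#' @param geno A [geno_matrix].
#' @param thresholds A [qc_thresholds].
#' @return A `qc_result` list: `genotypes` (filtered [geno_matrix]) and
#'   `report` with in/out counts, per-filter exclusion counts (first-failure
#'   and any-failure), dropped sample ids and the per-SNP QC table.
#' @export
qc_filter <- function(geno, thresholds = qc_thresholds()) {
  stopifnot(inherits(geno, "geno_matrix"), inherits(thresholds, "qc_thresholds"))
  d <- geno$dosage
  if (nrow(d) == 0 || ncol(d) == 0) {
    stop_bagprs("genotype matrix is empty.", "bagprs_invalid_geno")
  }

  sample_miss <- rowMeans(is.na(d))
  keep_sample <- sample_miss <= thresholds$sample_missing_max
  if (!any(keep_sample)) {
    stop_bagprs("all samples removed by QC.", "bagprs_empty_after_qc")
  }
  g1 <- subset_geno(geno, samples = which(keep_sample))

  st <- snp_stats(g1)
  st$hwe_p <- hwe_test(st$n_AA, st$n_Aa, st$n_aa)
  fail_maf <- st$maf < thresholds$maf_min
  fail_cr <- st$call_rate < thresholds$call_rate_min
  fail_hwe <- st$hwe_p < thresholds$hwe_p_min
  st$fail_reason <- dplyr::case_when(
    fail_maf ~ "maf",
    fail_cr ~ "call_rate",
    fail_hwe ~ "hwe",
    TRUE ~ NA_character_
  )
  st$pass <- is.na(st$fail_reason)
  if (!any(st$pass)) {
    stop_bagprs("all SNPs removed by QC.", "bagprs_empty_after_qc")
  }

  out <- subset_geno(g1, snps = which(st$pass))
  report <- list(
    n_samples_in = nrow(d), n_samples_out = nrow(out$dosage),
    n_snps_in = ncol(d), n_snps_out = ncol(out$dosage),
    samples_removed = rownames(d)[!keep_sample],
    exclusions = tibble::tibble(
      filter = c("maf", "call_rate", "hwe"),
      first_failure = c(
        sum(st$fail_reason == "maf", na.rm = TRUE),
        sum(st$fail_reason == "call_rate", na.rm = TRUE),
        sum(st$fail_reason == "hwe", na.rm = TRUE)
      ),
      any_failure = c(sum(fail_maf), sum(fail_cr), sum(fail_hwe))
    ),
    n_snps_failed_any = sum(!st$pass),
    snp_table = st,
    thresholds = thresholds
  )
  structure(list(genotypes = out, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<qc_result> samples %d -> %d, SNPs %d -> %d (maf %d, call_rate %d, hwe %d)\n",
    r$n_samples_in, r$n_samples_out, r$n_snps_in, r$n_snps_out,
    r$exclusions$first_failure[1], r$exclusions$first_failure[2],
    r$exclusions$first_failure[3]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qc_result <- function(x, ...) x$report$snp_table

#' @exportS3Method generics::glance
glance.qc_result <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_samples_in = r$n_samples_in, n_samples_out = r$n_samples_out,
    n_snps_in = r$n_snps_in, n_snps_out = r$n_snps_out,
    n_snps_failed = r$n_snps_failed_any
  )
}
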