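#' Genotype dosage container
#'
#' Holds a samples-by-SNPs additive dosage matrix (values 0/1/2, `NA` for a
#' missing call) together with per-SNP metadata. Rows are named by subject id
#' and columns by SNP id; the metadata tibble carries chromosome, 1-based
#' position and the effect/other allele labels used to orient scoring.
#'
#' @param dosage Numeric matrix, samples x SNPs, values in \{0, 1, 2, NA\},
#'   with row and column names.
#' @param snps Tibble with columns `snp`, `chr`, `pos`, `ea`, `oa`, one row
#'   per column of `dosage`, in the same order.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, snps) {
  if (!is.matrix(dosage) || !is.numeric(dosage)) {
    stop_bagprs("`dosage` must be a numeric matrix.", "bagprs_invalid_geno")
  }
  needed <- c("snp", "chr", "pos", "ea", "oa")
  if (!all(needed %in% names(snps))) {
    stop_bagprs(
      paste0("`snps` must have columns: ", paste(needed, collapse = ", "), "."),
      "bagprs_invalid_geno"
    )
  }
  if (nrow(snps) != ncol(dosage)) {
    stop_bagprs("`snps` must have one row per dosage column.", "bagprs_invalid_geno")
  }
  if (is.null(colnames(dosage))) colnames(dosage) <- snps$snp
  if (!identical(colnames(dosage), as.character(snps$snp))) {
    stop_bagprs("dosage column names must match `snps$snp`.", "bagprs_invalid_geno")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%05d", seq_len(nrow(dosage)))
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2)) {
    stop_bagprs("dosages must lie in [0, 2].", "bagprs_invalid_geno")
  }
  structure(
    list(dosage = dosage, snps = tibble::as_tibble(snps)),
    class = "geno_matrix"
  )
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs (%.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage), 100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' Per-SNP summary statistics
#'
#' Minor-allele frequency (computed on non-missing calls), call rate and
#' genotype-class counts for each SNP.
#'
#' @param geno A [geno_matrix].
#' @return Tibble with one row per SNP: `snp`, `chr`, `pos`, `maf`,
#'   `call_rate`, `n_AA`, `n_Aa`, `n_aa` (counts of dosage 2/1/0).
#' @export
snp_stats <- function(geno) {
  d <- geno$dosage
  n_obs <- colSums(!is.na(d))
  afreq <- colMeans(d, na.rm = TRUE) / 2
  afreq[n_obs == 0] <- NA_real_
  dplyr::mutate(
    geno$snps[, c("snp", "chr", "pos")],
    maf = pmin(afreq, 1 - afreq),
    call_rate = n_obs / nrow(d),
    n_AA = colSums(d == 2, na.rm = TRUE),
    n_Aa = colSums(d == 1, na.rm = TRUE),
    n_aa = colSums(d == 0, na.rm = TRUE)
  )
}

#' Effect-allele frequency on non-missing calls
#' @noRd
effect_allele_freq <- function(geno) {
  colMeans(geno$dosage, na.rm = TRUE) / 2
}

subset_geno <- function(geno, samples = NULL, snps = NULL) {
  d <- geno$dosage
  meta <- geno$snps
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    meta <- meta[snps, , drop = FALSE]
  }
  geno_matrix(d, meta)
}

#' Read / write a dosage table
#'
#' The on-disk form is TSV: a `subject` column followed by one numeric column
#' per SNP (`NA` for missing). SNP metadata travels in a sidecar tibble.
#'
#' @param geno A [geno_matrix].
#' @param path Output TSV path for dosages.
#' @param snp_path Output TSV path for the SNP metadata table.
#' @return `write_dosage_tsv()` returns `geno` invisibly; `read_dosage_tsv()`
#'   returns a [geno_matrix].
#' @export
write_dosage_tsv <- function(geno, path, snp_path) {
  tab <- tibble::as_tibble(geno$dosage)
  tab <- dplyr::bind_cols(tibble::tibble(subject = rownames(geno$dosage)), tab)
  readr::write_tsv(tab, path)
  readr::write_tsv(geno$snps, snp_path)
  invisible(geno)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path, snp_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  snps <- readr::read_tsv(snp_path, show_col_types = FALSE)
  d <- as.matrix(tab[, -1, drop = FALSE])
  rownames(d) <- tab$subject
  geno_matrix(d, snps)
}
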