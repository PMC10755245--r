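#' Configure a synthetic cohort simulation
#'
#' The generator emulates the causal chain the downstream analysis assumes:
#' genotypes in linkage-disequilibrium (LD) blocks, a true polygenic score
#' driving a smoking liability, pack-years accumulating for smokers, and
#' age- plus smoking-driven gray-matter atrophy spread over brain regions.
#'
#' @param n_subjects Number of target-cohort subjects.
#' @param n_snps Number of SNPs.
#' @param n_causal Number of SNPs with non-zero effect on smoking liability.
#' @param ld_block_size SNPs per LD block; blocks are mutually independent.
#' @param within_block_corr Latent Gaussian correlation within a block, in
#'   `[0, 1)`; induces dosage LD via a thresholded copula.
#' @param maf_range Minor-allele-frequency range, each in `(0, 0.5]`.
#' @param missing_rate Per-call missingness rate (completely at random).
#' @param h2_liability Proportion of smoking-liability variance explained by
#'   the true polygenic score, in `[0, 1]`.
#' @param smoking_prevalence Ever-smoker fraction (liability threshold).
#' @param n_regions Number of gray-matter regions (166 by default).
#' @param atrophy_age_slope Volume loss per region per year of age
#'   (mm^3/year, negative).
#' @param atrophy_packyear_slope Whole-brain volume loss per pack-year
#'   (mm^3/pack-year, negative); spread uniformly over regions.
#' @param noise_sd_region Per-region residual volume SD (mm^3).
#' @param age_range Age range in years.
#' @param discovery_n Discovery-GWAS sample size used to set the sampling
#'   error of the simulated summary statistics.
#' @param seed Integer seed; a fixed seed yields identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 2000,
                       n_snps = 1000,
                       n_causal = 50,
                       ld_block_size = 10,
                       within_block_corr = 0.6,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.01,
                       h2_liability = 0.3,
                       smoking_prevalence = 0.56,
                       n_regions = 166,
                       atrophy_age_slope = -3,
                       atrophy_packyear_slope = -40,
                       noise_sd_region = 50,
                       age_range = c(44, 81),
                       discovery_n = 5e4,
                       seed = 1L) {
  check_count(n_subjects, "n_subjects")
  check_count(n_snps, "n_snps")
  check_count(n_causal, "n_causal", min = 0L)
  check_count(ld_block_size, "ld_block_size")
  check_count(n_regions, "n_regions")
  check_count(discovery_n, "discovery_n")
  check_number(within_block_corr, "within_block_corr", 0, 1 - 1e-9)
  check_number(missing_rate, "missing_rate", 0, 1)
  check_number(h2_liability, "h2_liability", 0, 1)
  check_number(smoking_prevalence, "smoking_prevalence", 0, 1)
  check_number(noise_sd_region, "noise_sd_region", 0)
  if (n_causal > n_snps) {
    stop_bagprs("`n_causal` cannot exceed `n_snps`.", "bagprs_invalid_config")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_bagprs("`maf_range` must be (min, max) within (0, 0.5].", "bagprs_invalid_config")
  }
  if (length(age_range) != 2 || age_range[1] >= age_range[2]) {
    stop_bagprs("`age_range` must be (min, max) with min < max.", "bagprs_invalid_config")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
      n_causal = as.integer(n_causal), ld_block_size = as.integer(ld_block_size),
      within_block_corr = within_block_corr, maf_range = maf_range,
      missing_rate = missing_rate, h2_liability = h2_liability,
      smoking_prevalence = smoking_prevalence, n_regions = as.integer(n_regions),
      atrophy_age_slope = atrophy_age_slope,
      atrophy_packyear_slope = atrophy_packyear_slope,
      noise_sd_region = noise_sd_region, age_range = age_range,
      discovery_n = as.integer(discovery_n), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate genotype dosages in LD blocks
#'
#' Two latent allele draws per subject share a block-constant Gaussian
#' correlation (`within_block_corr`); each latent value is thresholded at the
#' allele-frequency quantile so every SNP is in Hardy-Weinberg proportions
#' marginally while adjacent SNPs in a block carry dosage LD. Positions are
#' spaced so a block spans under 250 kb and consecutive blocks are separated
#' by 1 Mb (no cross-block LD and no cross-block clumping window overlap).
#'
#' @param config A [sim_config].
#' @return A [geno_matrix] with MCAR missingness at `config$missing_rate`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  m <- config$n_snps
  bs <- config$ld_block_size
  rho <- config$within_block_corr

  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  block <- ceiling(seq_len(m) / bs)
  n_block <- max(block)

  dosage <- matrix(0L, n, m)
  for (gamete in 1:2) {
    shared <- matrix(rnorm(n * n_block), n, n_block)
    z <- sqrt(rho) * shared[, block, drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
    dosage <- dosage + (z < matrix(qnorm(maf), n, m, byrow = TRUE))
  }
  storage.mode(dosage) <- "double"
  if (config$missing_rate > 0) {
    dosage[matrix(runif(n * m) < config$missing_rate, n, m)] <- NA_real_
  }

  within_bp <- min(5000L, max(1L, 240000L %/% bs))
  offset_in_block <- (seq_len(m) - 1L) %% bs
  pos <- (block - 1L) * 1000000L + offset_in_block * within_bp + 1L

  snps <- tibble::tibble(
    snp = sprintf("snp%05d", seq_len(m)),
    chr = 1L, pos = as.integer(pos), ea = "A", oa = "G"
  )
  rownames(dosage) <- sprintf("S%05d", seq_len(n))
  colnames(dosage) <- snps$snp
  geno_matrix(dosage, snps)
}

#' Simulate discovery-GWAS summary statistics
#'
#' Adds sampling noise to true per-SNP effects at the standard error a
#' discovery sample of `discovery_n` unrelated individuals would give for an
#' additive dosage regression: `se_j = 1 / sqrt(2 MAF_j (1 - MAF_j) N)`.
#' Two-sided Wald p-values are attached.
#'
#' @param geno A [geno_matrix] supplying MAF and allele labels.
#' @param true_effects Numeric vector of per-SNP true effects (0 = null).
#' @param discovery_n Discovery sample size (> 0).
#' @param seed Integer seed.
#' @return Tibble with columns `snp`, `chr`, `pos`, `ea`, `oa`, `beta`,
#'   `se`, `p`.
#' @export
simulate_discovery_gwas <- function(geno, true_effects, discovery_n, seed = 1L) {
  if (length(true_effects) != ncol(geno$dosage)) {
    stop_bagprs("`true_effects` must have one entry per SNP.", "bagprs_invalid_config")
  }
  check_count(discovery_n, "discovery_n")
  set.seed(as.integer(seed))
  maf <- pmin(effect_allele_freq(geno), 1 - effect_allele_freq(geno))
  maf <- pmax(maf, 1e-6)
  se <- 1 / sqrt(2 * maf * (1 - maf) * discovery_n)
  beta_hat <- true_effects + rnorm(length(se), 0, se)
  dplyr::mutate(
    geno$snps,
    beta = beta_hat,
    se = se,
    p = 2 * pnorm(-abs(beta_hat / se))
  )
}

#' Simulate a full synthetic cohort
#'
#' Generative chain: (1) a true polygenic score over the causal SNPs; (2) a
#' smoking liability in which the score explains `h2_liability` of the
#' variance (plus small sex/BMI terms and Gaussian noise), thresholded at the
#' `1 - smoking_prevalence` quantile to define ever-smokers; (3) pack-years
#' increasing in liability for smokers, exactly 0 for never-smokers, with a
#' former-smoker subset carrying a quit duration; (4) regional gray-matter
#' volumes with a linear age slope per region, the whole-brain pack-year
#' slope spread over regions, small covariate effects and region noise. Total
#' gray-matter volume (`tgmv`) is the exact sum of the regional columns.
#'
#' @param config A [sim_config].
#' @return A `synthetic_cohort`: list with `genotypes` ([geno_matrix]),
#'   `true_effects`, `summary_stats` (discovery GWAS tibble), `cohort`
#'   (per-subject tibble incl. `rgmv_*` columns) and `region_baselines`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  geno <- simulate_genotypes(config)
  true_effects <- numeric(config$n_snps)

  set.seed(config$seed + 1000L)
  if (config$n_causal > 0) {
    causal <- sort(sample.int(config$n_snps, config$n_causal))
    true_effects[causal] <- rnorm(config$n_causal, 0, 0.05)
  }
  stats <- simulate_discovery_gwas(
    geno, true_effects, config$discovery_n, seed = config$seed + 2000L
  )

  set.seed(config$seed + 3000L)
  n <- config$n_subjects
  dos <- geno$dosage
  eaf <- effect_allele_freq(geno)
  dos_imp <- sweep_impute(dos, 2 * eaf)
  s_raw <- as.numeric(dos_imp %*% true_effects)
  s_std <- if (sd(s_raw) > 0) as.numeric(scale(s_raw)) else s_raw

  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- rbinom(n, 1, 0.5)
  ethnicity <- rbinom(n, 1, 0.95)
  handedness <- rbinom(n, 1, 0.9)
  bmi <- rnorm(n, 27, 4)
  alcohol <- rbinom(n, 1, 0.6)
  site <- sample(1:3, n, replace = TRUE)
  education <- sample(1:5, n, replace = TRUE)
  pcs <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("pc", 1:5)))

  # liability: genetic part explains h2; small covariate terms; noise fills
  # the remainder so total non-genetic variance is 1 - h2
  cov_term <- 0.1 * (sex - 0.5) + 0.02 * (bmi - 27)
  noise_var <- max(1 - config$h2_liability - var(cov_term), 0.02)
  liability <- sqrt(config$h2_liability) * s_std + cov_term +
    rnorm(n, 0, sqrt(noise_var))

  smoker <- liability > quantile(liability, 1 - config$smoking_prevalence)
  pack_years <- numeric(n)
  pack_years[smoker] <- pmax(
    0, 20 + 8 * as.numeric(scale(liability))[smoker] + rnorm(sum(smoker), 0, 8)
  )
  status <- rep("never", n)
  former <- smoker & (runif(n) < 0.55)
  status[smoker] <- "current"
  status[former] <- "former"
  quit_years <- numeric(n)
  quit_years[former] <- runif(sum(former), 1, 30)

  tiv <- rnorm(n, 1.45e6, 1.2e5) + 8e4 * (sex - 0.5)

  k <- config$n_regions
  baselines <- rnorm(k, 3600, 600)
  region <- matrix(baselines, n, k, byrow = TRUE) +
    config$atrophy_age_slope * age +
    (config$atrophy_packyear_slope / k) * pack_years +
    30 * (sex - 0.5) + 5e-4 * (tiv - 1.45e6) +
    matrix(rnorm(n * k, 0, config$noise_sd_region), n, k)
  colnames(region) <- sprintf("rgmv_%03d", seq_len(k))

  cohort <- dplyr::bind_cols(
    tibble::tibble(
      subject = rownames(dos), age = age, sex = sex, ethnicity = ethnicity,
      handedness = handedness, bmi = bmi, alcohol = alcohol, site = site,
      education = education
    ),
    tibble::as_tibble(pcs),
    tibble::tibble(
      true_score = s_std, liability = liability, smoker = smoker,
      smoking_status = status, pack_years = pack_years,
      quit_years = quit_years, tiv = tiv
    ),
    tibble::as_tibble(region)
  )
  cohort$tgmv <- rowSums(region)

  structure(
    list(
      genotypes = geno, true_effects = true_effects, summary_stats = stats,
      cohort = cohort, region_baselines = baselines, config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects, %d SNPs (%d causal), %d regions; %.1f%% smokers\n",
    nrow(x$cohort), ncol(x$genotypes$dosage), sum(x$true_effects != 0),
    x$config$n_regions, 100 * mean(x$cohort$smoker)
  ))
  invisible(x)
}

#' Synthetic gene annotation for enrichment testing
#'
#' Builds one gene interval (0-based half-open, BED convention) around each
#' LD block of a simulated SNP panel plus a set of random gene-set
#' memberships, so the SNP-to-gene mapping and over-representation stages can
#' run on simulated data. Labelled synthetic; no real genome coordinates.
#'
#' @param snps SNP metadata tibble (`snp`, `chr`, `pos`).
#' @param n_sets Number of gene sets.
#' @param set_size_range Genes per set (min, max).
#' @param seed Integer seed.
#' @return List with `intervals` (tibble `chrom`, `start`, `end`, `gene`) and
#'   `sets` (named list of gene-id vectors).
#' @export
simulate_gene_annotation <- function(snps, n_sets = 20,
                                     set_size_range = c(5, 25), seed = 1L) {
  set.seed(as.integer(seed))
  block <- floor((snps$pos - 1) / 1000000L)
  keys <- unique(paste(snps$chr, block, sep = ":"))
  gene_ids <- sprintf("GENE%04d", seq_along(keys))
  span <- vapply(keys, function(kk) {
    sel <- paste(snps$chr, block, sep = ":") == kk
    range(snps$pos[sel])
  }, numeric(2))
  intervals <- tibble::tibble(
    chrom = as.integer(sub(":.*", "", keys)),
    start = pmax(0L, as.integer(span[1, ]) - 1001L),
    end = as.integer(span[2, ]) + 1000L,
    gene = gene_ids
  )
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets, replace = TRUE)
  sizes <- pmin(sizes, length(gene_ids))
  sets <- lapply(sizes, function(sz) sample(gene_ids, sz))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  list(intervals = intervals, sets = sets)
}

# column-wise mean imputation with supplied fill values
sweep_impute <- function(d, fill) {
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- fill[idx[, 2]]
  d
}
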