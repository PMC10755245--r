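two_snp_stats <- function(pos2, p1 = 1e-8, p2 = 1e-4) {
  tibble::tibble(
    snp = c("s001", "s002"), chr = 1L, pos = c(100000L, as.integer(pos2)),
    ea = "A", oa = "G", beta = c(0.1, 0.1), p = c(p1, p2)
  )
}

test_that("clumping keeps the stronger SNP and respects the physical window", {
  set.seed(21)
  d <- correlated_dosages(400, 0.8)
  g_near <- make_geno(d, pos = c(100000L, 150000L))   # 50 kb apart
  st <- two_snp_stats(150000L)
  expect_equal(clump(st, g_near)$snp, "s001")

  g_far <- make_geno(d, pos = c(100000L, 400000L))    # 300 kb apart
  st_far <- two_snp_stats(400000L)
  expect_equal(clump(st_far, g_far)$snp, c("s001", "s002"))

  # single SNP is its own index
  g1 <- make_geno(cbind(rbinom(100, 2, 0.3)))
  st1 <- tibble::tibble(snp = "s001", chr = 1L, pos = 1000L, ea = "A",
                        oa = "G", beta = 0.2, p = 0.01)
  expect_equal(clump(st1, g1)$snp, "s001")

  # panel-missing SNP policy
  st_extra <- dplyr::bind_rows(
    st1, tibble::tibble(snp = "absent", chr = 1L, pos = 2000L, ea = "A",
                        oa = "G", beta = 0, p = 0.5)
  )
  expect_warning(out <- clump(st_extra, g1), "absent")
  expect_equal(out$snp, "s001")
  expect_error(clump(st_extra, g1, missing_policy = "error"),
               class = "bagprs_missing_snp")
})

test_that("clumping matches the set-based greedy oracle on random panels", {
  for (s in 1:25) {
    set.seed(s)
    n <- 150; m <- 20
    d <- matrix(NA_real_, n, m)
    base <- rnorm(n)
    for (j in seq_len(m)) {
      rho <- runif(1, 0, 0.95)
      z1 <- rho * base + sqrt(1 - rho^2) * rnorm(n)
      z2 <- rho * base + sqrt(1 - rho^2) * rnorm(n)
      thr <- qnorm(runif(1, 0.1, 0.5))
      d[, j] <- (z1 < thr) + (z2 < thr)
    }
    pos <- sort(sample.int(600000L, m))
    g <- make_geno(d, pos = pos)
    st <- dplyr::mutate(g$snps, beta = rnorm(m), p = runif(m))
    got <- clump(st, g, r2_cutoff = 0.1, window_kb = 250)$snp
    want <- oracle_clump(st, g$dosage, r2_cutoff = 0.1, window_kb = 250)
    expect_identical(got, want)
  }
})

test_that("scoring follows the averaged effect-allele formula with mean imputation", {
  st <- tibble::tibble(
    snp = c("s001", "s002"), chr = 1L, pos = c(1000L, 2000L),
    ea = "A", oa = "G", beta = c(0.5, -0.2), p = c(0.001, 0.001)
  )
  g <- make_geno(rbind(c(2, 1), c(0, 0)), pos = c(1000L, 2000L))

  one <- prs_score(g, st, "s001", p_threshold = 0.05)
  expect_equal(one$score[1], 0.5 * 2 / 1)
  expect_equal(attr(one, "n_snps_used"), 1L)

  both <- prs_score(g, st, c("s001", "s002"), p_threshold = 0.05)
  expect_equal(both$score[1], (0.5 * 2 - 0.2 * 1) / 2)
  raw <- prs_score(g, st, c("s001", "s002"), p_threshold = 0.05, average = FALSE)
  expect_equal(raw$score, both$score * 2)

  # missing call imputed with 2 * target MAF (here 0.25 -> dosage 0.5)
  d <- cbind(c(NA, 1, 1, 0, 0))
  gm <- make_geno(d)
  stm <- tibble::tibble(snp = "s001", chr = 1L, pos = 1000L, ea = "A",
                        oa = "G", beta = 0.4, p = 0.001)
  sc <- prs_score(gm, stm, "s001", 0.05)
  expect_equal(sc$score[1], 0.4 * 0.5)

  # swapped alleles flip the dosage to 2 - G
  st_flip <- dplyr::mutate(stm, ea = "G", oa = "A")
  g2 <- make_geno(cbind(c(2, 0, 1, 1)))
  expect_equal(prs_score(g2, st_flip, "s001", 0.05)$score,
               0.4 * (2 - c(2, 0, 1, 1)))

  # mismatched alleles are skipped, and an empty score errors
  st_bad <- dplyr::mutate(stm, ea = "T", oa = "C")
  expect_warning(
    expect_error(prs_score(g2, st_bad, "s001", 0.05),
                 class = "bagprs_empty_score"),
    "mismatched"
  )
  expect_error(prs_score(g2, stm, "s001", 1e-10), class = "bagprs_empty_score")
})

test_that("partial correlation residualizes covariates correctly", {
  x <- rnorm(50)
  expect_equal(partial_correlation(x, x)$r, 1)

  set.seed(33)
  c0 <- rnorm(2000)
  x <- c0 + rnorm(2000)
  y <- c0 + 0.5 * rnorm(2000)  # shared variance lives entirely in c0
  expect_lt(abs(partial_correlation(x, y, cbind(c = c0))$r), 0.05)
  # without adjustment the shared driver dominates
  expect_gt(partial_correlation(x, y)$r, 0.5)

  expect_error(partial_correlation(rnorm(4), rnorm(4), matrix(rnorm(8), 4)),
               class = "bagprs_underdetermined")
})

test_that("partial correlation p-values are uniform under the null", {
  set.seed(1234)
  ps <- replicate(200, partial_correlation(rnorm(500), rnorm(500))$p)
  expect_gte(mean(ps < 0.05), 0.01)
  expect_lte(mean(ps < 0.05), 0.10)
})

test_that("threshold scan ranks thresholds and z-scores the optimum", {
  set.seed(55)
  cfg <- sim_config(n_subjects = 600, n_snps = 150, n_causal = 25,
                    n_regions = 5, seed = 55)
  sc <- simulate_cohort(cfg)
  cl <- clump(sc$summary_stats, sc$genotypes)
  scan <- threshold_scan(
    sc$genotypes, sc$summary_stats, cl$snp,
    phenotype = as.numeric(sc$cohort$smoker),
    covariates = sc$cohort[, c("age", "sex", "bmi")]
  )
  thr <- tidy(scan)
  expect_equal(nrow(thr), 100)
  # SNP count is monotone non-decreasing in the threshold
  expect_true(all(diff(thr$n_snps_used) >= 0))
  expect_equal(mean(scan$optimal$prs_z), 0, tolerance = 1e-9)
  expect_equal(sd(scan$optimal$prs_z), 1, tolerance = 1e-9)
  expect_equal(length(scan$selected_thresholds), 10)
  expect_equal(scan$optimal_threshold,
               thr$p_t[which.max(abs(thr$r))])

  # a one-point grid selects that point
  single <- threshold_scan(sc$genotypes, sc$summary_stats, cl$snp,
                           as.numeric(sc$cohort$smoker), grid = 0.3)
  expect_equal(single$optimal_threshold, 0.3)
})

test_that("the scan recovers an early threshold and the score's sign on causal cohorts", {
  hits <- 0; signs <- 0; reps <- 10
  for (s in 1:reps) {
    # moderate discovery power: causal SNPs reach small p-values while null
    # weights remain large enough that lax thresholds dilute the score
    cfg <- sim_config(n_subjects = 1000, n_snps = 200, n_causal = 30,
                      h2_liability = 0.5, n_regions = 5,
                      discovery_n = 15000, seed = 100 + s)
    sc <- simulate_cohort(cfg)
    cl <- clump(sc$summary_stats, sc$genotypes)
    scan <- threshold_scan(sc$genotypes, sc$summary_stats, cl$snp,
                           phenotype = sc$cohort$liability)
    if (scan$optimal_threshold <= 0.05) hits <- hits + 1
    if (cor(scan$optimal$prs_z, sc$cohort$liability) > 0) signs <- signs + 1
  }
  expect_gte(hits, ceiling(0.8 * reps))
  expect_equal(signs, reps)
})
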