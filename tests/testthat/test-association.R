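test_that("association model recovers coefficients under covariate adjustment", {
  set.seed(12)
  x <- rnorm(200)
  row <- suppressWarnings(glm_association(2 * x, x))  # exact fit by design
  expect_equal(row$beta, 2, tolerance = 1e-10)
  expect_lt(row$p, 1e-100)

  # outcome = x + c with independent covariate c: beta on x is exactly 1
  n <- 500
  c0 <- rnorm(n); x0 <- rnorm(n)
  row2 <- suppressWarnings(glm_association(x0 + c0, x0, cbind(c = c0)))
  expect_equal(row2$beta, 1, tolerance = 1e-8)

  expect_error(glm_association(rnorm(50), x0[1:50], cbind(dup = x0[1:50])),
               class = "bagprs_collinear")

  # logistic route returns a finite slope on a separable-ish signal
  yb <- rbinom(n, 1, stats::plogis(x0))
  rowb <- glm_association(yb, x0, family = "binomial")
  expect_gt(rowb$beta, 0)
  expect_lt(rowb$p, 0.01)
})

test_that("association p-values are uniform under the null", {
  set.seed(77)
  ps <- replicate(200, glm_association(rnorm(300), rnorm(300))$p)
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("group comparison computes classical Cohen's d with Welch p", {
  g1 <- c(1, 2, 3); g2 <- c(3, 4, 5)
  cmp <- two_sample_comparison(g1, g2)
  expect_equal(cmp$cohens_d, -2)           # means 2 vs 4, pooled SD 1
  swapped <- two_sample_comparison(g2, g1)
  expect_equal(swapped$cohens_d, 2)
  expect_equal(swapped$p, cmp$p)

  same <- two_sample_comparison(g1, g1)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p, 1)

  expect_error(two_sample_comparison(c(1, 1), c(1, 1)), class = "bagprs_degenerate")
  expect_error(two_sample_comparison(1, g1), class = "bagprs_invalid_config")
})

test_that("BH adjustment matches the step-up oracle and its bounds", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_fdr(numeric(0)), numeric(0))

  set.seed(99)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
  }
})

test_that("region-wise scan flags planted signal and stays quiet under the null", {
  # null: false positives at q < 0.05 are rare
  fp <- 0
  for (s in 1:5) {
    set.seed(s)
    prs <- rnorm(400)
    rv <- matrix(rnorm(400 * 20), 400, dimnames = list(NULL, paste0("r", 1:20)))
    fp <- fp + sum(regionwise_scan(prs, rv)$significant)
  }
  expect_lte(fp, 2)

  # a strong planted region ranks first
  wins <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    prs <- rnorm(400)
    rv <- matrix(rnorm(400 * 20), 400, dimnames = list(NULL, paste0("r", 1:20)))
    rv[, 7] <- rv[, 7] + 1.5 * prs
    tab <- regionwise_scan(prs, rv)
    if (tab$region[which.max(abs(tab$r))] == "r7") wins <- wins + 1
  }
  expect_gte(wins, 9)

  # alpha = 1 flags every testable region; constant regions go NA
  set.seed(5)
  rv <- cbind(a = rnorm(100), b = rep(1, 100))
  tab <- regionwise_scan(rnorm(100), rv, alpha = 1)
  expect_true(tab$significant[tab$region == "a"])
  expect_true(is.na(tab$r[tab$region == "b"]))
  expect_false(tab$significant[tab$region == "b"])
})

test_that("GWAS scan finds planted SNPs and derives Bonferroni thresholds from m", {
  set.seed(41)
  d <- sapply(1:50, function(i) rbinom(300, 2, 0.3))
  g <- make_geno(d)
  pheno <- 2 * d[, 17]
  res <- gwas_scan(g, pheno)
  expect_equal(res$table$snp[which.min(res$table$p)], "s017")
  expect_equal(res$m, 50)
  expect_equal(res$genomewide_threshold, 0.05 / 50)
  expect_equal(res$suggestive_threshold, 1 / 50)

  # monomorphic SNPs yield NA rows and are excluded from m
  d2 <- cbind(d[, 1:5], mono = rep(1, 300))
  g2 <- make_geno(d2)
  res2 <- gwas_scan(g2, rnorm(300))
  expect_true(is.na(res2$table$p[6]))
  expect_equal(res2$m, 5)

  # covariate-adjusted effect estimate matches a direct per-SNP lm fit
  set.seed(42)
  cv <- cbind(age = rnorm(300))
  y <- 0.4 * d[, 3] + 0.8 * cv[, 1] + rnorm(300)
  res3 <- gwas_scan(g, y, cv)
  ref <- summary(lm(y ~ d[, 3] + cv))$coefficients[2, ]
  expect_equal(res3$table$beta[3], unname(ref[1]), tolerance = 1e-10)
  expect_equal(res3$table$p[3], unname(ref[4]), tolerance = 1e-10)
})

test_that("demographic summary reports group and male percentages", {
  co <- tibble::tibble(
    smoker = rep(c(TRUE, FALSE), c(60, 40)),
    sex = c(rep(1, 30), rep(0, 30), rep(1, 10), rep(0, 30))
  )
  dem <- smoking_demographics(co)
  expect_equal(dem$pct[dem$group == "smoker"], 60)
  expect_equal(dem$male_pct[dem$group == "smoker"], 50)
  expect_equal(dem$pct[dem$group == "non-smoker"], 40)
  expect_equal(dem$male_pct[dem$group == "non-smoker"], 25)
})
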