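test_that("full mediation gives PM = 100% and the linear identity holds exactly", {
  set.seed(17)
  x <- rnorm(200)
  m <- 0.7 * x + rnorm(200, 0, 1e-6)  # identifiable but effectively noiseless
  y <- 0.9 * m
  res <- mediate(x, m, y, n_boot = 100, seed = 1)
  est <- setNames(res$estimates$estimate, res$estimates$term)
  expect_equal(res$pm, 100, tolerance = 1e-6)
  expect_equal(est[["tau_prime"]], 0, tolerance = 1e-8)
  expect_equal(est[["tau"]], est[["tau_prime"]] + est[["acme"]],
               tolerance = 1e-8)
})

test_that("mediation recovers generative path coefficients", {
  set.seed(23)
  n <- 2000
  x <- rnorm(n)
  m <- 0.5 * x + rnorm(n)
  y <- 0.4 * m + 0.3 * x + rnorm(n)
  res <- mediate(x, m, y, n_boot = 300, seed = 7)
  est <- setNames(res$estimates$estimate, res$estimates$term)
  expect_lt(abs(est[["acme"]] - 0.2), 0.05)
  expect_lt(abs(est[["tau_prime"]] - 0.3), 0.08)
  expect_equal(est[["tau"]], est[["tau_prime"]] + est[["acme"]],
               tolerance = 1e-8)
  # ACME interval excludes zero for a true indirect path
  ci <- res$estimates[res$estimates$term == "acme", ]
  expect_gt(ci$ci_lo, 0)
})

test_that("null-mediator intervals cover zero at the nominal rate", {
  covered <- 0
  for (s in 1:50) {
    set.seed(s)
    x <- rnorm(200); m <- rnorm(200); y <- 0.3 * x + rnorm(200)
    res <- mediate(x, m, y, n_boot = 200, seed = s)
    ci <- res$estimates[res$estimates$term == "acme", ]
    if (ci$ci_lo <= 0 && ci$ci_hi >= 0) covered <- covered + 1
  }
  expect_gte(covered, 45)
})

test_that("bootstrap intervals shrink with sample size", {
  width <- sapply(c(500, 4000), function(n) {
    set.seed(31)
    x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.4 * m + 0.3 * x + rnorm(n)
    res <- mediate(x, m, y, n_boot = 200, seed = 3)
    ci <- res$estimates[res$estimates$term == "acme", ]
    ci$ci_hi - ci$ci_lo
  })
  expect_lt(width[2], width[1])
})

test_that("parallel two-mediator model decomposes the indirect effect", {
  set.seed(37)
  n <- 2000
  x <- rnorm(n)
  m1 <- 0.5 * x + rnorm(n)
  m2 <- rnorm(n)                       # dead pathway
  y <- 0.4 * m1 + 0.3 * x + rnorm(n)
  two <- mediate_two(x, m1, m2, y, n_boot = 200, seed = 5)
  one <- mediate(x, m1, y, n_boot = 100, seed = 5)
  est2 <- setNames(two$estimates$estimate, two$estimates$term)
  est1 <- setNames(one$estimates$estimate, one$estimates$term)
  expect_equal(est2[["acme_total"]], est1[["acme"]], tolerance = 0.05)
  expect_equal(est2[["tau"]], est2[["tau_prime"]] + est2[["acme_total"]],
               tolerance = 1e-8)

  # symmetric pathways give near-equal per-mediator effects
  set.seed(39)
  n <- 5000
  x <- rnorm(n)
  ma <- 0.5 * x + rnorm(n); mb <- 0.5 * x + rnorm(n)
  ys <- 0.4 * ma + 0.4 * mb + rnorm(n)
  sym <- mediate_two(x, ma, mb, ys, n_boot = 100, seed = 9)
  es <- setNames(sym$estimates$estimate, sym$estimates$term)
  expect_gt(es[["acme1"]] / es[["acme2"]], 0.8)
  expect_lt(es[["acme1"]] / es[["acme2"]], 1.25)

  expect_error(mediate_two(x, ma, ma, ys), class = "bagprs_collinear")
})

test_that("covariates are regressed out of every path", {
  set.seed(43)
  n <- 1500
  c0 <- rnorm(n)
  x <- 0.8 * c0 + rnorm(n)
  m <- 0.8 * c0 + rnorm(n)       # m related to x only through the confounder
  y <- 0.8 * c0 + rnorm(n)
  adj <- mediate(x, m, y, covariates = cbind(c = c0), n_boot = 200, seed = 11)
  ci <- adj$estimates[adj$estimates$term == "acme", ]
  expect_true(ci$ci_lo <= 0 && ci$ci_hi >= 0)
  # unadjusted, the confounder masquerades as mediation
  raw <- mediate(x, m, y, n_boot = 200, seed = 11)
  raw_ci <- raw$estimates[raw$estimates$term == "acme", ]
  expect_gt(raw_ci$ci_lo, 0)
})

test_that("proportion mediated follows the printed formula with stability guards", {
  expect_equal(proportion_mediated(2, 1)$pm, 50)
  expect_equal(proportion_mediated(1.7, 1.7)$pm, 0)
  sup <- proportion_mediated(1, -0.2)
  expect_equal(sup$pm, 120)
  expect_true(sup$unstable)
  expect_false(proportion_mediated(2, 1)$unstable)
  expect_error(proportion_mediated(0, 1), class = "bagprs_degenerate")
})

test_that("degenerate mediation inputs are rejected", {
  x <- rnorm(50)
  expect_error(mediate(x, rep(1, 50), rnorm(50)), class = "bagprs_degenerate")
  expect_error(mediate(x[1:5], rnorm(5), rnorm(5)), class = "bagprs_invalid_config")
  expect_warning(mediate(x, rnorm(50), rnorm(50), n_boot = 50, seed = 1),
                 "bootstrap")
})
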