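#' Proportion mediated
#'
#' `PM = 100 * (tau - tau_prime) / tau`, the percentage of the total effect
#' carried by the mediator(s). Flagged unstable when the total effect is
#' near zero or the direct effect has the opposite sign (suppression), where
#' the percentage loses its interpretation.
#'
#' @param tau Total effect.
#' @param tau_prime Direct effect.
#' @param tol Magnitude below which `tau` is treated as zero.
#' @return Tibble (`pm`, `unstable`).
#' @export
proportion_mediated <- function(tau, tau_prime, tol = 1e-8) {
  if (tau == 0) stop_bagprs("total effect is zero: PM undefined.", "bagprs_degenerate")
  tibble::tibble(
    pm = 100 * (tau - tau_prime) / tau,
    unstable = abs(tau) < tol || sign(tau) != sign(tau_prime)
  )
}

# OLS coefficient extraction on [1 | C | terms]; returns named coefficients
path_coefs <- function(y, terms, cm) {
  design <- cbind(cm, terms)
  fit <- .lm.fit(design, y)
  setNames(fit$coefficients, colnames(design))
}

mediation_estimates_one <- function(x, m, y, cm) {
  a <- path_coefs(m, cbind(x = x), cm)[["x"]]
  cf <- path_coefs(y, cbind(x = x, m = m), cm)
  tau <- path_coefs(y, cbind(x = x), cm)[["x"]]
  c(acme = a * cf[["m"]], tau = tau, tau_prime = cf[["x"]])
}

mediation_estimates_two <- function(x, m1, m2, y, cm) {
  a1 <- path_coefs(m1, cbind(x = x), cm)[["x"]]
  a2 <- path_coefs(m2, cbind(x = x), cm)[["x"]]
  cf <- path_coefs(y, cbind(x = x, m1 = m1, m2 = m2), cm)
  tau <- path_coefs(y, cbind(x = x), cm)[["x"]]
  c(acme1 = a1 * cf[["m1"]], acme2 = a2 * cf[["m2"]],
    acme_total = a1 * cf[["m1"]] + a2 * cf[["m2"]],
    tau = tau, tau_prime = cf[["x"]])
}

# bias-corrected percentile interval
bc_ci <- function(boot, est, conf_level) {
  boot <- boot[is.finite(boot)]
  if (!length(boot) || length(unique(boot)) == 1L) return(c(NA_real_, NA_real_))
  prop <- mean(boot < est)
  prop <- min(max(prop, 1 / (length(boot) + 1)), length(boot) / (length(boot) + 1))
  z0 <- qnorm(prop)
  zq <- qnorm(c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
  unname(quantile(boot, pnorm(2 * z0 + zq), names = FALSE, type = 7))
}

mediate_core <- function(est_fun, vars, covariates, n_boot, seed, conf_level,
                         n_mediators) {
  n <- length(vars[[1]])
  lens <- vapply(vars, length, integer(1))
  if (any(lens != n)) stop_bagprs("all variables must have equal length.", "bagprs_invalid_config")
  if (n < 10) stop_bagprs("need at least 10 observations.", "bagprs_invalid_config")
  sds <- vapply(vars, sd, numeric(1))
  if (any(sds == 0)) {
    stop_bagprs("zero variance in x, a mediator, or y.", "bagprs_degenerate")
  }
  if (n_boot < 100) rlang::warn("fewer than 100 bootstrap samples: CIs will be unstable.")
  cm <- covariate_matrix(covariates, n)

  est <- do.call(est_fun, c(vars, list(cm = cm)))

  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    vb <- lapply(vars, function(v) v[idx])
    boot[b, ] <- tryCatch(
      do.call(est_fun, c(vb, list(cm = cm[idx, , drop = FALSE]))),
      error = function(e) rep(NA_real_, length(est))
    )
  }
  cis <- t(vapply(names(est), function(nm) bc_ci(boot[, nm], est[[nm]], conf_level),
                  numeric(2)))
  pm <- proportion_mediated(est[["tau"]], est[["tau_prime"]])
  structure(
    list(
      estimates = tibble::tibble(
        term = names(est), estimate = unname(est),
        ci_lo = cis[, 1], ci_hi = cis[, 2]
      ),
      pm = pm$pm, pm_unstable = pm$unstable,
      n = n, n_boot = n_boot, seed = as.integer(seed),
      conf_level = conf_level, n_mediators = n_mediators,
      boot = boot
    ),
    class = "mediation_result"
  )
}

#' Single-mediator mediation analysis
#'
#' Product-of-coefficients decomposition on linear models with all
#' covariates regressed out in every sub-model: `m ~ x + C` gives the `a`
#' path, `y ~ x + m + C` gives `b` and the direct effect `tau_prime`, and
#' `y ~ x + C` gives the total effect `tau`. The indirect effect (ACME) is
#' `a * b`; on linear models `tau = tau_prime + ACME` exactly. Inference is
#' by nonparametric case-resampling bootstrap with bias-corrected percentile
#' intervals (1000 resamples by default), and the proportion mediated is
#' `100 * (tau - tau_prime) / tau` on the point estimates.
#'
#' @param x Exposure vector (e.g. z-scored PRS).
#' @param m Mediator vector.
#' @param y Outcome vector.
#' @param covariates Optional covariate matrix / data frame.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return A `mediation_result`: `estimates` tibble (`term` in acme / tau /
#'   tau_prime, `estimate`, `ci_lo`, `ci_hi`), `pm`, `pm_unstable`, `n`,
#'   `n_boot`.
#' @export
mediate <- function(x, m, y, covariates = NULL, n_boot = 1000, seed = 1L,
                    conf_level = 0.95) {
  mediate_core(mediation_estimates_one, list(x = x, m = m, y = y),
               covariates, n_boot, seed, conf_level, n_mediators = 1L)
}

#' Parallel two-mediator mediation analysis
#'
#' Both mediators enter simultaneously and non-sequentially (no path between
#' them): `m1 ~ x + C`, `m2 ~ x + C`, `y ~ x + m1 + m2 + C`. Per-mediator
#' indirect effects are `a1*b1` and `a2*b2`; their sum is the total indirect
#' effect and `tau = tau_prime + a1*b1 + a2*b2` exactly on linear models.
#'
#' @param m1,m2 Mediator vectors (must not be collinear).
#' @inheritParams mediate
#' @return A `mediation_result` with terms acme1 / acme2 / acme_total / tau /
#'   tau_prime.
#' @export
mediate_two <- function(x, m1, m2, y, covariates = NULL, n_boot = 1000,
                        seed = 1L, conf_level = 0.95) {
  if (sd(m1) > 0 && sd(m2) > 0 && abs(cor(m1, m2)) > 1 - 1e-10) {
    stop_bagprs("mediators are collinear.", "bagprs_collinear")
  }
  mediate_core(mediation_estimates_two, list(x = x, m1 = m1, m2 = m2, y = y),
               covariates, n_boot, seed, conf_level, n_mediators = 2L)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> %d mediator(s), n = %d, %d bootstraps; PM = %.2f%%%s\n",
    x$n_mediators, x$n, x$n_boot, x$pm,
    if (x$pm_unstable) " (unstable)" else ""
  ))
  print(x$estimates)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mediation_result <- function(x, ...) x$estimates

#' @exportS3Method generics::glance
glance.mediation_result <- function(x, ...) {
  tibble::tibble(
    pm = x$pm, pm_unstable = x$pm_unstable, n = x$n, n_boot = x$n_boot,
    conf_level = x$conf_level, n_mediators = x$n_mediators
  )
}

#' @describeIn mediate Point estimates with bootstrap intervals.
#' @param object A `mediation_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.mediation_result <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "effect (outcome units per exposure unit)") +
    ggplot2::theme_minimal()
}
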