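#' Covariate-adjusted association model
#'
#' Regresses the outcome on the predictor plus covariates with an intercept:
#' ordinary least squares for continuous outcomes, logistic regression for
#' binary ones. Reports the predictor's coefficient, standard error and
#' two-sided p-value.
#'
#' @param outcome Numeric outcome vector (0/1 for `family = "binomial"`).
#' @param predictor Numeric predictor vector (e.g. the z-scored PRS).
#' @param covariates Optional covariate matrix / data frame.
#' @param family `"gaussian"` (default) or `"binomial"`.
#' @param outcome_name,model_tag Labels carried into the result row.
#' @return One-row tibble (`outcome`, `model`, `beta`, `se`, `statistic`,
#'   `p`, `n`).
#' @export
glm_association <- function(outcome, predictor, covariates = NULL,
                            family = c("gaussian", "binomial"),
                            outcome_name = "outcome", model_tag = NA_character_) {
  family <- match.arg(family)
  n <- length(outcome)
  stopifnot(length(predictor) == n)
  cm <- covariate_matrix(covariates, n)
  design <- cbind(cm, predictor = predictor)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop_bagprs(
      paste0("design is collinear; column(s): ", paste(bad, collapse = ", ")),
      "bagprs_collinear"
    )
  }
  if (family == "gaussian") {
    fit <- lm(outcome ~ design - 1)
    sm <- summary(fit)$coefficients
    row <- sm[rownames(sm) == "designpredictor", , drop = FALSE]
  } else {
    fit <- stats::glm(outcome ~ design - 1, family = stats::binomial())
    sm <- summary(fit)$coefficients
    row <- sm[rownames(sm) == "designpredictor", , drop = FALSE]
  }
  tibble::tibble(
    outcome = outcome_name, model = model_tag,
    beta = row[1, 1], se = row[1, 2], statistic = row[1, 3], p = row[1, 4],
    n = n
  )
}

#' Two-group comparison with effect size
#'
#' Welch two-sample t-test with classical Cohen's d (pooled SD with n-1
#' denominators). The sign convention is `group1 - group2`.
#'
#' @param group1,group2 Numeric vectors, each with at least 2 values.
#' @return Tibble (`cohens_d`, `t`, `p`, `n1`, `n2`).
#' @export
two_sample_comparison <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) {
    stop_bagprs("each group needs at least 2 observations.", "bagprs_invalid_config")
  }
  sp2 <- ((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) / (n1 + n2 - 2)
  if (sp2 == 0) stop_bagprs("zero pooled SD.", "bagprs_degenerate")
  tt <- t.test(group1, group2)
  tibble::tibble(
    cohens_d = (mean(group1) - mean(group2)) / sqrt(sp2),
    t = unname(tt$statistic), p = tt$p.value, n1 = n1, n2 = n2
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (empty input gives empty output).
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop_bagprs("p-values must lie in [0, 1].", "bagprs_invalid_config")
  }
  p.adjust(pvalues, method = "BH")
}

#' Region-wise PRS association scan
#'
#' Covariate-adjusted partial correlation of the score with each regional
#' volume, BH-adjusted across regions. Constant regions are reported as `NA`
#' and excluded from the adjustment.
#'
#' @param prs Numeric score vector.
#' @param region_volumes Matrix / data frame, subjects x regions.
#' @param covariates Optional covariate matrix / data frame.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Tibble (`region`, `r`, `p`, `q`, `significant`).
#' @export
regionwise_scan <- function(prs, region_volumes, covariates = NULL, alpha = 0.05) {
  rv <- as.matrix(as.data.frame(region_volumes))
  storage.mode(rv) <- "double"
  regions <- colnames(rv)
  if (is.null(regions)) regions <- sprintf("region_%03d", seq_len(ncol(rv)))
  out <- purrr::map(seq_len(ncol(rv)), function(j) {
    if (sd(rv[, j]) == 0) {
      return(tibble::tibble(region = regions[j], r = NA_real_, p = NA_real_))
    }
    pc <- partial_correlation(prs, rv[, j], covariates)
    tibble::tibble(region = regions[j], r = pc$r, p = pc$p)
  })
  tab <- dplyr::bind_rows(out)
  tab$q <- NA_real_
  ok <- !is.na(tab$p)
  tab$q[ok] <- bh_fdr(tab$p[ok])
  tab$significant <- !is.na(tab$q) & tab$q < alpha
  tab
}

#' Multiple-testing thresholds for a SNP scan
#'
#' Bonferroni genome-wide significance `0.05 / m` and the conventional
#' suggestive line `1 / m` for `m` SNPs tested.
#'
#' @param m Number of SNPs tested (positive integer).
#' @return Tibble (`m`, `genomewide`, `suggestive`).
#' @export
gwas_thresholds <- function(m) {
  m <- check_count(m, "m")
  tibble::tibble(m = m, genomewide = 0.05 / m, suggestive = 1 / m)
}

#' Per-SNP association scan with significance thresholds
#'
#' Additive-dosage regression of the phenotype on each SNP with shared
#' covariates. For the Gaussian family, missing dosages are mean-imputed per
#' SNP and phenotype and dosages are residualized on the covariates once
#' (Frisch-Waugh), which matches the per-SNP OLS t-test with
#' `df = n - k - 2`. The Bonferroni genome-wide threshold is `0.05 / m` and
#' the suggestive threshold `1 / m`, with `m` the number of SNPs tested
#' (monomorphic SNPs are reported as `NA` and not counted).
#'
#' @param geno A [geno_matrix].
#' @param phenotype Numeric phenotype (0/1 for `family = "binomial"`).
#' @param covariates Optional covariate matrix / data frame.
#' @param family `"gaussian"` (default) or `"binomial"` (per-SNP glm).
#' @return A `gwas_result`: `table` tibble (`snp`, `chr`, `pos`, `beta`,
#'   `se`, `p`), `m`, `genomewide_threshold`, `suggestive_threshold`,
#'   `n_genomewide`, `n_suggestive`.
#' @export
gwas_scan <- function(geno, phenotype, covariates = NULL,
                      family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  d <- geno$dosage
  n <- nrow(d)
  stopifnot(length(phenotype) == n)
  cm <- covariate_matrix(covariates, n)
  k <- ncol(cm) - 1L

  eaf <- colMeans(d, na.rm = TRUE) / 2
  dimp <- sweep_impute(d, 2 * eaf)
  mono <- apply(dimp, 2, sd) == 0

  if (family == "gaussian") {
    ry <- as.numeric(ls_residuals(cm, phenotype))
    rx <- ls_residuals(cm, dimp)
    sxx <- unname(colSums(rx^2))
    sxy <- unname(colSums(rx * ry))
    beta <- sxy / sxx
    df <- n - k - 2L
    rss <- sum(ry^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / sxx)
    p <- 2 * pt(-abs(beta / se), df)
  } else {
    res <- purrr::map(seq_len(ncol(dimp)), function(j) {
      if (mono[j]) return(c(NA_real_, NA_real_, NA_real_))
      fit <- suppressWarnings(
        stats::glm(phenotype ~ cm - 1 + dimp[, j], family = stats::binomial())
      )
      sm <- summary(fit)$coefficients
      row <- sm[nrow(sm), ]
      c(row[1], row[2], row[4])
    })
    mt <- do.call(rbind, res)
    beta <- mt[, 1]; se <- mt[, 2]; p <- mt[, 3]
  }
  beta[mono] <- NA_real_; se[mono] <- NA_real_; p[mono] <- NA_real_

  m <- sum(!mono)
  if (m == 0) stop_bagprs("no testable SNPs.", "bagprs_degenerate")
  thr <- gwas_thresholds(m)
  gw <- thr$genomewide
  sug <- thr$suggestive
  structure(
    list(
      table = dplyr::mutate(geno$snps[, c("snp", "chr", "pos")],
                            beta = beta, se = se, p = p),
      m = m,
      genomewide_threshold = gw,
      suggestive_threshold = sug,
      n_genomewide = sum(p < gw, na.rm = TRUE),
      n_suggestive = sum(p < sug, na.rm = TRUE)
    ),
    class = "gwas_result"
  )
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf(
    "<gwas_result> %d SNPs tested; %d genome-wide (p < %.3g), %d suggestive (p < %.3g)\n",
    x$m, x$n_genomewide, x$genomewide_threshold, x$n_suggestive,
    x$suggestive_threshold
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gwas_result <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.gwas_result <- function(x, ...) {
  tibble::tibble(
    m = x$m, genomewide_threshold = x$genomewide_threshold,
    suggestive_threshold = x$suggestive_threshold,
    n_genomewide = x$n_genomewide, n_suggestive = x$n_suggestive
  )
}

#' @describeIn gwas_scan Manhattan-style plot of -log10 p by position.
#' @param object A `gwas_result`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.gwas_result <- function(object, ...) {
  dat <- dplyr::filter(object$table, !is.na(.data$p))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$pos, y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(object$genomewide_threshold),
                        colour = "firebrick", linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(object$suggestive_threshold),
                        colour = "steelblue", linetype = 3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Smoking-group demographic summary
#'
#' Group sizes with percentages of the full cohort and the male percentage
#' within each group, from a per-subject table with logical/0-1 `smoker` and
#' 0/1 `sex` (1 = male) columns.
#'
#' @param cohort Data frame with `smoker` and `sex` columns.
#' @return Tibble (`group`, `n`, `pct`, `n_male`, `male_pct`).
#' @export
smoking_demographics <- function(cohort) {
  stopifnot(all(c("smoker", "sex") %in% names(cohort)))
  total <- nrow(cohort)
  cohort |>
    dplyr::mutate(group = ifelse(as.logical(.data$smoker), "smoker", "non-smoker")) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_male = sum(.data$sex == 1),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct = 100 * .data$n / total,
      male_pct = 100 * .data$n_male / .data$n
    ) |>
    dplyr::select("group", "n", "pct", "n_male", "male_pct") |>
    dplyr::arrange(dplyr::desc(.data$group))
}
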