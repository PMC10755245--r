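#' Default p-value threshold grid
#'
#' 100 thresholds from 0.005 to 0.5 in steps of 0.005.
#'
#' @return Strictly increasing numeric vector of P_T values.
#' @export
default_threshold_grid <- function() seq(0.005, 0.5, by = 0.005)

#' P-value-informed LD clumping
#'
#' Greedy index-SNP selection: SNPs are visited in ascending discovery
#' p-value; each index SNP removes all remaining SNPs on the same chromosome
#' within `window_kb` whose dosage r-squared with it (pairwise-complete in
#' the LD panel) exceeds `r2_cutoff`. Ties on p are broken by chromosome,
#' position, then SNP id for determinism.
#'
#' @param stats Summary-statistics tibble (`snp`, `chr`, `pos`, `p`, ...).
#' @param ld_panel A [geno_matrix] used as LD reference.
#' @param r2_cutoff Squared-correlation cutoff (default 0.1).
#' @param window_kb Physical window half-width in kb (default 250).
#' @param missing_policy What to do with stats SNPs absent from the panel:
#'   `"skip"` (drop with a warning) or `"error"`.
#' @return Tibble of index SNPs in selection order (`snp`, `chr`, `pos`,
#'   `p`, `n_clumped` SNPs it absorbed).
#' @export
clump <- function(stats, ld_panel, r2_cutoff = 0.1, window_kb = 250,
                  missing_policy = c("skip", "error")) {
  missing_policy <- match.arg(missing_policy)
  check_number(r2_cutoff, "r2_cutoff", 1e-12, 1 - 1e-12)
  check_number(window_kb, "window_kb", 1e-9)
  absent <- !(stats$snp %in% colnames(ld_panel$dosage))
  if (any(absent)) {
    msg <- sprintf("%d stats SNP(s) absent from the LD panel.", sum(absent))
    if (missing_policy == "error") stop_bagprs(msg, "bagprs_missing_snp")
    rlang::warn(paste(msg, "Skipping them."))
    stats <- stats[!absent, , drop = FALSE]
  }
  if (nrow(stats) == 0) {
    return(tibble::tibble(
      snp = character(), chr = integer(), pos = integer(),
      p = double(), n_clumped = integer()
    ))
  }
  ord <- order(stats$p, stats$chr, stats$pos, stats$snp)
  st <- stats[ord, , drop = FALSE]
  d <- ld_panel$dosage[, st$snp, drop = FALSE]
  window_bp <- window_kb * 1000

  alive <- rep(TRUE, nrow(st))
  idx_rows <- integer(0)
  n_clumped <- integer(0)
  for (i in seq_len(nrow(st))) {
    if (!alive[i]) next
    alive[i] <- FALSE
    cand <- which(
      alive & st$chr == st$chr[i] & abs(st$pos - st$pos[i]) <= window_bp
    )
    removed <- 0L
    if (length(cand)) {
      r <- suppressWarnings(
        cor(d[, i], d[, cand, drop = FALSE], use = "pairwise.complete.obs")
      )
      r2 <- as.numeric(r)^2
      r2[is.na(r2)] <- 0
      kill <- cand[r2 > r2_cutoff]
      alive[kill] <- FALSE
      removed <- length(kill)
    }
    idx_rows <- c(idx_rows, i)
    n_clumped <- c(n_clumped, removed)
  }
  dplyr::mutate(
    st[idx_rows, c("snp", "chr", "pos", "p")],
    n_clumped = n_clumped
  )
}

#' Compute a polygenic score at one p-value threshold
#'
#' `score_i = sum_j beta_j G_ij / m_i` over SNPs with discovery `p < p_threshold`,
#' where `G_ij` is the effect-allele dosage (missing calls imputed with twice
#' the target-sample effect-allele frequency) and `m_i` the number of SNPs in
#' the sum — the PLINK-style per-SNP average. `average = FALSE` returns the
#' raw weighted sum. Dosages are flipped (`2 - G`) when the summary-stats
#' effect allele matches the panel's other allele; SNPs whose alleles match
#' neither orientation are skipped with a warning.
#'
#' @param geno Target [geno_matrix].
#' @param stats Summary-statistics tibble (`snp`, `ea`, `oa`, `beta`, `p`).
#' @param snps Character vector of (clumped) SNP ids to consider.
#' @param p_threshold Discovery p-value cutoff P_T (strict `<`).
#' @param average Divide by the number of SNPs entering the sum (default).
#' @return Tibble (`subject`, `score`) with attribute `n_snps_used`.
#' @export
prs_score <- function(geno, stats, snps, p_threshold, average = TRUE) {
  st <- stats[stats$snp %in% snps & stats$p < p_threshold, , drop = FALSE]
  st <- st[st$snp %in% colnames(geno$dosage), , drop = FALSE]
  if (nrow(st)) {
    meta <- geno$snps[match(st$snp, geno$snps$snp), ]
    aligned <- st$ea == meta$ea & st$oa == meta$oa
    flipped <- st$ea == meta$oa & st$oa == meta$ea
    if (any(!aligned & !flipped)) {
      rlang::warn(sprintf(
        "%d SNP(s) with mismatched alleles skipped.", sum(!aligned & !flipped)
      ))
    }
    keep <- aligned | flipped
    st <- st[keep, , drop = FALSE]
    flipped <- flipped[keep]
  }
  if (nrow(st) == 0) {
    stop_bagprs("no SNPs pass the threshold: empty score.", "bagprs_empty_score")
  }
  d <- geno$dosage[, st$snp, drop = FALSE]
  eaf <- colMeans(d, na.rm = TRUE) / 2
  d <- sweep_impute(d, 2 * eaf)
  if (any(flipped)) d[, flipped] <- 2 - d[, flipped, drop = FALSE]
  raw <- as.numeric(d %*% st$beta)
  m <- nrow(st)
  out <- tibble::tibble(
    subject = rownames(geno$dosage),
    score = if (average) raw / m else raw
  )
  attr(out, "n_snps_used") <- m
  out
}

#' Partial correlation with covariate adjustment
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and returns the Pearson correlation of the residuals with a
#' two-sided t-test p-value on `n - 2 - k` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix / data frame of covariates.
#' @return Tibble (`r`, `p`, `df`, `n`).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  cmat <- covariate_matrix(covariates, n)
  k <- ncol(cmat) - 1L
  if (n <= k + 2) {
    stop_bagprs("too few observations for the covariate set.", "bagprs_underdetermined")
  }
  rx <- as.numeric(ls_residuals(cmat, x))
  ry <- as.numeric(ls_residuals(cmat, y))
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop_bagprs("zero-variance residuals.", "bagprs_degenerate")
  }
  r <- cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, p = 2 * pt(-abs(tval), df), df = df, n = n)
}

#' Scan polygenic scores over a threshold grid
#'
#' Computes the score at every threshold, its covariate-adjusted partial
#' correlation with the phenotype, ranks thresholds by `|r|` (or signed `r`),
#' keeps the `top_k`, and z-scores the score at the optimal threshold.
#' Thresholds admitting zero SNPs are recorded with `n_snps_used = 0` and
#' excluded from ranking.
#'
#' @param geno Target [geno_matrix].
#' @param stats Summary-statistics tibble.
#' @param clumped_snps Character vector of index-SNP ids (see [clump()]).
#' @param phenotype Numeric per-subject phenotype (e.g. ever-smoker 0/1).
#' @param covariates Optional covariate matrix / data frame.
#' @param grid Increasing vector of P_T values ([default_threshold_grid()]).
#' @param top_k Number of best thresholds to record (default 10).
#' @param rank_by `"abs"` (strongest association, default) or `"signed"`.
#' @return A `prs_scan` object: `thresholds` tibble (`p_t`, `n_snps_used`,
#'   `r`, `p`, `rank`, `selected`), `scores` matrix (subjects x thresholds),
#'   `optimal_threshold`, `selected_thresholds`, and `optimal` tibble
#'   (`subject`, `score`, `prs_z`).
#' @export
threshold_scan <- function(geno, stats, clumped_snps, phenotype,
                           covariates = NULL, grid = default_threshold_grid(),
                           top_k = 10, rank_by = c("abs", "signed")) {
  rank_by <- match.arg(rank_by)
  if (length(grid) == 0 || any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1)) {
    stop_bagprs("`grid` must be strictly increasing within (0, 1].", "bagprs_invalid_config")
  }
  n <- nrow(geno$dosage)
  scores <- matrix(NA_real_, n, length(grid),
                   dimnames = list(rownames(geno$dosage), paste0("pt_", grid)))
  res <- purrr::map(seq_along(grid), function(i) {
    sc <- tryCatch(
      prs_score(geno, stats, clumped_snps, grid[i]),
      bagprs_empty_score = function(e) NULL
    )
    if (is.null(sc)) {
      return(tibble::tibble(p_t = grid[i], n_snps_used = 0L,
                            r = NA_real_, p = NA_real_))
    }
    scores[, i] <<- sc$score
    pc <- partial_correlation(sc$score, phenotype, covariates)
    tibble::tibble(p_t = grid[i], n_snps_used = attr(sc, "n_snps_used"),
                   r = pc$r, p = pc$p)
  })
  thr <- dplyr::bind_rows(res)
  key <- if (rank_by == "abs") abs(thr$r) else thr$r
  key[thr$n_snps_used == 0] <- NA_real_
  if (all(is.na(key))) {
    stop_bagprs("no threshold admits any SNP.", "bagprs_empty_score")
  }
  ord <- order(key, decreasing = TRUE, na.last = TRUE)
  thr$rank <- NA_integer_
  thr$rank[ord[seq_len(sum(!is.na(key)))]] <- seq_len(sum(!is.na(key)))
  k_sel <- min(top_k, sum(!is.na(key)))
  thr$selected <- !is.na(thr$rank) & thr$rank <= k_sel
  best <- which(thr$rank == 1L)
  z <- as.numeric(scale(scores[, best]))
  structure(
    list(
      thresholds = thr,
      scores = scores,
      optimal_threshold = thr$p_t[best],
      selected_thresholds = thr$p_t[thr$selected][order(thr$rank[thr$selected])],
      optimal = tibble::tibble(
        subject = rownames(geno$dosage),
        score = scores[, best],
        prs_z = z
      ),
      rank_by = rank_by
    ),
    class = "prs_scan"
  )
}

#' @export
print.prs_scan <- function(x, ...) {
  cat(sprintf(
    "<prs_scan> %d thresholds; optimal P_T = %.3g (r = %.3f); top %d recorded\n",
    nrow(x$thresholds), x$optimal_threshold,
    x$thresholds$r[x$thresholds$rank == 1L], sum(x$thresholds$selected)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prs_scan <- function(x, ...) x$thresholds

#' @exportS3Method generics::glance
glance.prs_scan <- function(x, ...) {
  best <- x$thresholds[x$thresholds$rank == 1L, ]
  tibble::tibble(
    optimal_threshold = x$optimal_threshold,
    r = best$r, p = best$p, n_snps_used = best$n_snps_used,
    n_thresholds = nrow(x$thresholds)
  )
}

#' @describeIn threshold_scan Plot partial correlation against P_T with the
#'   selected thresholds highlighted.
#' @param object A `prs_scan`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.prs_scan <- function(object, ...) {
  dat <- object$thresholds
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$p_t, y = .data$r)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 1.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey40")) +
    ggplot2::labs(
      x = expression(P[T]), y = "partial correlation with phenotype",
      colour = "top-k"
    ) +
    ggplot2::theme_minimal()
}

# design-matrix helpers -------------------------------------------------------

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  cm <- as.matrix(as.data.frame(covariates))
  storage.mode(cm) <- "double"
  if (nrow(cm) != n) {
    stop_bagprs("covariates must have one row per observation.", "bagprs_invalid_config")
  }
  cm <- cbind(`(Intercept)` = 1, cm)
  qr_c <- qr(cm)
  if (qr_c$rank < ncol(cm)) {
    bad <- colnames(cm)[qr_c$pivot[(qr_c$rank + 1):ncol(cm)]]
    stop_bagprs(
      paste0("covariates are rank deficient; collinear column(s): ",
             paste(bad, collapse = ", ")),
      "bagprs_collinear"
    )
  }
  cm
}

ls_residuals <- function(design, y) {
  y <- as.matrix(y)
  y - design %*% qr.coef(qr(design), y)
}
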