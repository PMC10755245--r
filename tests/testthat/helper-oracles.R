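# Independent reference implementations used as oracles. These are written
# from the definitions (set operations, explicit enumeration) and do not
# share code with the package internals they check.

# geno_matrix from a bare dosage matrix
make_geno <- function(dosage, chr = 1L, pos = NULL, ea = "A", oa = "G") {
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  colnames(dosage) <- sprintf("s%03d", seq_len(m))
  rownames(dosage) <- sprintf("i%03d", seq_len(nrow(dosage)))
  geno_matrix(dosage, tibble::tibble(
    snp = colnames(dosage), chr = chr, pos = as.integer(pos),
    ea = ea, oa = oa
  ))
}

# greedy clumping by explicit set bookkeeping
oracle_clump <- function(stats, dosage, r2_cutoff, window_kb) {
  remaining <- stats[order(stats$p, stats$chr, stats$pos, stats$snp), ]
  index <- character(0)
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    index <- c(index, top$snp)
    remaining <- remaining[-1, , drop = FALSE]
    if (nrow(remaining) == 0) break
    drop <- logical(nrow(remaining))
    for (j in seq_len(nrow(remaining))) {
      row <- remaining[j, ]
      if (row$chr != top$chr) next
      if (abs(row$pos - top$pos) > window_kb * 1000) next
      r <- suppressWarnings(cor(dosage[, top$snp], dosage[, row$snp],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r^2 > r2_cutoff) drop[j] <- TRUE
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  index
}

# HWE chi-square p by direct scalar arithmetic
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  expected <- c(n * p * p, 2 * n * p * q, n * q * q)
  observed <- c(n_AA, n_Aa, n_aa)
  chi2 <- 0
  for (i in 1:3) chi2 <- chi2 + (observed[i] - expected[i])^2 / expected[i]
  pchisq(chi2, df = 1, lower.tail = FALSE)
}

# BH step-up by its textbook definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[ord] <- pmin(adj, 1)
  out
}

# upper-tail hypergeometric by summing the exact pmf
oracle_hyper_tail <- function(k, K, N, n) {
  ks <- k:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (length(ks) == 0) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# a correlated pair of dosage vectors for clumping fixtures
correlated_dosages <- function(n, rho, maf = 0.3) {
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  za <- rnorm(n); zb <- rho * za + sqrt(1 - rho^2) * rnorm(n)
  thr <- qnorm(maf)
  cbind((z1 < thr) + (za < thr), (z2 < thr) + (zb < thr))
}

# single-row hyperparameter set: skips the inner CV loop, keeps tests fast
tiny_grid <- data.frame(max_depth = 3, eta = 0.1, nrounds = 60)
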