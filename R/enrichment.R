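#' Read a BED interval file
#'
#' Expects at least four tab-separated columns: chrom, start, end, name
#' (gene id), with 0-based half-open coordinates. Malformed lines (too few
#' fields, non-integer bounds, end <= start) raise an error naming the line.
#'
#' @param path Path to a BED file.
#' @return Tibble (`chrom`, `start`, `end`, `gene`).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- purrr::map(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (length(f) < 4) {
      stop_bagprs(sprintf("malformed BED line %d: fewer than 4 fields.", i),
                  "bagprs_malformed_bed")
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || end <= start || start < 0) {
      stop_bagprs(sprintf("malformed BED line %d: bad interval [%s, %s).",
                          i, f[2], f[3]),
                  "bagprs_malformed_bed")
    }
    tibble::tibble(chrom = f[1], start = start, end = end, gene = f[4])
  })
  dplyr::bind_rows(rows)
}

#' Read a GMT gene-set file
#'
#' Standard format: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path Path to a GMT file.
#' @param source Optional source tag (e.g. "GO-BP", "KEGG", "custom").
#' @return Named list of character vectors, with attribute `source`.
#' @export
read_gmt <- function(path, source = "custom") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad)) {
    stop_bagprs(sprintf("malformed GMT line %d: need name, description, genes.",
                        bad[1]),
                "bagprs_malformed_gmt")
  }
  sets <- lapply(parts, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) {
    stop_bagprs("duplicate set names in GMT file.", "bagprs_malformed_gmt")
  }
  attr(sets, "source") <- source
  sets
}

#' Map SNPs to genes by interval containment
#'
#' A SNP (1-based position, VCF convention) maps to every gene whose BED
#' interval (0-based half-open), extended by `flank_kb` on both sides,
#' contains it: the conversion is `start < pos <= end` after flanking. The
#' result is the de-duplicated gene list.
#'
#' @param snps Tibble with `chr` and `pos` (1-based) columns.
#' @param gene_intervals Tibble as from [read_bed()].
#' @param flank_kb Flank added to each interval side, in kb (default 0).
#' @return Character vector of unique gene ids (sorted).
#' @export
map_snps_to_genes <- function(snps, gene_intervals, flank_kb = 0) {
  check_number(flank_kb, "flank_kb", 0)
  flank <- flank_kb * 1000
  hits <- dplyr::inner_join(
    dplyr::mutate(snps[, c("chr", "pos")], chrom = as.character(.data$chr)),
    dplyr::mutate(gene_intervals, chrom = as.character(.data$chrom)),
    by = "chrom", relationship = "many-to-many"
  )
  hits <- dplyr::filter(
    hits,
    .data$pos > .data$start - flank, .data$pos <= .data$end + flank
  )
  sort(unique(hits$gene))
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query genes over-represent the set
#' relative to the universe: upper-tail hypergeometric
#' `p = P(X >= k)` with `X ~ Hypergeom(N, K, n)` where `N` is the universe
#' size, `K` the universe genes in the set, `n` the query size and `k` the
#' query genes in the set. BH adjustment is applied across the tested terms;
#' sets with no universe genes are skipped. Query genes outside the universe
#' are dropped with a warning.
#'
#' @param query Character vector of query gene ids.
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param universe Character vector of background gene ids.
#' @return Tibble (`term`, `k`, `K`, `n`, `N`, `p`, `q`), sorted by `p`.
#' @export
ora <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_bagprs("empty universe.", "bagprs_invalid_config")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    rlang::warn(sprintf("%d query gene(s) outside the universe dropped.",
                        length(outside)))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::map(names(sets), function(term) {
    set_u <- intersect(unique(sets[[term]]), universe)
    K <- length(set_u)
    if (K == 0) return(NULL)
    k <- length(intersect(query, set_u))
    tibble::tibble(
      term = term, k = k, K = K, n = n, N = N,
      p = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (nrow(tab) == 0) {
    return(tibble::tibble(term = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = double(),
                          q = double()))
  }
  tab$q <- bh_fdr(tab$p)
  dplyr::arrange(tab, .data$p, .data$term)
}
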