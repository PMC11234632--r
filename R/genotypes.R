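#' Construct a genotype set
#'
#' Holds a sample-by-SNP matrix of allele-B dosage codes (0/1/2, `NA` for
#' missing) together with a SNP map. On construction, SNPs are sorted by
#' position within each chromosome (chromosomes keep their incoming order); a
#' warning is issued if any reordering occurred.
#'
#' @param codes integer/numeric matrix, samples in rows, SNPs in columns,
#'   entries in \{0, 1, 2, NA\} counting copies of `allele_b`.
#' @param sample_ids character vector of unique sample ids (defaults to
#'   rownames of `codes`).
#' @param map data.frame with columns `snp_id`, `chrom`, `pos` (1-based bp),
#'   `allele_a`, `allele_b`. `snp_id` must be unique, `pos` positive.
#' @return An object of class `genotype_set`: a list with elements `codes`
#'   (dimnamed matrix) and `map`.
#' @export
genotype_set <- function(codes, sample_ids = rownames(codes), map = NULL) {
  codes <- as.matrix(codes)
  if (is.null(sample_ids)) stop("sample ids are required")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(codes)) stop("sample_ids length != nrow(codes)")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (is.null(map)) {
    map <- data.frame(snp_id = if (is.null(colnames(codes)))
                        sprintf("snp%d", seq_len(ncol(codes))) else colnames(codes),
                      chrom = "1", pos = seq_len(ncol(codes)),
                      allele_a = "A", allele_b = "B",
                      stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(map))) {
    stop("map must have columns: ", paste(need, collapse = ", "))
  }
  map$chrom <- as.character(map$chrom)
  if (nrow(map) != ncol(codes)) stop("map rows != number of SNP columns")
  if (anyDuplicated(map$snp_id)) stop("duplicate snp ids in map")
  if (any(map$pos < 1)) stop("positions must be positive (1-based)")
  map$pos <- as.integer(map$pos)
  bad <- codes[!is.na(codes) & !(codes %in% c(0, 1, 2))]
  if (length(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  # stable sort: chromosomes in order of first appearance, positions ascending
  chrom_f <- factor(map$chrom, levels = unique(map$chrom))
  ord <- order(chrom_f, map$pos)
  if (any(ord != seq_along(ord))) {
    warning("SNPs reordered by position within chromosome")
    map <- map[ord, , drop = FALSE]
    codes <- codes[, ord, drop = FALSE]
  }
  rownames(map) <- NULL
  dimnames(codes) <- list(sample_ids, map$snp_id)
  structure(list(codes = codes, map = map), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", nrow(x$codes), "samples x", ncol(x$codes), "SNPs on",
      length(unique(x$map$chrom)), "chromosome(s);",
      sprintf("%.3f%%", 100 * mean(is.na(x$codes))), "missing\n")
  if (!is.null(attr(x, "qc"))) {
    qc <- attr(x, "qc")
    cat("  QC removed:", qc["maf"], "MAF,", qc["callrate"], "call-rate,",
        qc["hwe"], "HWE;", qc["kept"], "kept\n")
  }
  invisible(x)
}

#' Number of samples / SNPs
#' @param g a [genotype_set()].
#' @return Integer count.
#' @export
n_samples <- function(g) nrow(g$codes)

#' @rdname n_samples
#' @export
n_snps <- function(g) ncol(g$codes)

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test: all heterozygote counts consistent with the observed
#' allele counts are enumerated, and the probabilities of configurations no
#' more probable than the observed one are summed (Levene-Haldane
#' distribution; no mid-p correction).
#'
#' @param n_AA,n_AB,n_BB non-negative genotype counts, total > 0.
#' @return Exact two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_test(1, 0, 1)  # 1/3
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  counts <- c(n_AA, n_AB, n_BB)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("total genotype count must be positive")
  nA <- 2 * n_AA + n_AB
  nB <- 2 * n_BB + n_AB
  # possible het counts share parity with nA
  het <- seq.int(nA %% 2, min(nA, nB), by = 2)
  # log P(n_AB = h | nA, n) = log[ n! / (nAA! h! nBB!) * 2^h * nA! nB! / (2n)! ]
  log_p <- lgamma(n + 1) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((nB - het) / 2 + 1) + het * log(2) +
    lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  p <- exp(log_p - max(log_p))
  p <- p / sum(p)
  p_obs <- p[match(n_AB, het)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Per-SNP QC summaries
#'
#' Allele-B frequency, minor allele frequency, call rate and HWE exact-test
#' p-value per SNP (unweighted; all samples).
#'
#' @param g a [genotype_set()].
#' @return data.frame with columns `snp_id`, `freq_b`, `maf`, `callrate`,
#'   `hwe_p`.
#' @export
snp_qc_stats <- function(g) {
  M <- g$codes
  n_obs <- colSums(!is.na(M))
  freq_b <- ifelse(n_obs > 0, colSums(M, na.rm = TRUE) / (2 * n_obs), NA_real_)
  n_het <- colSums(M == 1, na.rm = TRUE)
  n_bb <- colSums(M == 2, na.rm = TRUE)
  n_aa <- n_obs - n_het - n_bb
  hwe_p <- vapply(seq_len(ncol(M)), function(j) {
    if (n_obs[j] == 0) return(NA_real_)
    hwe_exact_test(n_aa[j], n_het[j], n_bb[j])
  }, numeric(1))
  data.frame(snp_id = g$map$snp_id, freq_b = freq_b,
             maf = pmin(freq_b, 1 - freq_b),
             callrate = n_obs / nrow(M), hwe_p = hwe_p,
             stringsAsFactors = FALSE)
}

#' SNP quality-control filter
#'
#' Keeps a SNP iff MAF > `maf_min` AND call rate >= `callrate_min` AND HWE
#' exact p > `hwe_p_min` (strict/non-strict comparisons exactly as written).
#' Samples are never removed. Per-filter exclusion counts (a SNP failing two
#' filters is counted under both) are attached as attribute `"qc"`.
#'
#' @param g a [genotype_set()].
#' @param maf_min minor-allele-frequency threshold (default 0.01).
#' @param callrate_min call-rate threshold (default 0.9).
#' @param hwe_p_min HWE exact-test p-value threshold (default 1e-7).
#' @return A filtered `genotype_set` with attribute `qc` = named counts
#'   `c(maf, callrate, hwe, removed, kept)`.
#' @export
qc_filter <- function(g, maf_min = 0.01, callrate_min = 0.9, hwe_p_min = 1e-7) {
  for (th in c(maf_min, callrate_min, hwe_p_min)) {
    if (!is.numeric(th) || th <= 0 || th >= 1) stop("thresholds must lie in (0, 1)")
  }
  st <- snp_qc_stats(g)
  fail_maf <- !(st$maf > maf_min) | is.na(st$maf)
  fail_cr <- st$callrate < callrate_min
  fail_hwe <- !(st$hwe_p > hwe_p_min) | is.na(st$hwe_p)
  keep <- !(fail_maf | fail_cr | fail_hwe)
  if (!any(keep)) stop("no SNPs survive QC")
  out <- genotype_set(g$codes[, keep, drop = FALSE],
                      rownames(g$codes), g$map[keep, , drop = FALSE])
  attr(out, "qc") <- c(maf = sum(fail_maf), callrate = sum(fail_cr),
                       hwe = sum(fail_hwe), removed = sum(!keep),
                       kept = sum(keep))
  out
}
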