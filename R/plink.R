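#' Read / write PLINK 1 binary genotypes
#'
#' SNP-major PLINK v1 `.bed` (magic bytes 0x6c 0x1b 0x01) with companion
#' `.bim` and `.fam`. The 2-bit codes are mapped so that the stored dosage
#' counts copies of `allele_b` (= `.bim` allele 2): 00 -> 0, 10 -> 1,
#' 11 -> 2, 01 -> missing; the first sample occupies the lowest-order bits.
#'
#' @param prefix path without extension; `prefix.bed/.bim/.fam` are used.
#' @return `read_plink()` returns a [genotype_set()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("missing file: ", f)
  map <- read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos",
                                  "allele_a", "allele_b"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  famdf <- read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")
  sample_ids <- famdf[[2]]
  n <- length(sample_ids)
  m <- nrow(map)
  bpv <- ceiling(n / 4)  # bytes per variant
  raw <- readBin(bed, "raw", n = 3 + bpv * m)
  if (length(raw) < 3 + bpv * m) stop("truncated .bed file: ", bed)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK v1 .bed file: ", bed)
  }
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  # unpack 2-bit fields: sample i sits in byte floor((i-1)/4), bits 2*((i-1)%%4)
  codes <- matrix(NA_integer_, n, m)
  lut <- c(0L, NA_integer_, 1L, 2L)  # bed code 0,1,2,3 -> dosage
  for (k in 0:3) {
    idx <- seq.int(k + 1, n, by = 4)
    if (!length(idx)) next
    bytes <- body[ceiling(idx / 4), , drop = FALSE]
    two_bits <- bytes %/% (4L^k) %% 4L
    codes[idx, ] <- lut[two_bits + 1L]
  }
  genotype_set(codes, sample_ids,
               map[, c("snp_id", "chrom", "pos", "allele_a", "allele_b")])
}

#' @rdname read_plink
#' @param g a [genotype_set()].
#' @export
write_plink <- function(g, prefix) {
  n <- nrow(g$codes)
  m <- ncol(g$codes)
  map <- g$map
  write.table(data.frame(map$chrom, map$snp_id, 0, map$pos,
                         map$allele_a, map$allele_b),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- rownames(g$codes)
  write.table(data.frame(ids, ids, 0, 0, 0, -9), paste0(prefix, ".fam"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  # dosage -> bed 2-bit code
  bedcode <- matrix(1L, n, m)  # missing
  bedcode[g$codes == 0] <- 0L
  bedcode[g$codes == 1] <- 2L
  bedcode[g$codes == 2] <- 3L
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  if (pad > 0) bedcode <- rbind(bedcode, matrix(0L, pad, m))
  dim(bedcode) <- c(4, bpv * m)
  bytes <- as.raw(bedcode[1, ] + 4L * bedcode[2, ] + 16L * bedcode[3, ] +
                    64L * bedcode[4, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}

#' Read / write a TSV dosage matrix
#'
#' Samples in rows: first column `sample_id`, remaining header names are SNP
#' ids, entries 0/1/2 with missing written as `NA`. A SNP map can be given;
#' otherwise a single-chromosome map with unit-spaced positions is assumed.
#'
#' @param path file path.
#' @param map optional SNP map data.frame (see [genotype_set()]).
#' @return `read_dosage()` returns a [genotype_set()].
#' @export
read_dosage <- function(path, map = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = c(sample_id = "character"))
  if (names(df)[1] != "sample_id") stop("first column must be 'sample_id'")
  codes <- as.matrix(df[, -1, drop = FALSE])
  rownames(codes) <- df$sample_id
  genotype_set(codes, df$sample_id, map)
}

#' @rdname read_dosage
#' @param g a [genotype_set()].
#' @export
write_dosage <- function(g, path) {
  df <- data.frame(sample_id = rownames(g$codes), g$codes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
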