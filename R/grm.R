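#' Per-SNP weight vector for a weighted relationship matrix
#'
#' @param d non-negative numeric vector, at least one entry > 0.
#' @param mode provenance tag: `"uniform"`, `"topsnps"`, `"gwablup"`,
#'   `"cross-trait"` or `"custom"`.
#' @return Numeric vector of class `snp_weights` with attribute `mode`.
#' @export
snp_weights <- function(d, mode = "custom") {
  d <- as.numeric(d)
  if (any(!is.finite(d)) || any(d < 0)) stop("SNP weights must be >= 0 and finite")
  if (!any(d > 0)) stop("at least one SNP weight must be positive")
  structure(d, mode = mode, class = "snp_weights")
}

#' Build a (weighted) genomic relationship matrix
#'
#' VanRaden method-1 style quadratic form
#' `G_D = X D X' / sum_j 2 p_j (1 - p_j) D_jj`, with `D` a diagonal matrix of
#' per-SNP weights. With all weights equal (any positive constant) the result
#' is the unweighted `G_u`; the matrix is invariant to rescaling `D` by a
#' positive scalar. Built over all samples in `X` (training and validation)
#' with the single training-derived denominator.
#'
#' @param X a [center_genotypes()] result.
#' @param D per-SNP weights ([snp_weights()] or plain non-negative vector);
#'   default all 1 (unweighted).
#' @return Object of class `grm`: list with `values` (symmetric matrix with
#'   sample-id dimnames), `ids`, `denominator`, `weights`.
#' @export
build_grm <- function(X, D = NULL) {
  if (!inherits(X, "centered_genotypes")) stop("'X' must be centered_genotypes")
  m <- ncol(X$X)
  if (is.null(D)) D <- snp_weights(rep(1, m), mode = "uniform")
  if (length(D) != m) stop("length(D) != number of SNPs")
  if (any(!is.finite(D)) || any(D < 0)) stop("SNP weights must be >= 0 and finite")
  denom <- sum(2 * X$p * (1 - X$p) * D)
  if (denom <= 0) stop("zero denominator: all weight on monomorphic SNPs")
  use <- D > 0  # skip zero-weight columns entirely
  Xs <- X$X[, use, drop = FALSE] * rep(sqrt(D[use]), each = nrow(X$X))
  G <- tcrossprod(Xs) / denom
  G <- (G + t(G)) / 2
  structure(list(values = G, ids = rownames(X$X), denominator = denom,
                 weights = D), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", length(x$ids), "x", length(x$ids),
      "; mean diagonal", signif(mean(diag(x$values)), 4),
      "; denominator", signif(x$denominator, 6), "\n")
  invisible(x)
}

#' Summary diagnostics of a relationship matrix
#'
#' Mean diagonal, extreme relationships, implied mean inbreeding
#' `F = mean(diag) - 1`, and (optionally) the smallest eigenvalue.
#'
#' @param G a [build_grm()] result.
#' @param eigenvalues if `TRUE`, also report the smallest eigenvalue.
#' @return Named list of diagnostics.
#' @export
grm_diagnostics <- function(G, eigenvalues = FALSE) {
  V <- G$values
  d <- diag(V)
  off <- V[upper.tri(V)]
  out <- list(n = length(d), mean_diag = mean(d),
              min_diag = min(d), max_diag = max(d),
              min_off = if (length(off)) min(off) else NA_real_,
              max_off = if (length(off)) max(off) else NA_real_,
              mean_inbreeding = mean(d) - 1)
  if (eigenvalues) {
    out$min_eigenvalue <- min(eigen(V, symmetric = TRUE, only.values = TRUE)$values)
  }
  out
}

#' Read / write a relationship matrix
#'
#' `format = "tsv"`: full matrix, first column `sample_id`, header of sample
#' ids; lossless round trip. `format = "gcta"`: GCTA binary triple —
#' `.grm.bin` (float32 lower triangle including diagonal, row by row),
#' `.grm.N.bin` (float32 SNP counts) and `.grm.id` (FID/IID); round trip is
#' exact to float32 precision.
#'
#' @param G a `grm` object.
#' @param path output path (`tsv`) or prefix (`gcta`).
#' @param format `"gcta"` or `"tsv"`.
#' @param n_snps number of SNPs recorded in `.grm.N.bin` (gcta only).
#' @return `read_grm()` returns a `grm` object (with `denominator = NA` for
#'   files written elsewhere, `weights = NULL`).
#' @export
write_grm <- function(G, path, format = c("tsv", "gcta"), n_snps = NA_integer_) {
  format <- match.arg(format)
  if (format == "tsv") {
    vals <- matrix(formatC(G$values, digits = 17, format = "g"),
                   nrow(G$values))
    df <- data.frame(sample_id = G$ids, vals, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("sample_id", G$ids)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    n <- length(G$ids)
    lower <- G$values[upper.tri(G$values, diag = TRUE)]
    # GCTA stores rows i = 1..n, elements (i,1..i); column-major upper.tri of
    # a symmetric matrix enumerates exactly these values in the same order
    con <- file(paste0(path, ".grm.bin"), "wb")
    writeBin(as.numeric(lower), con, size = 4)
    close(con)
    con <- file(paste0(path, ".grm.N.bin"), "wb")
    writeBin(rep(as.numeric(if (is.na(n_snps)) 0 else n_snps), length(lower)),
             con, size = 4)
    close(con)
    write.table(data.frame(G$ids, G$ids), paste0(path, ".grm.id"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path, format = c("tsv", "gcta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = c(sample_id = "character"))
    ids <- df$sample_id
    V <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(V) != ncol(V)) stop("malformed GRM TSV: matrix not square")
    dimnames(V) <- list(ids, ids)
  } else {
    idf <- paste0(path, ".grm.id")
    binf <- paste0(path, ".grm.bin")
    if (!file.exists(idf) || !file.exists(binf)) stop("missing GCTA GRM files at ", path)
    ids <- read.table(idf, header = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character")[[2]]
    n <- length(ids)
    nel <- n * (n + 1) / 2
    vals <- readBin(binf, "numeric", n = nel + 1, size = 4)
    if (length(vals) != nel) {
      stop("GCTA GRM size mismatch: expected ", nel, " float32 values for ",
           n, " ids, found ", length(vals))
    }
    V <- matrix(0, n, n, dimnames = list(ids, ids))
    V[upper.tri(V, diag = TRUE)] <- vals
    V <- V + t(V) - diag(diag(V))
  }
  structure(list(values = V, ids = ids, denominator = NA_real_, weights = NULL),
            class = "grm")
}
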