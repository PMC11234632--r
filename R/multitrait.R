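#' Canonical transformation of a multitrait covariance pair
#'
#' Simultaneously diagonalises the genetic and environmental covariance
#' matrices: returns `Q` such that `Q Ecov Q' = I` and `Q Gcov Q'` is
#' diagonal. The canonical traits `y* = Q y` are genetically and
#' environmentally independent with environmental variance 1; their genetic
#' variances are the returned eigenvalues (equivalently, canonical
#' heritability ratios). Construction: whiten by `Ecov^(-1/2)` (spectral),
#' then eigendecompose the whitened `Gcov`. Output is ordered by descending
#' canonical genetic variance with a deterministic sign convention (the
#' largest-magnitude entry of each row of `Q` is positive).
#'
#' @param Gcov genetic covariance matrix (symmetric, PSD).
#' @param Ecov environmental covariance matrix (symmetric, must be positive
#'   definite; a non-PD input is rejected naming the offending eigenvalue,
#'   unless `make_pd = TRUE` clips eigenvalues below `1e-6`).
#' @param make_pd clip non-positive eigenvalues of `Ecov` instead of
#'   erroring (off by default).
#' @return Object of class `canonical_transform`: `Q` (traits x traits),
#'   `Qinv`, `canonical_genetic_variances`, `traits`.
#' @export
canonical_transform <- function(Gcov, Ecov, make_pd = FALSE) {
  Gcov <- as.matrix(Gcov); Ecov <- as.matrix(Ecov)
  if (!isTRUE(all.equal(Gcov, t(Gcov), tolerance = 1e-8)) ||
      !isTRUE(all.equal(Ecov, t(Ecov), tolerance = 1e-8))) {
    stop("covariance matrices must be symmetric")
  }
  traits <- rownames(Gcov)
  if (is.null(traits)) traits <- paste0("trait", seq_len(nrow(Gcov)))
  ee <- eigen((Ecov + t(Ecov)) / 2, symmetric = TRUE)
  if (min(ee$values) <= 0) {
    if (!make_pd) {
      stop(sprintf(paste0("environmental covariance is not positive definite ",
                          "(smallest eigenvalue %.4g); see make_pd"),
                   min(ee$values)))
    }
    ee$values <- pmax(ee$values, 1e-6)
  }
  ge <- eigen((Gcov + t(Gcov)) / 2, symmetric = TRUE, only.values = TRUE)
  if (min(ge$values) < -1e-8 * max(abs(ge$values), 1)) {
    stop("genetic covariance must be positive semidefinite")
  }
  E_isqrt <- ee$vectors %*% diag(1 / sqrt(ee$values), nrow(Ecov)) %*% t(ee$vectors)
  A <- E_isqrt %*% Gcov %*% E_isqrt
  ea <- eigen((A + t(A)) / 2, symmetric = TRUE)  # descending by default
  Q <- t(ea$vectors) %*% E_isqrt
  for (i in seq_len(nrow(Q))) {
    if (Q[i, which.max(abs(Q[i, ]))] < 0) Q[i, ] <- -Q[i, ]
  }
  dimnames(Q) <- list(paste0("can", seq_len(nrow(Q))), traits)
  structure(list(Q = Q, Qinv = solve(Q),
                 canonical_genetic_variances = pmax(ea$values, 0),
                 traits = traits),
            class = "canonical_transform")
}

#' @export
print.canonical_transform <- function(x, ...) {
  cat("canonical transform of", length(x$traits), "traits:",
      paste(x$traits, collapse = ", "), "\n")
  cat("  canonical genetic variances:",
      paste(signif(x$canonical_genetic_variances, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Map observations to canonical traits and back
#'
#' `to_canonical()` maps a samples-x-traits matrix to the canonical scale
#' (`Y Q'`); `back_transform()` maps canonical-scale predictions back to the
#' original traits (`Y* Q^-T`). Both are exact linear round trips. Missing
#' records are rejected: the transformation requires complete multitrait
#' records (analyse traits singly otherwise).
#'
#' @param Y numeric matrix, samples in rows, traits in columns.
#' @param ct a [canonical_transform()].
#' @return Numeric matrix of the same shape.
#' @export
to_canonical <- function(Y, ct) {
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("missing trait records: run single-trait analyses instead")
  if (ncol(Y) != ncol(ct$Q)) stop("trait count mismatch")
  out <- Y %*% t(ct$Q)
  colnames(out) <- rownames(ct$Q)
  out
}

#' @rdname to_canonical
#' @export
back_transform <- function(Y, ct) {
  Y <- as.matrix(Y)
  if (ncol(Y) != ncol(ct$Q)) stop("trait count mismatch")
  out <- Y %*% t(ct$Qinv)
  colnames(out) <- ct$traits
  out
}

#' Combine GWAS likelihood ratios across independent canonical traits
#'
#' Because the canonical traits are genetically and environmentally
#' independent, their per-SNP log-likelihood ratios add. The combined
#' `2 sum(LR)` is referred to chi-square with one df per trait for the
#' reported p-value.
#'
#' @param scans list of `gwas_scan` data.frames, one per canonical trait,
#'   with identical SNP maps.
#' @return A `gwas_scan`-like data.frame with columns `snp_id`, `chrom`,
#'   `pos`, `lr`, `p_value`, `neg_log10_p`.
#' @export
combine_canonical_lr <- function(scans) {
  if (!length(scans)) stop("no scans supplied")
  ref <- scans[[1]]
  for (sc in scans[-1]) {
    if (!identical(ref$snp_id, sc$snp_id) || !identical(ref$chrom, sc$chrom) ||
        !identical(ref$pos, sc$pos)) {
      stop("SNP maps differ across canonical-trait scans")
    }
  }
  lr <- Reduce(`+`, lapply(scans, `[[`, "lr"))
  k <- length(scans)
  out <- data.frame(snp_id = ref$snp_id, chrom = ref$chrom, pos = ref$pos,
                    lr = lr,
                    p_value = pchisq(2 * lr, df = k, lower.tail = FALSE),
                    neg_log10_p = -pchisq(2 * lr, df = k, lower.tail = FALSE,
                                          log.p = TRUE) / log(10),
                    stringsAsFactors = FALSE)
  class(out) <- c("gwas_scan", "data.frame")
  out
}

#' Cross-trait SNP weights
#'
#' For the covariance block between traits `t` and `s` in a per-trait-pair
#' weighting scheme, the SNP weight is the geometric mean
#' `D_jj(t, s) = sqrt(PP_j(t) PP_j(s))` of the two smoothed posterior
#' probabilities.
#'
#' @param pp_t,pp_s numeric vectors of smoothed posterior probabilities in
#'   (0, 1], equal length.
#' @return A [snp_weights()] vector tagged `"cross-trait"`.
#' @export
cross_trait_weights <- function(pp_t, pp_s) {
  if (length(pp_t) != length(pp_s)) stop("weight vectors differ in length")
  if (any(pp_t <= 0 | pp_t > 1) || any(pp_s <= 0 | pp_s > 1)) {
    stop("posterior probabilities must lie in (0, 1]")
  }
  snp_weights(sqrt(pp_t * pp_s), mode = "cross-trait")
}

#' Multitrait genomic prediction via the canonical transformation
#'
#' Transforms complete multitrait records to independent canonical traits,
#' fits each with single-trait GBLUP (environmental variance 1, genetic
#' variance = the canonical eigenvalue), and back-transforms the canonical
#' predictions — equivalent to the stacked multitrait animal model. Modes:
#' `"gblup"` uses the unweighted matrix for every canonical trait;
#' `"gwablup"` first scans each canonical trait, sums the likelihood ratios
#' across traits, smooths, converts to posterior probabilities and uses one
#' shared weighted matrix; `"topsnps"` selects genome-wide significant SNPs
#' from the combined scan and upweights them by 1000.
#'
#' @param Y samples-x-traits matrix of training phenotypes (rownames =
#'   sample ids), no missing entries.
#' @param X a [center_genotypes()] result over all animals.
#' @param Gcov,Ecov trait covariance matrices (see
#'   [canonical_transform()]).
#' @param mode `"gblup"`, `"gwablup"` or `"topsnps"`.
#' @param w optional named observation weights (applied unchanged to every
#'   canonical trait).
#' @param s smoothing window for `"gwablup"`.
#' @param pi prior SNP probability for `"gwablup"`.
#' @param p_threshold,min_peak_gap_bp top-SNP parameters for `"topsnps"`;
#'   the combined-scan p-value is referred to chi-square with one df per
#'   trait.
#' @return List of class `mt_fit`: `gebv` (all animals x traits, original
#'   scale), `canonical` (the transform), `combined_scan` (for weighted
#'   modes), `weights`, `fits` (per-canonical-trait `gblup_fit`s).
#' @export
mt_predict <- function(Y, X, Gcov, Ecov,
                       mode = c("gblup", "gwablup", "topsnps"),
                       w = NULL, s = 5, pi = 0.001,
                       p_threshold = 1e-7, min_peak_gap_bp = 1e6) {
  mode <- match.arg(mode)
  Y <- as.matrix(Y)
  ids <- rownames(Y)
  if (is.null(ids)) stop("'Y' must have sample ids as rownames")
  ct <- canonical_transform(Gcov, Ecov)
  Yc <- to_canonical(Y, ct)
  Gu <- build_grm(X)
  k <- ncol(Yc)
  combined <- NULL
  if (mode != "gblup") {
    scans <- lapply(seq_len(k), function(j) {
      yj <- setNames(Yc[, j], ids)
      emmax_scan(yj, X, Gu,
                 list(sigma2_g = ct$canonical_genetic_variances[j],
                      sigma2_e = 1),
                 w = w, trait = colnames(Yc)[j])
    })
    combined <- combine_canonical_lr(scans)
  }
  D <- switch(mode,
    gblup = make_weights("uniform", m = ncol(X$X)),
    gwablup = make_weights("gwablup", scan = combined, s = s, pi = pi),
    topsnps = make_weights("topsnps", scan = combined,
                           p_threshold = p_threshold,
                           min_peak_gap_bp = min_peak_gap_bp))
  Gfit <- if (mode == "gblup") Gu else build_grm(X, D)
  fits <- lapply(seq_len(k), function(j) {
    yj <- setNames(Yc[, j], ids)
    gblup_solve(yj, Gfit,
                list(sigma2_g = max(ct$canonical_genetic_variances[j], 1e-10),
                     sigma2_e = 1), w = w)
  })
  gebv_c <- do.call(cbind, lapply(fits, `[[`, "gebv"))
  colnames(gebv_c) <- rownames(ct$Q)
  gebv <- back_transform(gebv_c, ct)
  rownames(gebv) <- Gu$ids
  structure(list(gebv = gebv, canonical = ct, combined_scan = combined,
                 weights = D, fits = fits, mode = mode),
            class = "mt_fit")
}
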