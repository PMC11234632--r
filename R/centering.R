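#' Weighted allele frequencies from training data
#'
#' `p_j = sum(w_i M_ij) / (2 sum(w_i))` over the non-missing training
#' genotypes, with per-animal observation weights `w` (Eq. of
#' [observation_weight()]). Validation animals never contribute.
#'
#' @param g a [genotype_set()].
#' @param w named numeric vector of observation weights (names = sample ids),
#'   or a data.frame with columns `sample_id`, `w`.
#' @param training_ids character vector of training sample ids.
#' @return Named numeric vector `p` of allele-B frequencies in `[0, 1]`.
#' @export
weighted_allele_freq <- function(g, w, training_ids) {
  w <- as_weight_vector(w)
  training_ids <- as.character(training_ids)
  if (!all(training_ids %in% rownames(g$codes))) {
    stop("training ids not all present in genotype set")
  }
  wt <- w[training_ids]
  if (anyNA(wt)) stop("weights missing for some training ids")
  M <- g$codes[training_ids, , drop = FALSE]
  obs <- !is.na(M)
  num <- colSums(M * wt, na.rm = TRUE)
  den <- 2 * colSums(obs * wt)
  if (any(den == 0)) {
    stop("all training genotypes missing for SNP(s): ",
         paste(g$map$snp_id[den == 0], collapse = ", "))
  }
  setNames(num / den, g$map$snp_id)
}

as_weight_vector <- function(w) {
  if (is.data.frame(w)) w <- setNames(w$w, w$sample_id)
  if (is.null(names(w))) stop("weights must be named by sample id")
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  w
}

#' Centered genotype scores
#'
#' `X_ij = M_ij - 2 p_j` with `p` the weighted training allele frequencies;
#' missing genotypes become 0 after centering (mean imputation on the
#' centered scale). By construction the w-weighted training mean of every
#' column is 0.
#'
#' @param g a [genotype_set()].
#' @param p named vector of allele frequencies as from
#'   [weighted_allele_freq()] (computed with the same `w`/`training_ids`).
#' @param w observation weights (see [weighted_allele_freq()]).
#' @param training_ids character vector of training sample ids.
#' @return An object of class `centered_genotypes`: list with `X` (matrix
#'   over all samples), `p`, `w`, `training_ids`, `map`.
#' @export
center_genotypes <- function(g, p = NULL, w = NULL, training_ids = rownames(g$codes)) {
  if (is.null(w)) {
    w <- setNames(rep(1, nrow(g$codes)), rownames(g$codes))
  }
  w <- as_weight_vector(w)
  if (is.null(p)) p <- weighted_allele_freq(g, w, training_ids)
  if (length(p) != ncol(g$codes)) stop("length(p) != number of SNPs")
  X <- sweep(g$codes, 2L, 2 * p, `-`)
  X[is.na(g$codes)] <- 0
  structure(list(X = X, p = p, w = w,
                 training_ids = as.character(training_ids), map = g$map),
            class = "centered_genotypes")
}

#' @export
print.centered_genotypes <- function(x, ...) {
  cat("centered_genotypes:", nrow(x$X), "samples x", ncol(x$X), "SNPs;",
      length(x$training_ids), "training\n")
  invisible(x)
}
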