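#' Moving-average smoothing of likelihood ratios along the genome
#'
#' Per SNP, the mean LR over a window of `s` SNPs centred on it, computed
#' within chromosomes only. At chromosome ends the window is truncated and
#' the divisor is the number of SNPs actually in the window, so a constant
#' series is left unchanged and no signal leaks across chromosomes. `s = 1`
#' is the identity.
#'
#' @param scan a `gwas_scan` data.frame (SNPs ordered by chrom, pos), or a
#'   numeric LR vector combined with `chrom`.
#' @param s odd window size >= 1 (the study used 5 for strong-signal traits
#'   and 81 for a weak-signal one).
#' @param chrom chromosome labels when `scan` is a plain vector.
#' @return Numeric vector of smoothed LR values.
#' @export
smooth_lr <- function(scan, s = 5, chrom = NULL) {
  if (inherits(scan, "gwas_scan") || is.data.frame(scan)) {
    lr <- scan$lr
    chrom <- scan$chrom
  } else {
    lr <- as.numeric(scan)
    if (is.null(chrom)) chrom <- rep("1", length(lr))
  }
  if (s < 1 || s %% 2 == 0) stop("window size 's' must be odd and >= 1")
  if (s == 1) return(lr)
  h <- (s - 1) / 2
  out <- numeric(length(lr))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- lr[idx]
    nc <- length(v)
    cs <- c(0, cumsum(v))
    i <- seq_len(nc)
    lo <- pmax(1L, i - h)
    hi <- pmin(nc, i + h)
    out[idx] <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  out
}

#' Posterior probability of a non-zero SNP effect
#'
#' Mixture posterior `PP = pi e^LR / (pi e^LR + 1 - pi)` given prior `pi`,
#' evaluated in the numerically stable logistic form
#' `1 / (1 + exp(log((1 - pi)/pi) - LR))`; no overflow for arbitrarily large
#' LR. Typically applied to smoothed LR values.
#'
#' @param lr numeric vector of (smoothed) likelihood ratios.
#' @param pi prior probability that a SNP has a substantial effect, in
#'   (0, 1); default 0.001.
#' @return Numeric vector of posterior probabilities.
#' @examples
#' posterior_prob(0)         # = pi = 0.001
#' posterior_prob(log(999))  # 0.5
#' @export
posterior_prob <- function(lr, pi = 0.001) {
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1) {
    stop("'pi' must lie in (0, 1)")
  }
  plogis(lr - log((1 - pi) / pi))
}

#' Select genome-wide significant top SNPs
#'
#' SNPs with `p_value < p_threshold` are clustered into peaks: significant
#' SNPs on the same chromosome closer than `min_peak_gap_bp` are merged, and
#' the maximum-LR SNP of each peak is returned.
#'
#' @param scan a `gwas_scan` data.frame.
#' @param p_threshold genome-wide significance threshold (default 1e-7).
#' @param min_peak_gap_bp peaks closer than this merge (default 1e6).
#' @return Integer vector of row indices into `scan` (possibly empty), with
#'   the selected snp ids as names.
#' @export
select_top_snps <- function(scan, p_threshold = 1e-7, min_peak_gap_bp = 1e6) {
  sig <- which(scan$p_value < p_threshold)
  if (!length(sig)) return(integer(0))
  picks <- integer(0)
  for (ch in unique(scan$chrom[sig])) {
    idx <- sig[scan$chrom[sig] == ch]
    idx <- idx[order(scan$pos[idx])]
    gap_new <- c(TRUE, diff(scan$pos[idx]) >= min_peak_gap_bp)
    peak_id <- cumsum(gap_new)
    for (pk in unique(peak_id)) {
      members <- idx[peak_id == pk]
      picks <- c(picks, members[which.max(scan$lr[members])])
    }
  }
  picks <- sort(picks)
  names(picks) <- scan$snp_id[picks]
  picks
}

#' Assemble per-SNP weights for a weighted relationship matrix
#'
#' `"uniform"`: all 1. `"topsnps"`: 1000 on the selected top SNPs, 1
#' elsewhere. `"gwablup"`: smoothed posterior probabilities as weights.
#' `"custom"`: weights from a TSV with columns `snp_id`, `d` (must be
#' non-negative).
#'
#' @param mode one of `"uniform"`, `"topsnps"`, `"gwablup"`, `"custom"`.
#' @param scan a `gwas_scan` (needed for `topsnps` and `gwablup`).
#' @param m number of SNPs (needed for `uniform` when no scan is given).
#' @param s smoothing window for `gwablup` (default 5).
#' @param pi prior SNP probability for `gwablup` (default 0.001).
#' @param p_threshold,min_peak_gap_bp top-SNP selection parameters
#'   (see [select_top_snps()]).
#' @param top_weight weight given to top SNPs (default 1000).
#' @param path TSV path for `custom` mode.
#' @param snp_ids snp ids to align custom weights against.
#' @return A [snp_weights()] vector.
#' @export
make_weights <- function(mode = c("uniform", "topsnps", "gwablup", "custom"),
                         scan = NULL, m = if (!is.null(scan)) nrow(scan) else NULL,
                         s = 5, pi = 0.001, p_threshold = 1e-7,
                         min_peak_gap_bp = 1e6, top_weight = 1000,
                         path = NULL, snp_ids = NULL) {
  mode <- match.arg(mode)
  if (mode == "uniform") {
    if (is.null(m)) stop("'m' (or a scan) is required for uniform weights")
    return(snp_weights(rep(1, m), mode = "uniform"))
  }
  if (mode == "topsnps") {
    if (is.null(scan)) stop("a scan is required for topsnps weights")
    d <- rep(1, nrow(scan))
    top <- select_top_snps(scan, p_threshold, min_peak_gap_bp)
    d[top] <- top_weight
    out <- snp_weights(d, mode = "topsnps")
    attr(out, "top_snps") <- top
    return(out)
  }
  if (mode == "gwablup") {
    if (is.null(scan)) stop("a scan is required for gwablup weights")
    slr <- smooth_lr(scan, s = s)
    pp <- posterior_prob(slr, pi = pi)
    out <- snp_weights(pp, mode = "gwablup")
    attr(out, "smoothed_lr") <- slr
    attr(out, "s") <- s
    attr(out, "pi") <- pi
    return(out)
  }
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(snp_id = "character"))
  if (!all(c("snp_id", "d") %in% names(df))) {
    stop("custom weights TSV needs columns snp_id, d")
  }
  if (any(df$d < 0)) stop("custom weights must be non-negative")
  if (!is.null(snp_ids)) {
    pos <- match(snp_ids, df$snp_id)
    if (anyNA(pos)) stop("custom weights missing for some SNPs")
    df <- df[pos, ]
  }
  snp_weights(df$d, mode = "custom")
}

#' Pick a smoothing window by validation reliability
#'
#' Builds GWABLUP weights for each candidate window, refits the weighted
#' prediction and scores it against a supplied validation set, returning the
#' window with the highest validation reliability. Note that a window chosen
#' this way is tuned on the validation animals; reliabilities reported for
#' the winning window on the same animals are optimistic.
#'
#' @param scan a `gwas_scan` from the training animals.
#' @param X a [center_genotypes()] result (all animals).
#' @param y named training phenotypes.
#' @param varcomp as in [gblup_solve()].
#' @param y_v validation phenotypes, named by sample id.
#' @param w optional named observation weights.
#' @param windows candidate odd window sizes (default
#'   `c(1, 5, 11, 21, 41, 81, 161)`).
#' @param pi prior SNP probability (default 0.001).
#' @return List: `s` (chosen window), `reliability` (named vector of
#'   validation reliabilities per candidate).
#' @export
tune_window <- function(scan, X, y, varcomp, y_v, w = NULL,
                        windows = c(1, 5, 11, 21, 41, 81, 161), pi = 0.001) {
  if (is.null(names(y_v))) stop("'y_v' must be named by sample id")
  rel <- vapply(windows, function(s) {
    D <- make_weights("gwablup", scan = scan, s = s, pi = pi)
    fit <- gblup_solve(y, build_grm(X, D), varcomp, w = w)
    prediction_reliability(y_v, fit$gebv[names(y_v)])
  }, 0)
  names(rel) <- windows
  list(s = windows[which.max(rel)], reliability = rel)
}

#' Write a weights table (snp_id, chrom, pos, LR, smoothed LR, PP, D) to TSV
#'
#' @param scan a `gwas_scan`.
#' @param D a [make_weights()] result aligned with the scan.
#' @param path output path.
#' @param s,pi smoothing window and prior used for the PP column (taken from
#'   `D`'s attributes when present).
#' @return The path, invisibly.
#' @export
write_weights <- function(scan, D, path, s = attr(D, "s"), pi = attr(D, "pi")) {
  slr <- attr(D, "smoothed_lr")
  if (is.null(slr)) slr <- smooth_lr(scan, s = if (is.null(s)) 5 else s)
  if (is.null(pi)) pi <- 0.001
  df <- data.frame(snp_id = scan$snp_id, chrom = scan$chrom, pos = scan$pos,
                   lr = scan$lr, smoothed_lr = slr,
                   pp = posterior_prob(slr, pi = pi), d = as.numeric(D),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
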