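#' Forward-prediction reliability
#'
#' Squared Pearson correlation between validation phenotypes and their
#' predictions; the standard proxy for prediction reliability in forward
#' validation (invariant to positive linear rescaling of the predictions).
#'
#' @param y_v validation phenotypes (>= 10 values).
#' @param g_hat_v predictions, aligned with `y_v`.
#' @return Squared correlation in `[0, 1]`.
#' @export
prediction_reliability <- function(y_v, g_hat_v) {
  check_validation_pair(y_v, g_hat_v)
  cor(y_v, g_hat_v)^2
}

check_validation_pair <- function(y_v, g_hat_v) {
  if (length(y_v) != length(g_hat_v)) stop("vectors differ in length")
  if (length(y_v) < 10) stop("need at least 10 validation animals")
  if (any(!is.finite(y_v)) || any(!is.finite(g_hat_v))) stop("non-finite values")
  if (sd(y_v) == 0 || sd(g_hat_v) == 0) stop("zero variance in a validation vector")
  invisible(TRUE)
}

#' Dispersion (inflation) bias regression
#'
#' OLS regression of validation phenotypes on predictions, with intercept.
#' Under unbiased BLUP, `Cov(g_hat, g) = Var(g_hat)`, so the slope is 1;
#' slope < 1 flags inflated (over-dispersed) predictions, slope > 1
#' deflated.
#'
#' @inheritParams prediction_reliability
#' @return List: `beta`, `se`, `flag` (`"unbiased"` within 2 se of 1, else
#'   `"inflated"`/`"deflated"`).
#' @export
bias_regression <- function(y_v, g_hat_v) {
  check_validation_pair(y_v, g_hat_v)
  n <- length(y_v)
  gc <- g_hat_v - mean(g_hat_v)
  beta <- sum(gc * y_v) / sum(gc^2)
  resid <- y_v - mean(y_v) - beta * gc
  se <- sqrt(sum(resid^2) / (n - 2) / sum(gc^2))
  flag <- if (abs(beta - 1) <= 2 * se) "unbiased"
          else if (beta < 1) "inflated" else "deflated"
  list(beta = beta, se = se, flag = flag)
}

#' Paired bootstrap test for a difference in prediction reliability
#'
#' Case-resamples validation animals — their `(y, g_hat_k, g_hat_l)` triples
#' — so the two correlations share the resampled phenotypes, and tests
#' `cor_k = cor_l` two-sidedly from the resampled distribution of
#' `cor_k - cor_l` with the standard +1 small-sample correction. Degenerate
#' resamples (zero variance in any vector) are redrawn and counted.
#'
#' @param y_v validation phenotypes.
#' @param g_hat_k,g_hat_l predictions from the two methods.
#' @param B number of bootstrap resamples (>= 1000; default 10000).
#' @param seed RNG seed (results are reproducible given `B`, `seed`).
#' @return List: `p_value`, `diff` (observed `cor_k - cor_l`), `B`,
#'   `n_redrawn`.
#' @export
bootstrap_compare <- function(y_v, g_hat_k, g_hat_l, B = 10000, seed = 1) {
  check_validation_pair(y_v, g_hat_k)
  check_validation_pair(y_v, g_hat_l)
  if (B < 1000) stop("'B' must be at least 1000")
  n <- length(y_v)
  set.seed(seed)
  col_cor <- function(A, C) {
    # columnwise Pearson correlation of two n x B matrices
    Ac <- sweep(A, 2, colMeans(A))
    Cc <- sweep(C, 2, colMeans(C))
    sa <- sqrt(colSums(Ac^2)); sc <- sqrt(colSums(Cc^2))
    colSums(Ac * Cc) / (sa * sc)
  }
  d <- numeric(B)
  todo <- seq_len(B)
  n_redrawn <- 0L
  while (length(todo)) {
    idx <- matrix(sample.int(n, n * length(todo), replace = TRUE), n)
    Y <- matrix(y_v[idx], n); K <- matrix(g_hat_k[idx], n)
    L <- matrix(g_hat_l[idx], n)
    ok <- apply(Y, 2, sd) > 0 & apply(K, 2, sd) > 0 & apply(L, 2, sd) > 0
    d[todo[ok]] <- col_cor(Y[, ok, drop = FALSE], K[, ok, drop = FALSE]) -
      col_cor(Y[, ok, drop = FALSE], L[, ok, drop = FALSE])
    n_redrawn <- n_redrawn + sum(!ok)
    todo <- todo[!ok]
  }
  p <- min(1, 2 * min((1 + sum(d <= 0)) / (B + 1), (1 + sum(d >= 0)) / (B + 1)))
  list(p_value = p, diff = cor(y_v, g_hat_k) - cor(y_v, g_hat_l), B = B,
       n_redrawn = n_redrawn)
}

#' Forward-validation report over several prediction methods
#'
#' Per method: reliability `cor(y_v, g_hat_v)^2`, reliability relative to a
#' reference method, and the bias regression slope. All method pairs are
#' compared by the paired bootstrap, and methods sharing a letter in the
#' compact-letter display are not significantly different at `alpha`.
#'
#' @param y_v validation phenotypes.
#' @param predictions named list of prediction vectors aligned with `y_v`.
#' @param reference name of the reference method (default the first).
#' @param B,seed bootstrap settings (see [bootstrap_compare()]).
#' @param alpha significance level for the letter display (default 0.05).
#' @return List of class `evaluation_report`: `table` (data.frame with
#'   `method`, `cor2`, `relative`, `beta`, `beta_se`, `letters`),
#'   `pairwise_p` (matrix), `B`, `seed`.
#' @export
evaluation_report <- function(y_v, predictions, reference = names(predictions)[1],
                              B = 10000, seed = 1, alpha = 0.05) {
  stopifnot(is.list(predictions), !is.null(names(predictions)))
  if (!reference %in% names(predictions)) stop("unknown reference method")
  meth <- names(predictions)
  cor2 <- vapply(predictions, function(g) prediction_reliability(y_v, g), 0)
  bias <- lapply(predictions, function(g) bias_regression(y_v, g))
  k <- length(meth)
  P <- matrix(1, k, k, dimnames = list(meth, meth))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      P[i, j] <- P[j, i] <- bootstrap_compare(
        y_v, predictions[[i]], predictions[[j]], B = B,
        seed = seed + i * 1000 + j)$p_value
    }
  }
  letters_vec <- compact_letters(P, cor2, alpha)
  tab <- data.frame(method = meth, cor2 = unname(cor2),
                    relative = unname(cor2 / cor2[reference]),
                    beta = vapply(bias, `[[`, 0, "beta"),
                    beta_se = vapply(bias, `[[`, 0, "se"),
                    letters = letters_vec, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(list(table = tab, pairwise_p = P, reference = reference,
                 B = B, seed = seed, alpha = alpha),
            class = "evaluation_report")
}

# greedy compact-letter display: methods ordered by cor2; each letter marks a
# maximal group with no significant pairwise difference
compact_letters <- function(P, cor2, alpha) {
  k <- length(cor2)
  ord <- order(-cor2)
  groups <- list()
  for (i in ord) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(P[i, groups[[gi]]] >= alpha)) {
        groups[[gi]] <- c(groups[[gi]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- i
  }
  out <- character(k)
  for (gi in seq_along(groups)) {
    out[groups[[gi]]] <- paste0(out[groups[[gi]]], letters[gi])
  }
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("forward-validation report (reference:", x$reference, ")\n")
  tab <- x$table
  tab$cor2 <- signif(tab$cor2, 4)
  tab$relative <- signif(tab$relative, 4)
  tab$beta <- sprintf("%.2f +/- %.2f", tab$beta, tab$beta_se)
  tab$beta_se <- NULL
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report to TSV
#' @param report an [evaluation_report()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_evaluation <- function(report, path) {
  write.table(report$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
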