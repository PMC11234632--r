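#' Fit the BayesGC model by Gibbs sampling
#'
#' BayesGC extends GBLUP with a BayesC-type variable-selection term:
#' `y = mu + g + sum_j I_j X_j b_j + e`, with polygenic
#' `g ~ N(0, G sigma2_g)`, inclusion indicators `I_j ~ Bernoulli(pi)`, SNP
#' effects `b_j ~ N(0, sigma2_g / 1000)` by default, and weighted residuals
#' `e ~ N(0, diag(1/w) sigma2_e)`. Variance components stay fixed at their
#' REML estimates; `pi` is fixed, not learned. Each Gibbs cycle samples the
#' mean, every `(I_j, b_j)` pair jointly (effect integrated out of the
#' inclusion odds) in a fresh random order, and the polygenic term in the
#' spectral basis of the training block of `G` (decomposed once). Genetic
#' values of unphenotyped animals are predicted per sample through the
#' `G` cross-covariance block and averaged.
#'
#' @param y named numeric vector of training phenotypes.
#' @param X a [center_genotypes()] result (all animals).
#' @param G unweighted relationship matrix over all animals.
#' @param varcomp as in [gblup_solve()].
#' @param pi prior inclusion probability (default 0.001).
#' @param cycles MCMC cycles per chain (default 10000).
#' @param burnin burn-in cycles (default 2000, must be < cycles).
#' @param chains number of replicate chains (default 10); chain `c` runs
#'   under `set.seed(seed + c - 1)`.
#' @param seed base RNG seed.
#' @param effect_var prior SNP-effect variance (default `sigma2_g / 1000`).
#' @param w optional named observation weights.
#' @return Object of class `bayesgc_fit`: `gebv` (posterior-mean genetic
#'   values, named, all animals in `G`), `pip` (per-SNP posterior inclusion
#'   probability), `effects` (posterior-mean effects), `mu`,
#'   `gebv_by_chain` (animals x chains), `n_incl_trace` (cycles x chains),
#'   `config`.
#' @export
bayesgc_fit <- function(y, X, G, varcomp, pi = 0.001, cycles = 10000,
                        burnin = 2000, chains = 10, seed = 1,
                        effect_var = NULL, w = NULL) {
  vc <- as_varcomp_pair(varcomp)
  if (pi <= 0 || pi >= 1) stop("'pi' must lie in (0, 1)")
  if (burnin >= cycles) stop("'burnin' must be smaller than 'cycles'")
  if (chains < 1) stop("'chains' must be >= 1")
  if (is.null(effect_var)) effect_var <- vc$sigma2_g / 1000
  ids <- names(y)
  if (is.null(ids) || !all(ids %in% rownames(X$X)) || !all(ids %in% G$ids)) {
    stop("'y' must be named by ids present in X and G")
  }
  if (is.null(w)) w <- setNames(rep(1, length(y)), ids)
  w <- as_weight_vector(w)[ids]
  pred_ids <- setdiff(G$ids, ids)

  Gtt <- G$values[ids, ids, drop = FALSE]
  eg <- eigen(Gtt, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1)) {
    stop("G is not positive semidefinite on the training block")
  }
  keep <- eg$values > 1e-8 * max(eg$values)
  U <- eg$vectors[, keep, drop = FALSE]
  S <- eg$values[keep]
  # constant full-conditional precision of the spectral coordinates
  prec_a <- diag(1 / (S * vc$sigma2_g), length(S)) +
    crossprod(U * sqrt(w)) / vc$sigma2_e
  Ra <- chol(prec_a)
  Bv <- if (length(pred_ids)) {
    G$values[pred_ids, ids, drop = FALSE] %*% U %*% diag(1 / S, length(S))
  } else {
    matrix(0, 0, length(S))
  }
  Xt <- X$X[ids, , drop = FALSE]
  Xp <- X$X[pred_ids, , drop = FALSE]

  m <- ncol(Xt)
  gebv_by_chain <- matrix(0, length(G$ids), chains,
                          dimnames = list(c(ids, pred_ids), NULL))
  pip <- numeric(m)
  effects <- numeric(m)
  mu <- 0
  traces <- matrix(0, cycles, chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1)
    res <- .bayesgc_chain(unname(y), Xt, unname(w), U, S, Ra, Bv, Xp,
                          vc$sigma2_g, vc$sigma2_e, effect_var, pi,
                          as.integer(cycles), as.integer(burnin))
    gebv_by_chain[, ch] <- c(res$gebv_train, res$gebv_pred)
    pip <- pip + res$pip / chains
    effects <- effects + res$effects / chains
    mu <- mu + res$mu / chains
    traces[, ch] <- res$n_incl_trace
  }
  gebv <- rowMeans(gebv_by_chain)[G$ids]
  structure(list(gebv = gebv, pip = setNames(pip, X$map$snp_id),
                 effects = setNames(effects, X$map$snp_id), mu = mu,
                 gebv_by_chain = gebv_by_chain[G$ids, , drop = FALSE],
                 n_incl_trace = traces,
                 config = list(pi = pi, cycles = cycles, burnin = burnin,
                               chains = chains, seed = seed,
                               effect_var = effect_var, varcomp = vc)),
            class = "bayesgc_fit")
}

#' @export
print.bayesgc_fit <- function(x, ...) {
  cfg <- x$config
  cat("bayesgc_fit:", length(x$gebv), "animals,", length(x$pip), "SNPs;",
      cfg$chains, "chain(s) x", cfg$cycles, "cycles (burnin", cfg$burnin, ")\n")
  cat("  mean included SNPs (post-burnin):",
      signif(mean(x$n_incl_trace[-seq_len(cfg$burnin), , drop = FALSE]), 4), "\n")
  invisible(x)
}

#' Write BayesGC posterior summaries
#'
#' Writes `<prefix>_snps.tsv` (snp_id, pip, posterior-mean effect),
#' `<prefix>_gebv.tsv`, and `<prefix>_chains.tsv` (per-chain mean and sd of
#' the post-burnin included-SNP counts).
#'
#' @param fit a [bayesgc_fit()] result.
#' @param prefix output path prefix.
#' @param roles optional named roles per sample id (passed to
#'   [write_gebv()]).
#' @return Character vector of the files written, invisibly.
#' @export
bayesgc_report <- function(fit, prefix, roles = NULL) {
  snp_path <- paste0(prefix, "_snps.tsv")
  write.table(data.frame(snp_id = names(fit$pip), pip = unname(fit$pip),
                         effect = unname(fit$effects),
                         stringsAsFactors = FALSE),
              snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  gebv_path <- paste0(prefix, "_gebv.tsv")
  write_gebv(fit, gebv_path, roles = roles)
  post <- fit$n_incl_trace[-seq_len(fit$config$burnin), , drop = FALSE]
  chain_path <- paste0(prefix, "_chains.tsv")
  write.table(data.frame(chain = seq_len(ncol(post)),
                         mean_included = colMeans(post),
                         sd_included = apply(post, 2, sd)),
              chain_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(snp_path, gebv_path, chain_path))
}
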