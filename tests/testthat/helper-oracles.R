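# independent oracle implementations used across tests

# Levene-Haldane probabilities via binomial coefficients (independent of the
# lgamma-based implementation): p-value by brute-force enumeration
hwe_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  nA <- 2 * n_AA + n_AB
  het <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
  probs <- vapply(het, function(h) {
    aa <- (nA - h) / 2
    choose(n, aa) * choose(n - aa, h) * 2^h / choose(2 * n, nA)
  }, 0)
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_AB, het)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# naive double-loop weighted GRM
grm_oracle <- function(X, D, p) {
  n <- nrow(X)
  G <- matrix(0, n, n)
  denom <- sum(2 * p * (1 - p) * D)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    G[i, k] <- sum(X[i, ] * D * X[k, ]) / denom
  }
  G
}

# dense per-SNP generalised least squares scan
gls_scan_oracle <- function(y, Xmat, Gtt, sigma2_g, sigma2_e, w = NULL) {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  V <- Gtt * sigma2_g + diag(sigma2_e / w, n)
  Vi <- solve(V)
  yc <- y - sum(w * y) / sum(w)
  t(vapply(seq_len(ncol(Xmat)), function(j) {
    xj <- Xmat[, j]
    xx <- drop(t(xj) %*% Vi %*% xj)
    xy <- drop(t(xj) %*% Vi %*% yc)
    b <- xy / xx
    c(b_hat = b, se = 1 / sqrt(xx), lr = 0.5 * drop(t(yc) %*% Vi %*% xj) * b)
  }, c(b_hat = 0, se = 0, lr = 0)))
}

# dense restricted log-likelihood (direct V algebra, intercept-only fixed part)
reml_ll_oracle <- function(y, Gtt, sigma2_g, sigma2_e, w = NULL) {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  V <- Gtt * sigma2_g + diag(sigma2_e / w, n)
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  xvx <- drop(t(X) %*% Vi %*% X)
  beta <- drop(t(X) %*% Vi %*% y) / xvx
  r <- y - X %*% beta
  -0.5 * (as.numeric(determinant(V)$modulus) + log(xvx) +
            drop(t(r) %*% Vi %*% r) + (n - 1) * log(2 * pi))
}

# animal-model mixed-model equations with an explicit G inverse; predicts
# data-free animals jointly
gblup_mme_oracle <- function(y, G_all, train_idx, sigma2_g, sigma2_e, w = NULL) {
  n_all <- nrow(G_all)
  n_t <- length(train_idx)
  if (is.null(w)) w <- rep(1, n_t)
  Z <- matrix(0, n_t, n_all)
  Z[cbind(seq_len(n_t), train_idx)] <- 1
  X <- matrix(1, n_t, 1)
  W <- diag(w, n_t)
  C <- rbind(
    cbind(t(X) %*% W %*% X / sigma2_e, t(X) %*% W %*% Z / sigma2_e),
    cbind(t(Z) %*% W %*% X / sigma2_e,
          t(Z) %*% W %*% Z / sigma2_e + solve(G_all) / sigma2_g))
  rhs <- rbind(t(X) %*% W %*% y / sigma2_e, t(Z) %*% W %*% y / sigma2_e)
  sol <- solve(C, rhs)
  list(mu = sol[1], gebv = drop(sol[-1]))
}

# stacked multitrait GLS: Cov(g) = Gcov x G, Cov(e) = Ecov x diag(1/w)
mt_mme_oracle <- function(Y, G_all, train_idx, Gcov, Ecov, w = NULL) {
  k <- ncol(Y)
  n_t <- length(train_idx)
  n_all <- nrow(G_all)
  if (is.null(w)) w <- rep(1, n_t)
  Gtt <- G_all[train_idx, train_idx]
  V <- kronecker(Gcov, Gtt) + kronecker(Ecov, diag(1 / w, n_t))
  Vi <- solve(V)
  Xf <- kronecker(diag(k), matrix(1, n_t, 1))
  yv <- as.vector(Y)
  mu <- solve(t(Xf) %*% Vi %*% Xf, t(Xf) %*% Vi %*% yv)
  r <- yv - Xf %*% mu
  Cgy <- kronecker(Gcov, G_all[, train_idx])
  matrix(Cgy %*% Vi %*% r, n_all, k)
}

# small simulated dataset prepared for model fitting
prep_sim <- function(cfg) {
  dat <- simulate_dataset(cfg)
  train <- dat$obs$sample_id[dat$obs$role == "train"]
  valid <- dat$obs$sample_id[dat$obs$role == "validation"]
  w <- setNames(observation_weight(dat$obs$n_records, vc_alpha(dat$varcomp)),
                dat$obs$sample_id)
  y <- setNames(dat$obs$y[match(train, dat$obs$sample_id)], train)
  X <- center_genotypes(dat$geno, w = w, training_ids = train)
  c(dat, list(train = train, valid = valid, w = w, y = y, X = X,
              y_v = dat$obs$y[match(valid, dat$obs$sample_id)]))
}

random_pd <- function(k, seed) {
  set.seed(seed)
  A <- matrix(rnorm(k * k), k)
  crossprod(A) + diag(k) * 0.5
}

tiny_geno <- function(codes, chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  map <- data.frame(snp_id = sprintf("s%02d", seq_len(m)),
                    chrom = if (is.null(chrom)) rep("1", m) else chrom,
                    pos = if (is.null(pos)) seq_len(m) * 1000L else pos,
                    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  genotype_set(codes, sprintf("id%03d", seq_len(nrow(codes))), map)
}
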