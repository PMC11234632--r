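test_that("diagonal covariances give the identity transform and the genetic
           variances themselves", {
  ct <- canonical_transform(diag(c(0.5, 0.2)), diag(2))
  expect_equal(abs(ct$Q), diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ct$canonical_genetic_variances, c(0.5, 0.2))
})

test_that("the transform simultaneously diagonalises random PD pairs", {
  for (seed in 1:5) {
    G <- random_pd(3, seed)
    E <- random_pd(3, seed + 100)
    ct <- canonical_transform(G, E)
    expect_lt(max(abs(ct$Q %*% E %*% t(ct$Q) - diag(3))), 1e-10)
    QG <- ct$Q %*% G %*% t(ct$Q)
    expect_lt(max(abs(QG - diag(diag(QG)))), 1e-10)
    expect_equal(diag(QG), ct$canonical_genetic_variances, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # descending order and positive sign convention
    expect_true(all(diff(ct$canonical_genetic_variances) <= 1e-12))
    expect_true(all(apply(ct$Q, 1, function(r) r[which.max(abs(r))] > 0)))
    # canonical variances solve the generalised eigenproblem E^-1 G
    ge <- sort(Re(eigen(solve(E) %*% G)$values), decreasing = TRUE)
    expect_equal(ct$canonical_genetic_variances, ge, tolerance = 1e-8)
  }
})

test_that("the two-trait equicorrelated closed form holds", {
  rho_g <- 0.6; rho_e <- 0.3; vg <- 0.4
  G <- vg * matrix(c(1, rho_g, rho_g, 1), 2)
  E <- matrix(c(1, rho_e, rho_e, 1), 2)
  ct <- canonical_transform(G, E)
  expect_equal(ct$canonical_genetic_variances,
               sort(c(vg * (1 + rho_g) / (1 + rho_e),
                      vg * (1 - rho_g) / (1 - rho_e)), decreasing = TRUE),
               tolerance = 1e-10)
})

test_that("canonical variances are invariant to rescaling the original traits", {
  G <- random_pd(3, 7); E <- random_pd(3, 8)
  S <- diag(c(10, 0.2, 3))
  ct1 <- canonical_transform(G, E)
  ct2 <- canonical_transform(S %*% G %*% S, S %*% E %*% S)
  expect_equal(ct1$canonical_genetic_variances,
               ct2$canonical_genetic_variances, tolerance = 1e-8)
})

test_that("forward and back transformation round trip and are linear", {
  G <- random_pd(3, 9); E <- random_pd(3, 10)
  ct <- canonical_transform(G, E)
  set.seed(11)
  Y <- matrix(rnorm(60), 20, 3)
  expect_equal(back_transform(to_canonical(Y, ct), ct), Y,
               tolerance = 1e-10, ignore_attr = TRUE)
  # linearity (superposition)
  A <- matrix(rnorm(60), 20, 3); B <- matrix(rnorm(60), 20, 3)
  expect_equal(back_transform(2 * A + 3 * B, ct),
               2 * back_transform(A, ct) + 3 * back_transform(B, ct),
               tolerance = 1e-12)
  # identity transform is a no-op
  ct_id <- canonical_transform(diag(c(2, 1)), diag(2))
  expect_equal(to_canonical(Y[, 1:2], ct_id), Y[, 1:2],
               tolerance = 1e-12, ignore_attr = TRUE)
  Yna <- Y; Yna[3, 2] <- NA
  expect_error(to_canonical(Yna, ct), "single-trait")
})

test_that("the printed dairy environmental correlations are rejected as
           non-positive-definite, with a clipping escape hatch", {
  re <- c(0.97, -0.17, 0.16)
  E <- diag(3)
  E[lower.tri(E)] <- re; E <- E + t(E) - diag(3)
  expect_lt(min(eigen(E, symmetric = TRUE, only.values = TRUE)$values), 0)
  G <- diag(c(0.26, 0.20, 0.16))
  expect_error(canonical_transform(G, E), "not positive definite")
  ct <- canonical_transform(G, E, make_pd = TRUE)
  expect_true(all(ct$canonical_genetic_variances >= 0))
})

test_that("canonical-route multitrait GBLUP equals the stacked animal-model
           oracle", {
  set.seed(13)
  cfg <- sim_config(n_train = 50, n_validation = 10, m = 150, n_chrom = 2,
                    seed = 14)
  g <- simulate_genotypes(cfg)
  ids <- rownames(g$codes)
  train <- ids[1:50]
  X <- center_genotypes(g, training_ids = train)
  Gu <- build_grm(X)
  Gcov <- random_pd(3, 15) / 3
  Ecov <- random_pd(3, 16)
  set.seed(17)
  Y <- matrix(rnorm(150), 50, 3, dimnames = list(train, paste0("t", 1:3)))
  mt <- mt_predict(Y, X, Gcov, Ecov, mode = "gblup")
  oracle <- mt_mme_oracle(Y, Gu$values, match(train, Gu$ids), Gcov, Ecov)
  expect_lt(max(abs(mt$gebv - oracle)), 1e-6)
})

test_that("summing canonical-trait likelihood ratios behaves like a
           chi-square with one df per trait", {
  cfg <- sim_config(n_train = 250, n_validation = 0, m = 1500,
                    switch_rate = 1, n_qtl = 0, qtl_var_frac = 0, seed = 18)
  g <- simulate_genotypes(cfg)
  ids <- rownames(g$codes)
  X <- center_genotypes(g)
  Gu <- build_grm(X)
  set.seed(19)
  scans <- lapply(1:3, function(k) {
    # EMMAX fixes the components at their own null-model estimates
    yk <- setNames(rnorm(250), ids)
    emmax_scan(yk, X, Gu, reml_estimate(yk, Gu), trait = paste0("c", k))
  })
  comb <- combine_canonical_lr(scans)
  expect_equal(comb$lr, scans[[1]]$lr + scans[[2]]$lr + scans[[3]]$lr)
  expect_lt(abs(mean(2 * comb$lr) - 3), 0.3)
  # single scan is the identity
  one <- combine_canonical_lr(scans[1])
  expect_equal(one$lr, scans[[1]]$lr)
  expect_equal(one$p_value, pchisq(2 * one$lr, 1, lower.tail = FALSE))
  # map mismatch rejected
  bad <- scans[[2]]
  bad$pos[1] <- bad$pos[1] + 1
  expect_error(combine_canonical_lr(list(scans[[1]], bad)), "maps differ")
})

test_that("a QTL affecting one trait dominates the combined scan at the same
           position", {
  d <- prep_sim(sim_config(n_train = 500, n_validation = 0, m = 1000,
                           n_chrom = 2, n_qtl = 1, qtl_var_frac = 0.8,
                           h2 = 0.45, pe_ratio = 0.3, qtl_on_panel = TRUE,
                           seed = 20))
  Gu <- build_grm(d$X)
  vcp <- reml_estimate(d$y, Gu, w = d$w[d$train])
  sc1 <- emmax_scan(d$y, d$X, Gu, vcp, w = d$w[d$train])
  set.seed(21)
  sc0 <- emmax_scan(setNames(rnorm(length(d$y)), names(d$y)), d$X, Gu,
                    list(sigma2_g = 0.1, sigma2_e = 1), w = d$w[d$train])
  comb <- combine_canonical_lr(list(sc1, sc0))
  expect_equal(which.max(comb$lr), which.max(sc1$lr))
})

test_that("cross-trait weights are the geometric mean with the
           Cauchy-Schwarz bound", {
  pp <- runif(50, 0.01, 0.99)
  expect_equal(as.numeric(cross_trait_weights(pp, pp)), pp)
  expect_equal(as.numeric(cross_trait_weights(0.25, 1.0)), 0.5)
  set.seed(22)
  pt <- runif(50, 0.01, 1); ps <- runif(50, 0.01, 1)
  dts <- as.numeric(cross_trait_weights(pt, ps))
  expect_true(all(dts^2 <= pt * ps + 1e-12))
  expect_error(cross_trait_weights(pt, ps[-1]), "length")
  expect_error(cross_trait_weights(pt, ps * 1.5))
})

test_that("a single-trait canonical analysis reproduces single-trait
           GWABLUP exactly", {
  d <- prep_sim(sim_config(n_train = 200, n_validation = 50, m = 400,
                           n_qtl = 2, qtl_var_frac = 0.6, h2 = 0.4,
                           pe_ratio = 0.3, seed = 23))
  Gu <- build_grm(d$X)
  vg <- 0.8; ve <- 1.2
  Y <- matrix(d$y, ncol = 1, dimnames = list(d$train, "t1"))
  mt <- mt_predict(Y, d$X, matrix(vg), matrix(ve), mode = "gwablup", s = 5)
  # single-trait route on the standardised scale: canonical trait is
  # y / sqrt(ve) with genetic variance vg / ve and unit residual variance
  ys <- setNames(d$y / sqrt(ve), d$train)
  sc <- emmax_scan(ys, d$X, Gu, list(sigma2_g = vg / ve, sigma2_e = 1))
  D <- make_weights("gwablup", scan = sc, s = 5)
  fit <- gblup_solve(ys, build_grm(d$X, D),
                     list(sigma2_g = vg / ve, sigma2_e = 1))
  expect_equal(unname(mt$gebv[, 1]),
               unname(fit$gebv[rownames(mt$gebv)] * sqrt(ve)),
               tolerance = 1e-8)
})
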