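test_that("moving-average smoothing respects windows and chromosome ends", {
  # constant series is unchanged by any window
  for (s in c(1, 5, 11, 81)) {
    expect_equal(smooth_lr(rep(3.7, 40), s = s), rep(3.7, 40))
  }
  # truncation rule at the ends
  v <- c(0, 0, 10, 0, 0)
  sm <- smooth_lr(v, s = 5)
  expect_equal(sm[3], 2.0)
  expect_equal(sm[1], 10 / 3)
  expect_equal(sm[2], 10 / 4)
  # no leakage across chromosomes
  lr <- c(0, 0, 0, 0, 50, 0, 0, 0, 0, 0)
  chrom <- rep(c("1", "2"), each = 5)
  sm2 <- smooth_lr(lr, s = 5, chrom = chrom)
  expect_equal(sm2[6:10], rep(0, 5))
  expect_gt(sm2[5], 0)
  # identity window and error cases
  expect_equal(smooth_lr(v, s = 1), v)
  expect_error(smooth_lr(v, s = 4), "odd")
  # nonnegative input stays nonnegative
  set.seed(9)
  x <- rexp(200)
  expect_true(all(smooth_lr(x, s = 21) >= 0))
})

test_that("posterior probabilities follow the mixture closed forms and are
           numerically stable", {
  expect_equal(posterior_prob(0, 0.001), 0.001)
  expect_equal(posterior_prob(log(999), 0.001), 0.5)
  expect_equal(posterior_prob(80, 0.001), 1 - 6.93e-33, tolerance = 1e-34)
  expect_equal(posterior_prob(1e6), 1)   # no overflow
  # strictly monotone in LR and in pi
  lr_grid <- seq(0, 30, length.out = 100)
  expect_true(all(diff(posterior_prob(lr_grid, 0.001)) > 0))
  for (lr in c(0, 2, 10)) {
    pp <- vapply(c(1e-4, 1e-3, 1e-2, 0.1, 0.5), function(p)
      posterior_prob(lr, p), 0)
    expect_true(all(diff(pp) > 0))
  }
  expect_error(posterior_prob(1, 0), "pi")
  expect_error(posterior_prob(1, 1), "pi")
})

test_that("top-SNP selection clusters significant SNPs into peaks", {
  scan <- data.frame(
    snp_id = sprintf("s%02d", 1:8),
    chrom = c("1", "1", "1", "1", "2", "2", "2", "2"),
    pos = c(1e6, 1.01e6, 5e6, 9e6, 1e6, 2e6, 3e6, 8e6),
    lr = c(20, 25, 1, 18, 30, 28, 2, 1),
    p_value = c(1e-9, 1e-11, 0.5, 1e-8, 1e-13, 1e-12, 0.4, 0.6),
    stringsAsFactors = FALSE)
  # gap 1 Mb: chr1 has peaks {s1,s2} (10 kb apart) and {s4}; chr2 peaks
  # {s5} and {s6} (exactly 1 Mb apart does not merge)
  top <- select_top_snps(scan, p_threshold = 1e-7, min_peak_gap_bp = 1e6)
  expect_equal(names(top), c("s02", "s04", "s05", "s06"))
  # bigger gap merges the chr2 pair; max-LR SNP represents each peak
  top2 <- select_top_snps(scan, p_threshold = 1e-7, min_peak_gap_bp = 2e6)
  expect_equal(names(top2), c("s02", "s04", "s05"))
  # nothing significant
  expect_length(select_top_snps(scan, p_threshold = 1e-20), 0)
})

test_that("top SNPs land inside the true QTL regions of a simulation", {
  cfg <- sim_config(n_train = 800, n_validation = 0, m = 2000, n_chrom = 2,
                    n_qtl = 2, qtl_var_frac = 0.7, h2 = 0.45, pe_ratio = 0.3,
                    qtl_on_panel = TRUE, seed = 61)
  d <- prep_sim(cfg)
  Gu <- build_grm(d$X)
  sc <- emmax_scan(d$y, d$X, Gu, reml_estimate(d$y, Gu, w = d$w[d$train]),
                   w = d$w[d$train])
  top <- select_top_snps(sc)
  expect_equal(length(top), 2L)
  for (i in seq_len(nrow(d$qtl))) {
    same_chr <- sc$chrom[top] == d$qtl$chrom[i]
    expect_true(any(same_chr &
                      abs(sc$pos[top] - sc$pos[d$qtl$index[i]]) < 1e6))
  }
})

test_that("weight assembly covers all modes with the stated values", {
  scan <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                     pos = c(1e5, 2e5, 3e5), lr = c(0, 20, 0),
                     p_value = c(1, 1e-10, 1), stringsAsFactors = FALSE)
  expect_equal(as.numeric(make_weights("uniform", m = 3)), rep(1, 3))
  d_top <- make_weights("topsnps", scan = scan)
  expect_equal(as.numeric(d_top), c(1, 1000, 1))   # exactly 1000
  # empty selection degenerates to the uniform vector
  d_none <- make_weights("topsnps", scan = scan, p_threshold = 1e-20)
  expect_equal(as.numeric(d_none), rep(1, 3))
  d_gwa <- make_weights("gwablup", scan = scan, s = 1, pi = 0.001)
  expect_equal(as.numeric(d_gwa), posterior_prob(scan$lr, 0.001))
  # custom weights from TSV, negative rejected
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(snp_id = c("b", "a", "c"), d = c(2, 1, 3)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  d_cst <- make_weights("custom", path = path, snp_ids = c("a", "b", "c"))
  expect_equal(as.numeric(d_cst), c(1, 2, 3))
  write.table(data.frame(snp_id = "a", d = -1), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(make_weights("custom", path = path), "non-negative")
})

test_that("a zero-signal scan yields constant weights equal to the prior,
           hence a matrix identical to the unweighted one", {
  set.seed(62)
  g <- tiny_geno(matrix(rbinom(40 * 60, 2, 0.5), 40, 60))
  X <- center_genotypes(g)
  scan0 <- data.frame(snp_id = g$map$snp_id, chrom = g$map$chrom,
                      pos = g$map$pos, lr = rep(0, 60),
                      p_value = rep(1, 60), stringsAsFactors = FALSE)
  D <- make_weights("gwablup", scan = scan0, s = 5)
  expect_equal(as.numeric(D), rep(0.001, 60))
  G_D <- build_grm(X, D)
  G_u <- build_grm(X)
  expect_lt(max(abs(G_D$values - G_u$values)), 1e-6)
})

test_that("window tuning scores candidate windows on validation data", {
  d <- prep_sim(sim_config(n_train = 400, n_validation = 120, m = 800,
                           n_qtl = 3, qtl_var_frac = 0.6, h2 = 0.4,
                           pe_ratio = 0.3, seed = 63))
  Gu <- build_grm(d$X)
  vcp <- reml_estimate(d$y, Gu, w = d$w[d$train])
  sc <- emmax_scan(d$y, d$X, Gu, vcp, w = d$w[d$train])
  y_v <- setNames(d$y_v, d$valid)
  tw <- tune_window(sc, d$X, d$y, vcp, y_v, w = d$w[d$train],
                    windows = c(1, 5, 21))
  expect_true(tw$s %in% c(1, 5, 21))
  expect_length(tw$reliability, 3)
  expect_equal(unname(tw$reliability[as.character(tw$s)]),
               max(tw$reliability))
})
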