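test_that("observation weights follow the repeatability-model formula", {
  expect_equal(observation_weight(1, 0.3), 1)
  expect_equal(observation_weight(1, 17.2), 1)
  # milk-trait alpha = 735/283 at n = 2
  expect_equal(observation_weight(2, 735 / 283), 1.56495, tolerance = 1e-5)
  # large-n limit is alpha + 1
  expect_equal(observation_weight(1e9, 2), 3, tolerance = 1e-6)
  expect_equal(observation_weight(c(1, 2, 3), Inf), c(1, 2, 3))
  expect_error(observation_weight(0, 1), "'n'")
  expect_error(observation_weight(2, -1), "'alpha'")
})

test_that("yield-deviation reliability matches the printed heritabilities at n = 1", {
  expect_equal(yd_reliability(1, 735 / 448, 283 / 448), 448 / 1466)
  expect_equal(yd_reliability(1, 0.551 / 0.152, 0.199 / 0.152), 0.152 / 0.902)
  expect_equal(yd_reliability(1e9, 1, 1), 0.5, tolerance = 1e-6)
  expect_error(yd_reliability(1, -1, 0.5))
})

test_that("weight and reliability are increasing in n with the stated limits,
           and r2(1) equals the heritability identically", {
  set.seed(1)
  for (rep in 1:25) {
    vc <- variance_components(runif(1, 0.1, 5), runif(1, 0.1, 5),
                              runif(1, 0.1, 5))
    al <- vc_alpha(vc); la <- vc_lambda(vc); ka <- vc_kappa(vc)
    w <- observation_weight(1:20, al)
    r2 <- yd_reliability(1:20, la, ka)
    expect_true(all(diff(w) > 0) && all(diff(r2) > 0))
    expect_true(all(w >= 1 & w < al + 1))
    expect_true(all(r2 > 0 & r2 < 1 / (1 + ka)))
    expect_equal(r2[1], vc_h2(vc))
  }
})

test_that("reference dairy variance components give the exact heritability ratios", {
  h2 <- vapply(norwegian_red_varcomp(), vc_h2, 0)
  expect_equal(unname(h2),
               c(448 / 1466, 642 / 2953, 362 / 1527, 0.152 / 0.902))
})

test_that("HWE exact test matches hand-enumerated cases", {
  expect_equal(hwe_exact_test(0, 2, 0), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-7)
  expect_error(hwe_exact_test(-1, 2, 0), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "positive")
})

test_that("HWE exact test agrees with the enumeration oracle for all
           configurations up to total 50", {
  worst <- 0
  for (n in 1:50) {
    for (n_ab in 0:n) {
      for (n_aa in 0:(n - n_ab)) {
        n_bb <- n - n_ab - n_aa
        worst <- max(worst, abs(hwe_exact_test(n_aa, n_ab, n_bb) -
                                  hwe_oracle(n_aa, n_ab, n_bb)))
      }
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("QC filter applies MAF, call-rate and HWE rules and is idempotent", {
  set.seed(42)
  n <- 100
  codes <- cbind(
    mono = rep(0L, n),                                   # MAF = 0
    hwe_ok = rep(c(0L, 1L, 2L), c(25, 50, 25)),          # p ~ 1
    hwe_bad = rep(c(0L, 2L), c(50, 50)),                 # p << 1e-7
    lowcall = ifelse(seq_len(n) <= 85, 1L, NA),          # 85% call rate
    common = rbinom(n, 2, 0.4))
  g <- tiny_geno(codes)
  filt <- qc_filter(g)
  qc <- attr(filt, "qc")
  expect_equal(n_snps(filt), 2L)  # hwe_ok (s02) and common (s05) survive
  expect_true(all(c("s02", "s05") %in% filt$map$snp_id))
  expect_equal(unname(qc["maf"]), 1)        # the monomorphic SNP
  expect_equal(unname(qc["callrate"]), 1)   # the 85%-call SNP
  # the all-het SNPs (s03 and the observed part of s04) both violate HWE;
  # a SNP failing two filters is counted under each
  expect_equal(unname(qc["hwe"]), 2)
  # idempotent: filtering again removes nothing
  filt2 <- qc_filter(filt)
  expect_equal(attr(filt2, "qc")[["removed"]], 0L)
  expect_identical(filt2$codes, filt$codes)
  # everything failing is an explicit error
  expect_error(qc_filter(tiny_geno(matrix(0L, 10, 2))), "no SNPs survive")
})

test_that("weighted allele frequencies use training animals and weights only", {
  g <- tiny_geno(rbind(c(0L, 2L), c(2L, 2L), c(1L, 2L)))
  w <- setNames(c(1, 3, 10), rownames(g$codes))
  p <- weighted_allele_freq(g, w, c("id001", "id002"))
  expect_equal(unname(p), c(6 / 8, 1))     # (0*1 + 2*3)/(2*4); all-2 SNP
  # equal weights reduce to the plain frequency
  p_eq <- weighted_allele_freq(g, setNames(rep(2, 3), rownames(g$codes)),
                               rownames(g$codes))
  expect_equal(unname(p_eq), c(mean(c(0, 2, 1)) / 2, 1))
  g_na <- tiny_geno(rbind(c(NA, 0L), c(NA, 1L)))
  expect_error(weighted_allele_freq(g_na, setNames(c(1, 1), rownames(g_na$codes)),
                                    rownames(g_na$codes)), "s01")
})

test_that("centred genotypes have zero weighted training mean and imputed zeros", {
  set.seed(7)
  codes <- matrix(rbinom(60 * 20, 2, 0.3), 60, 20)
  codes[sample(length(codes), 40)] <- NA
  g <- tiny_geno(codes)
  ids <- rownames(g$codes)
  w <- setNames(runif(60, 0.5, 3), ids)
  train <- ids[1:45]
  X <- center_genotypes(g, w = w, training_ids = train)
  # missing entries are 0 after centring, regardless of p
  expect_true(all(X$X[is.na(codes)] == 0))
  # weighted training mean of every column is 0 (observed entries only by
  # construction; imputed zeros do not move the mean)
  obs <- !is.na(codes[1:45, , drop = FALSE])
  wt <- w[train]
  col_mean <- vapply(seq_len(20), function(j) {
    o <- obs[, j]
    sum(wt[o] * X$X[train, j][o]) / sum(wt[o])
  }, 0)
  expect_true(all(abs(col_mean) < 1e-10))
  expect_equal(unname(X$X[1, 1]), unname(codes[1, 1] - 2 * X$p[1]))
})

test_that("PLINK binary round trip is bit-exact including missing codes", {
  set.seed(11)
  codes <- matrix(sample(c(0L, 1L, 2L, NA), 17 * 23, replace = TRUE), 17, 23)
  chrom <- rep(c("1", "2"), c(12, 11))
  g <- tiny_geno(codes, chrom = chrom)
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_plink(g, prefix)
  g2 <- read_plink(prefix)
  expect_identical(g2$codes, g$codes)
  expect_identical(g2$map, g$map)
  expect_identical(rownames(g2$codes), rownames(g$codes))
  # corrupt magic bytes (full-length file) and truncation
  bed <- readBin(paste0(prefix, ".bed"), "raw", n = 1e6)
  bed[1] <- as.raw(0)
  writeBin(bed, paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "PLINK")
  writeBin(bed[1:5], paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "truncated")
})

test_that("dosage TSV round trip preserves codes and ids", {
  set.seed(3)
  codes <- matrix(sample(c(0L, 1L, 2L, NA), 8 * 5, replace = TRUE), 8, 5)
  g <- tiny_geno(codes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dosage(g, path)
  g2 <- read_dosage(path, map = g$map)
  expect_identical(unname(g2$codes), unname(codes))
  expect_identical(rownames(g2$codes), rownames(g$codes))
})

test_that("phenotype and variance-component files round trip", {
  obs <- trait_observations(c("a", "b", "c"), c(1.5, -0.2, 3.1),
                            n_records = c(1L, 3L, 2L),
                            birth_year = c(2017L, 2017L, 2018L),
                            role = c("train", "train", "validation"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(obs, path)
  obs2 <- read_phenotypes(path)
  expect_equal(obs2$y, obs$y)
  expect_equal(obs2$role, obs$role)
  expect_equal(trait_names(obs2), "y")

  vcs <- norwegian_red_varcomp()
  vpath <- withr::local_tempfile(fileext = ".yaml")
  write_varcomp(vcs, vpath)
  vcs2 <- read_varcomp(vpath)
  expect_equal(vapply(vcs2, vc_h2, 0), vapply(vcs, vc_h2, 0))
})

test_that("genotype_set enforces its invariants", {
  expect_error(genotype_set(matrix(0L, 2, 2), c("a", "a")), "duplicate")
  expect_error(genotype_set(matrix(3L, 2, 2), c("a", "b")), "codes")
  map <- data.frame(snp_id = c("x", "y"), chrom = "1", pos = c(200L, 100L),
                    allele_a = "A", allele_b = "B")
  expect_warning(g <- genotype_set(matrix(0L, 2, 2), c("a", "b"), map),
                 "reordered")
  expect_equal(g$map$snp_id, c("y", "x"))
})
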