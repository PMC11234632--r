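#' Configuration for the synthetic dairy-data generator
#'
#' Emulates the structure of a cow yield-deviation dataset: LD-structured
#' biallelic genotypes on several chromosomes (haplotype-mosaic model),
#' traits driven by a handful of major QTL plus a polygenic background, and
#' per-animal yield deviations averaged over a variable number of lactations
#' with a permanent-environment effect. Defaults define the package's
#' reference simulation: 800 training + 250 validation animals, 4000 SNPs on
#' 5 chromosomes, 5 QTL jointly explaining half the genetic variance,
#' heritability 0.3 and a permanent-environment/genetic ratio of 0.6
#' (close to the milk-trait ratio 283/448), 1-4 lactations per cow.
#'
#' @param n_train,n_validation numbers of training / validation animals.
#' @param m total number of SNPs, split evenly over `n_chrom` chromosomes.
#' @param n_chrom number of chromosomes.
#' @param n_founders founder haplotypes per chromosome (LD-block donors).
#' @param switch_rate per-SNP probability that a haplotype switches its
#'   donor founder; small values give long shared segments (high LD),
#'   `switch_rate = 1` gives independent SNPs.
#' @param maf_range founder allele-frequency range (uniform draw).
#' @param spacing_bp distance between adjacent SNPs in bp.
#' @param n_qtl number of major QTL (spread round-robin over chromosomes).
#' @param qtl_var_frac fraction of genetic variance explained jointly by the
#'   major QTL (the rest is a polygenic tail over all remaining SNPs).
#' @param h2 narrow-sense heritability
#'   `sigma2_g / (sigma2_g + sigma2_pe + sigma2_e)` in (0, 1).
#' @param pe_ratio `sigma2_pe / sigma2_g`.
#' @param sigma2_g genetic variance (trait-unit scale; default 1).
#' @param n_lact_max lactation counts are uniform on `1..n_lact_max`.
#' @param qtl_on_panel if `FALSE` (default), the causal variants are masked
#'   from the marker panel returned by [simulate_dataset()], so predictions
#'   must work through markers in LD with them — the situation the study's
#'   SNP-weighting methods are designed for. `TRUE` keeps causal variants
#'   as genotyped markers.
#' @param Gcov,Ecov optional multitrait genetic / non-genetic covariance
#'   matrices; when given, traits are generated jointly (single record per
#'   animal, the non-genetic part drawn from `Ecov`).
#' @param seed RNG seed used by the generator functions.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_train = 800, n_validation = 250, m = 4000,
                       n_chrom = 5, n_founders = 20, switch_rate = 0.05,
                       maf_range = c(0.05, 0.95), spacing_bp = 10000,
                       n_qtl = 5, qtl_var_frac = 0.5, h2 = 0.3,
                       pe_ratio = 0.6, sigma2_g = 1, n_lact_max = 4,
                       qtl_on_panel = FALSE, Gcov = NULL, Ecov = NULL,
                       seed = 1) {
  cfg <- list(n_train = n_train, n_validation = n_validation, m = m,
              n_chrom = n_chrom, n_founders = n_founders,
              switch_rate = switch_rate, maf_range = maf_range,
              spacing_bp = spacing_bp, n_qtl = n_qtl,
              qtl_var_frac = qtl_var_frac, h2 = h2, pe_ratio = pe_ratio,
              sigma2_g = sigma2_g, n_lact_max = n_lact_max,
              qtl_on_panel = qtl_on_panel, Gcov = Gcov, Ecov = Ecov,
              seed = seed)
  if (n_train < 1 || n_validation < 0 || m < 1 || n_chrom < 1) {
    stop("infeasible population sizes")
  }
  if (m < n_qtl) stop("'m' must be at least 'n_qtl'")
  if (qtl_var_frac < 0 || qtl_var_frac > 1) stop("'qtl_var_frac' must lie in [0, 1]")
  if (is.null(Gcov)) {
    if (h2 <= 0 || h2 >= 1) stop("'h2' must lie in (0, 1)")
    if ((1 - h2) / h2 <= pe_ratio) stop("h2 and pe_ratio leave no residual variance")
  } else if (is.null(Ecov)) {
    stop("multitrait mode needs both Gcov and Ecov")
  }
  if (switch_rate <= 0 || switch_rate > 1) stop("'switch_rate' must lie in (0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate LD-structured genotypes (haplotype mosaic)
#'
#' Per chromosome, a pool of founder haplotypes is drawn at founder allele
#' frequencies uniform on `maf_range`; each individual haplotype copies
#' alleles from a founder, re-choosing its donor with probability
#' `switch_rate` at each SNP. Small switch rates create long shared segments
#' and hence realistic LD decay; the realised MAF spectrum is attached as
#' attribute `"realized_maf"`.
#'
#' @param config a [sim_config()].
#' @return A [genotype_set()] of `n_train + n_validation` animals (training
#'   animals first; ids `an00001`, ...).
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  n <- config$n_train + config$n_validation
  n_hap <- 2L * n
  m_per <- diff(round(seq(0, config$m, length.out = config$n_chrom + 1)))
  codes <- matrix(0L, n, config$m)
  maps <- vector("list", config$n_chrom)
  col0 <- 0L
  for (ch in seq_len(config$n_chrom)) {
    mc <- m_per[ch]
    pf <- runif(mc, config$maf_range[1], config$maf_range[2])
    FH <- matrix(rbinom(config$n_founders * mc, 1L, rep(pf, each = config$n_founders)),
                 config$n_founders, mc)
    f <- sample.int(config$n_founders, n_hap, replace = TRUE)
    H <- matrix(0L, n_hap, mc)
    for (j in seq_len(mc)) {
      if (j > 1L) {
        sw <- runif(n_hap) < config$switch_rate
        if (any(sw)) f[sw] <- sample.int(config$n_founders, sum(sw), replace = TRUE)
      }
      H[, j] <- FH[cbind(f, j)]
    }
    codes[, col0 + seq_len(mc)] <- H[seq(1, n_hap, 2), , drop = FALSE] +
      H[seq(2, n_hap, 2), , drop = FALSE]
    maps[[ch]] <- data.frame(
      snp_id = sprintf("c%d_s%04d", ch, seq_len(mc)),
      chrom = as.character(ch), pos = seq_len(mc) * config$spacing_bp,
      allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
    col0 <- col0 + mc
  }
  ids <- sprintf("an%05d", seq_len(n))
  g <- genotype_set(codes, ids, do.call(rbind, maps))
  p <- colMeans(g$codes) / 2
  attr(g, "realized_maf") <- pmin(p, 1 - p)
  g
}

#' Simulate yield-deviation phenotypes with known genetic values
#'
#' True genetic value = major-QTL effects (one QTL per chromosome,
#' round-robin, drawn among SNPs with realised MAF > 0.1) plus a polygenic
#' tail of small effects on all remaining SNPs; both parts are rescaled so
#' the realised genetic variance and QTL share hit their targets exactly.
#' Each cow gets `n_i ~ Uniform\{1..n_lact_max\}` lactation records
#' `g_i + pe_i + e_il`, and her phenotype is the yield deviation (record
#' mean). In multitrait mode (config with `Gcov`/`Ecov`) effects are drawn
#' jointly across traits and each animal has one record whose non-genetic
#' part comes from `Ecov`.
#'
#' @param g a [simulate_genotypes()] result.
#' @param config the same [sim_config()].
#' @return List: `obs` ([trait_observations()], training animals first),
#'   `true_g` (named vector, or matrix in multitrait mode), `varcomp`
#'   ([variance_components()], or per-trait list), `qtl` (data.frame of QTL
#'   snp ids and effects), `realized` (named realised-variance summary).
#' @export
simulate_phenotypes <- function(g, config) {
  set.seed(config$seed + 1L)
  n <- nrow(g$codes)
  ids <- rownames(g$codes)
  role <- rep(c("train", "validation"), c(config$n_train, config$n_validation))
  maf <- attr(g, "realized_maf")
  if (is.null(maf)) {
    p <- colMeans(g$codes, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
  }
  Xc <- scale(g$codes, center = TRUE, scale = FALSE)
  qtl_idx <- integer(0)
  if (config$n_qtl > 0 && config$qtl_var_frac > 0) {
    chroms <- unique(g$map$chrom)
    use_ch <- rep_len(chroms, config$n_qtl)
    qtl_idx <- vapply(seq_len(config$n_qtl), function(q) {
      cand <- which(g$map$chrom == use_ch[q] & maf > 0.1)
      if (!length(cand)) cand <- which(g$map$chrom == use_ch[q])
      cand <- setdiff(cand, qtl_idx)
      sample(cand, 1L)
    }, 0L)
  }

  scale_to <- function(vals, target_var) {
    if (target_var <= 0 || all(vals == 0)) return(vals * 0)
    vals * sqrt(target_var / var(vals))
  }

  if (is.null(config$Gcov)) {
    sg <- config$sigma2_g
    spe <- config$pe_ratio * sg
    se <- sg * (1 - config$h2) / config$h2 - spe
    g_qtl <- if (length(qtl_idx)) {
      # each major QTL contributes an equal share of the QTL variance
      per_qtl <- vapply(qtl_idx, function(qi) {
        scale_to(Xc[, qi] * sample(c(-1, 1), 1),
                 config$qtl_var_frac * sg / length(qtl_idx))
      }, numeric(n))
      scale_to(rowSums(per_qtl), config$qtl_var_frac * sg)
    } else rep(0, n)
    poly_idx <- setdiff(seq_len(ncol(Xc)), qtl_idx)
    g_poly <- scale_to(drop(Xc[, poly_idx, drop = FALSE] %*% rnorm(length(poly_idx))),
                       (1 - config$qtl_var_frac) * sg)
    true_g <- setNames(g_qtl + g_poly, ids)
    n_i <- sample.int(config$n_lact_max, n, replace = TRUE)
    pe <- rnorm(n, 0, sqrt(spe))
    ebar <- rnorm(n, 0, sqrt(se / n_i))
    y <- true_g + pe + ebar
    obs <- trait_observations(ids, y, n_i,
                              birth_year = 2017L + (role == "validation"),
                              role = role)
    vc <- variance_components(sg, spe, se)
    realized <- c(var_g = var(true_g), var_pe = var(pe),
                  mean_lact = mean(n_i))
    qtl_df <- if (length(qtl_idx)) {
      data.frame(snp_id = g$map$snp_id[qtl_idx], index = qtl_idx,
                 chrom = g$map$chrom[qtl_idx], stringsAsFactors = FALSE)
    } else data.frame()
    return(list(obs = obs, true_g = true_g, varcomp = vc, qtl = qtl_df,
                realized = realized))
  }

  # multitrait: joint effects across traits, one record per animal
  Gcov <- as.matrix(config$Gcov)
  Ecov <- as.matrix(config$Ecov)
  t_names <- rownames(Gcov)
  if (is.null(t_names)) t_names <- paste0("trait", seq_len(nrow(Gcov)))
  k <- nrow(Gcov)
  Rg <- chol(cov2cor(Gcov))
  draw_cor <- function(nr) matrix(rnorm(nr * k), nr) %*% Rg
  Gq <- if (length(qtl_idx)) {
    raw <- Xc[, qtl_idx, drop = FALSE] %*% draw_cor(length(qtl_idx))
    apply(raw, 2, function(v) if (var(v) > 0) v / sd(v) else v)
  } else matrix(0, n, k)
  poly_idx <- setdiff(seq_len(ncol(Xc)), qtl_idx)
  wq <- sqrt(config$qtl_var_frac); wp <- sqrt(1 - config$qtl_var_frac)
  Gp <- Xc[, poly_idx, drop = FALSE] %*% draw_cor(length(poly_idx))
  Gp <- apply(Gp, 2, function(v) v / sd(v))
  G_true <- sapply(seq_len(k), function(j) {
    scale_to(wq * Gq[, j] + wp * Gp[, j], Gcov[j, j])
  })
  E <- matrix(rnorm(n * k), n) %*% chol(Ecov)
  Y <- G_true + E
  colnames(Y) <- t_names
  rownames(G_true) <- ids
  colnames(G_true) <- t_names
  obs <- trait_observations(ids, Y, rep(1L, n),
                            birth_year = 2017L + (role == "validation"),
                            role = role)
  list(obs = obs, true_g = G_true,
       varcomp = lapply(seq_len(k), function(j) {
         list(sigma2_g = Gcov[j, j], sigma2_e = Ecov[j, j])
       }),
       qtl = if (length(qtl_idx)) {
         data.frame(snp_id = g$map$snp_id[qtl_idx], index = qtl_idx,
                    chrom = g$map$chrom[qtl_idx], stringsAsFactors = FALSE)
       } else data.frame(),
       realized = c(gcor = if (k > 1) cor(G_true[, 1], G_true[, 2]) else NA_real_))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_genotypes()] then
#' [simulate_phenotypes()]. With the default `qtl_on_panel = FALSE`, the
#' causal variants are removed from the returned marker panel after the
#' phenotypes are generated; `qtl` then records, per causal variant, the
#' index of the nearest remaining panel SNP (`panel_index`).
#'
#' @param config a [sim_config()].
#' @return List: `geno` (the marker panel), plus all elements of the
#'   phenotype simulation.
#' @export
simulate_dataset <- function(config = sim_config()) {
  geno <- simulate_genotypes(config)
  out <- c(list(geno = geno), simulate_phenotypes(geno, config))
  if (!isTRUE(config$qtl_on_panel) && nrow(out$qtl)) {
    qtl_idx <- out$qtl$index
    out$qtl$pos <- geno$map$pos[qtl_idx]
    keep <- setdiff(seq_len(ncol(geno$codes)), qtl_idx)
    out$geno <- genotype_set(geno$codes[, keep, drop = FALSE],
                             rownames(geno$codes),
                             geno$map[keep, , drop = FALSE])
    attr(out$geno, "realized_maf") <- attr(geno, "realized_maf")[keep]
    out$qtl$panel_index <- vapply(seq_len(nrow(out$qtl)), function(i) {
      same <- which(out$geno$map$chrom == out$qtl$chrom[i])
      same[which.min(abs(out$geno$map$pos[same] - out$qtl$pos[i]))]
    }, 0L)
    out$qtl$index <- NULL
  }
  out
}
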