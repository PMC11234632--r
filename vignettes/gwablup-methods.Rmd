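---
title: "GWAS-assisted genomic prediction: models, weights and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GWAS-assisted genomic prediction: models, weights and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwablup)
```

## The problem

GBLUP and SNP-BLUP, the workhorses of genomic selection, give every marker
the same prior variance, although most markers sit nowhere near a causal
variant. This package implements GWABLUP, which instead lets a genome-wide
association scan set the weight of *every* SNP in the prediction model:

1. a mixed-model (EMMAX-type) GWAS on the training animals produces a
   log-likelihood ratio `LR_j` per SNP;
2. the `LR_j` are smoothed by a moving average along each chromosome;
3. the smoothed values are converted into posterior probabilities of a
   non-zero effect given a prior `pi`;
4. those probabilities become the diagonal weights of a weighted genomic
   relationship matrix;
5. a standard (weighted) GBLUP yields the predictions.

The package also implements the comparison methods — uniform GBLUP, the
top-SNP variant that upweights genome-wide significant peaks by a factor
1000, and BayesGC, a Gibbs-sampled variable-selection model — together with
a canonical-transformation multitrait extension, forward-validation
statistics, and a synthetic-data generator so that every claim is testable
without access to the original cattle data.

## Data model

Phenotypes are yield deviations (YD): phenotypes corrected for systematic
effects and averaged over a cow's `n_i` lactations. With genetic,
permanent-environment and residual variances $\sigma^2_g, \sigma^2_{pe},
\sigma^2_e$ and ratios $\lambda = \sigma^2_e/\sigma^2_g$,
$\kappa = \sigma^2_{pe}/\sigma^2_g$, $\alpha = \sigma^2_e/\sigma^2_{pe}$:

* reliability of a YD: $r_i^2 = n_i / (n_i + \lambda + n_i \kappa)$ —
  at $n_i = 1$ this is exactly the heritability;
* observation weight: $w_i = n_i(\alpha + 1)/(\alpha + n_i)$, used as a
  diagonal residual weight $R = \mathrm{diag}(w_i^{-1})$ in every analysis.

The weight arises because a YD averaged over $n_i$ records has non-genetic
variance $\sigma^2_{pe} + \sigma^2_e/n_i = (\sigma^2_{pe} +
\sigma^2_e)/w_i$: under Eq.-style weighting the *model* residual variance is
the single parameter $\sigma^2_{pe} + \sigma^2_e$. Consequently, when
`reml_estimate()` is run on weighted YD, its "residual" estimates
$\sigma^2_{pe} + \sigma^2_e$, and `vc_h2`-style ratios of the fitted
components recover the full heritability.

Genotypes are allele-B dosages 0/1/2. Centred scores use *weighted* training
allele frequencies, $X_{ij} = M_{ij} - 2p_j$, which makes the weighted
training mean of every column zero; the GWAS can therefore omit the
intercept (the mean is orthogonal to every SNP effect). Missing genotypes
are excluded from frequency estimation and set to 0 after centring (mean
imputation on the centred scale) — a convention of this package, suited to
datasets that arrive fully imputed.

QC keeps a SNP iff MAF > 0.01 (strict), call rate ≥ 0.9, and the
Levene–Haldane HWE exact two-sided p-value > 1e-7 (no mid-p).

## Relationship matrices and the prediction models

The weighted matrix is the VanRaden-style quadratic form
$G_D = XDX' / \sum_j 2p_j(1-p_j)D_{jj}$, built once over all (training plus
validation) animals with the training-derived denominator. Its expectation
is invariant to `D` (both diagonals estimate $1 + F_i$), so any constant
weight vector reproduces the unweighted $G_u$ exactly — a reduction the test
suite asserts to machine precision. Zero-weight SNPs are skipped in the
accumulation. No blending toward the identity is applied by default; tests
that need an explicit $G^{-1}$ add a small ridge themselves.

GBLUP solves $y = \mu + g + e$, $g \sim N(0, G\sigma^2_g)$,
$e \sim N(0, R\sigma^2_e)$, with GLS for $\mu$ and the cross-covariance
block for unphenotyped animals. The residual weights $w_i$ are applied in
GBLUP as well as in the GWAS — applying them in both models is this
package's consistent convention. SNP-BLUP solves
the equivalent marker-effect system with per-SNP prior variance
$\sigma^2_g D_{jj} / \sum_j 2p_j(1-p_j)D_{jj}$; equality of the two routes
for arbitrary positive weights is a core acceptance property (1e-6
relative).

Variance components come from average-information REML on the rotated
(spectral) representation, with an EM-type positive fallback step and
backtracking so the accepted restricted likelihood never decreases.
Weighted-matrix analyses reuse the $G_u$-based estimates by default
(re-estimating with $G_D$ would let the GWAS-derived weights feed back into
the variance components); `run_gwablup(reml = TRUE)` re-estimates on
$G_u$, `vc = NULL` does the same without the record-count weights.

## The scan and the weights

EMMAX fixes $(\sigma^2_g, \sigma^2_e)$ at their null-model estimates and
tests one SNP at a time by GLS. After one $O(n^3)$ spectral rotation every
SNP costs $O(n)$, and
$LR_j = \tfrac12 y'V^{-1}X_j\hat b_j = \tfrac12 (\hat b_j/se_j)^2$ —
the identity is asserted per SNP at 1e-8. P-values use the
$\chi^2_1$ upper tail of $2LR$ on the log scale, stable to arbitrarily
large LR (at LR = 80, $-\log_{10}p = 35.95$).

Smoothing windows are odd sizes from {1, 5, 11, 21, 41, 81, 161}; 5 suits
strong-signal traits, 81 weak-signal (highly polygenic) ones. Windows
truncate at chromosome boundaries with the
divisor equal to the number of SNPs actually present — this keeps constant
series invariant and prevents cross-chromosome leakage; zero-padding and
wrap-around were rejected for violating those two properties. The boundary
convention is this package's choice. A validation-based
window pick (`tune_window()`) is available but deliberately not a default:
a window tuned on validation animals makes their reliabilities optimistic.

Posterior probabilities follow the two-component mixture
$PP_j = \pi e^{LR_j} / (\pi e^{LR_j} + 1 - \pi)$ with default
$\pi = 0.001$, computed in the stable logistic form
$1/(1+\exp(\log((1-\pi)/\pi) - LR))$; weights are naturally $\geq \pi > 0$,
so $G_D$ stays well defined without flooring. Top-SNP mode clusters
genome-wide significant SNPs ($p < 10^{-7}$) into peaks (same chromosome,
gaps under 1 Mb merge — a deterministic, reproducible replacement for
selecting peaks by eye) and gives the maximum-LR SNP of each peak weight
1000.

## BayesGC

BayesGC adds a BayesC-type term to GBLUP:
$y = \mu + g + \sum_j I_j X_j b_j + e$ with $P(I_j = 1) = \pi = 0.001$ and
$b_j \sim N(0, \sigma^2_g/1000)$. The Gibbs sampler fixes the variance
components at their REML estimates (they are not resampled), samples each $(I_j, b_j)$ jointly with the effect
integrated out of the inclusion odds (standard BayesC practice, chosen for
mixing), visits SNPs in a fresh random order each cycle, and draws the
polygenic term in the spectral basis of the training block of $G_u$, whose
full-conditional precision is constant and factorised once. Production
defaults are 10,000 cycles, 2,000 burn-in, 10 chains; the tests run
desk-scale chains (≈2,000 cycles, 2 chains), which the recovery and
collapse properties show to be sufficient at those problem sizes. Chains
use R's RNG (one stream per chain), so runs are bit-reproducible given a
seed; permutation equivariance across SNP columns is therefore statistical
rather than exact.

## Multitrait analysis

With complete records, simultaneous diagonalisation of the genetic and
environmental covariance matrices turns the multitrait animal model into
independent single-trait models on canonical traits with unit environmental
variance; back-transforming the canonical predictions reproduces the
stacked multitrait solution (asserted against a dense stacked-MME oracle).
Canonical-trait likelihood ratios simply add, and one shared
posterior-probability vector — hence one $G_D$ — is used for all canonical
traits, under the assumption that a SNP important for one trait matters for
all; the per-trait-pair alternative
$D_{jj}(t,s) = \sqrt{PP_j(t)PP_j(s)}$ is provided but not the default.
Observation weights pass through the transformation unchanged (an
assumption: heterogeneous-reliability multitrait weighting has no exact
canonical form). Non-positive-definite environmental matrices are rejected
by default with an explicit eigenvalue message — rounded published
correlation estimates can form exactly such a matrix: the dairy three-trait
set (0.97, −0.17, 0.16) has a negative eigenvalue under unit-variance
reconstruction, so no canonical variances exist for it as printed; an
opt-in `make_pd` clips eigenvalues at 1e-6 instead.

## Forward validation

Reliability is $\mathrm{cor}(y_v, \hat g_v)^2$ over the validation animals,
reported relative to GBLUP. Dispersion bias is the OLS slope of $y_v$ on
$\hat g_v$ (slope < 1 ⇒ inflated). Method pairs are compared with a paired
case bootstrap — resampling $(y, \hat g^k, \hat g^l)$ triples so both
correlations share phenotypes — using the difference of correlations as the
statistic, a two-sided percentile p-value with the +1 correction, and
B = 10,000 by default; degenerate resamples are redrawn and counted. A
compact-letter display summarises all pairwise tests at the 5% level.
Unweighted correlations are the default (a weighted variant exists behind a
flag).

## The synthetic-data generator

`sim_config()`/`simulate_dataset()` emulate the structure of a large dairy
yield-deviation dataset rather than its scale:

* **Genotypes** use a haplotype-mosaic model: per chromosome, founder
  haplotypes are drawn at frequencies uniform on [0.05, 0.95] and each
  individual haplotype copies from a founder, switching donors with
  probability `switch_rate` per SNP. The founder-pool size sets the LD
  *ceiling* (population r² between nearby SNPs ≈ 1/K for independent
  founder alleles) and the switch rate its decay length. This deliberately
  reproduces only block-wise LD — no deep genealogy, no mutation model, no
  allele-frequency spectrum realism.
* **Traits** combine `n_qtl` major QTL, each contributing an equal share of
  `qtl_var_frac` of the genetic variance (random sign), with a polygenic
  tail over all remaining SNPs; both parts are rescaled so the realised
  genetic variance matches its target (a few percent of slack remains from
  LD-induced covariance between the parts). By default the causal variants
  are *masked from the returned marker panel* (`qtl_on_panel = FALSE`):
  markers can only tag them through LD, which is the situation GWAS-based
  SNP weighting is designed for. Recovery-style tests that ask "is the
  genotyped causal SNP found?" opt back in.
* **Records**: each cow gets 1–4 lactations, a permanent-environment
  effect, and a YD equal to the record mean, so the Eq.-1 weights and
  reliabilities are exercised end to end. True breeding values are
  returned for oracle evaluation.

Reference conditions used by the acceptance properties (chosen once as this
package's desk-scale study): n_train = 800, n_val = 250, m = 4,000 SNPs on
5 chromosomes, h² = 0.3, $\sigma^2_{pe}/\sigma^2_g = 0.6$ (close to the
milk-trait ratio), 5 QTL at 50% of genetic variance for the QTL
architecture, 20 replicate seeds. On these conditions GWABLUP (window 5)
significantly outperforms GBLUP while the fully polygenic architecture
(window 81) ties it — the qualitative pattern reported for yield traits
versus somatic cell count. Two desk-scale artefacts are worth knowing:
top-SNP selection is usually *empty* here because no SNP reaches the fixed
1e-7 genome-wide threshold at n = 800 (top-SNP mode then coincides with
GBLUP, consistent with its need for strong significant peaks), and the
bias (slope) property is evaluated on the fully polygenic architecture with
a 60-founder pool and true variance components — BLUP unbiasedness is a
known-components statement, and an overly related validation cohort makes
the OLS slope standard error understate the replicate spread.

## Numerical choices and limitations

* Spectral rotation is the single $O(n^3)$ step shared by REML, the scan
  and the sampler; direct Cholesky solves are the reference path with a
  Jacobi-preconditioned conjugate-gradient fallback (tolerance 1e-8) for
  large n; the two agree to 1e-6 in tests.
* REML converges on a relative parameter change below 1e-6 or 100
  iterations; non-convergence is flagged, not thrown. Degenerate scan
  columns (no variance after centring) get LR = 0 and a flag.
* HWE exact p-values sum configuration probabilities ≤ the observed one
  (two-sided, no mid-p); ties are included with a 1e-9 relative guard.
* The package handles missing genotype codes but not missing multitrait
  records, pedigrees, single-step H-matrices, or genotype imputation.
* Simulation sizes in tests are desk-scale; passing them shows the
  machinery is correct and the qualitative method ranking holds under the
  stated architectures, not that the quantitative gains transfer to any
  real population.
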