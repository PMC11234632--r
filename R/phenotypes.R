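#' Variance components of a repeated-records trait
#'
#' Container for the genetic, permanent-environment and residual variances of
#' a trait with repeated records (e.g. lactation yield deviations). The
#' derived ratios used throughout the package are always recomputed from the
#' three stored components, never cached.
#'
#' @param sigma2_g genetic variance (squared trait units), > 0.
#' @param sigma2_pe permanent-environment variance, > 0.
#' @param sigma2_e residual variance, > 0.
#' @return An object of class `variance_components`.
#' @seealso [vc_lambda()], [vc_kappa()], [vc_alpha()], [vc_h2()]
#' @export
variance_components <- function(sigma2_g, sigma2_pe, sigma2_e) {
  for (v in c(sigma2_g = sigma2_g, sigma2_e = sigma2_e)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("genetic and residual variances must be single positive numbers")
    }
  }
  if (!is.numeric(sigma2_pe) || length(sigma2_pe) != 1L ||
      !is.finite(sigma2_pe) || sigma2_pe < 0) {
    stop("permanent-environment variance must be >= 0")
  }
  structure(list(sigma2_g = sigma2_g, sigma2_pe = sigma2_pe, sigma2_e = sigma2_e),
            class = "variance_components")
}

#' Derived variance ratios
#'
#' `vc_lambda()` is residual/genetic, `vc_kappa()` permanent-environment/
#' genetic, `vc_alpha()` residual/permanent-environment, and `vc_h2()` the
#' heritability genetic/(genetic + permanent environment + residual).
#'
#' @param vc a [variance_components()] object.
#' @return A single numeric value.
#' @export
vc_lambda <- function(vc) vc$sigma2_e / vc$sigma2_g

#' @rdname vc_lambda
#' @export
vc_kappa <- function(vc) vc$sigma2_pe / vc$sigma2_g

#' @rdname vc_lambda
#' @export
vc_alpha <- function(vc) vc$sigma2_e / vc$sigma2_pe

#' @rdname vc_lambda
#' @export
vc_h2 <- function(vc) vc$sigma2_g / (vc$sigma2_g + vc$sigma2_pe + vc$sigma2_e)

#' @export
print.variance_components <- function(x, ...) {
  cat("variance components: g =", x$sigma2_g, " pe =", x$sigma2_pe,
      " e =", x$sigma2_e, "\n")
  cat("  h2 =", signif(vc_h2(x), 4), " lambda =", signif(vc_lambda(x), 4),
      " kappa =", signif(vc_kappa(x), 4), " alpha =", signif(vc_alpha(x), 4), "\n")
  invisible(x)
}

#' Norwegian Red routine-evaluation variance components
#'
#' Variance components of four dairy traits (milk, fat and protein yield in
#' kg, log somatic cell count) as used in Norwegian Red national breeding
#' value evaluations. Milk components are on the 10^3 kg^2 scale. These serve
#' as reference inputs for worked examples.
#'
#' @return A named list of [variance_components()], one per trait.
#' @examples
#' sapply(norwegian_red_varcomp(), vc_h2)
#' @export
norwegian_red_varcomp <- function() {
  list(
    milk    = variance_components(448,   283,   735),
    fat     = variance_components(642,   529,   1782),
    protein = variance_components(362,   347,   818),
    scc     = variance_components(0.152, 0.199, 0.551)
  )
}

#' Observation weight for an averaged yield deviation
#'
#' A yield deviation averaged over `n` repeated records is weighted by
#' `w = n (alpha + 1) / (alpha + n)`, where `alpha` is the ratio of residual
#' to permanent-environment variance. `w(1) = 1` and `w` increases towards
#' `alpha + 1` as `n` grows.
#'
#' @param n number of records (>= 1); vectorised.
#' @param alpha residual / permanent-environment variance ratio, > 0
#'   (`Inf`, the no-permanent-environment limit, gives `w = n`).
#' @return Numeric vector of weights in `[1, alpha + 1)`.
#' @export
observation_weight <- function(n, alpha) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop("'n' must be numeric and >= 1")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("'alpha' must be a single positive number")
  }
  if (is.infinite(alpha)) return(n + 0)
  n * (alpha + 1) / (alpha + n)
}

#' Reliability of an averaged yield deviation
#'
#' `r2 = n / (n + lambda + n kappa)` for an animal with `n` records, where
#' `lambda` is residual/genetic and `kappa` permanent-environment/genetic
#' variance. At `n = 1` this equals the trait heritability; as `n` grows it
#' approaches `1 / (1 + kappa)`.
#'
#' @param n number of records (>= 1); vectorised.
#' @param lambda residual / genetic variance ratio, > 0.
#' @param kappa permanent-environment / genetic variance ratio, >= 0.
#' @return Numeric vector of reliabilities in (0, 1).
#' @export
yd_reliability <- function(n, lambda, kappa) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop("'n' must be numeric and >= 1")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 ||
      !is.numeric(kappa) || length(kappa) != 1L || kappa < 0) {
    stop("'lambda' must be positive and 'kappa' non-negative")
  }
  n / (n + lambda + n * kappa)
}

#' Construct a table of trait observations
#'
#' @param sample_id character vector of unique animal ids.
#' @param y numeric vector (single trait) or matrix/data.frame (one column
#'   per trait) of yield deviations.
#' @param n_records integer vector of record (lactation) counts, >= 1.
#' @param birth_year integer vector.
#' @param role `"train"` or `"validation"` per animal.
#' @return A `data.frame` with class `trait_observations`: columns
#'   `sample_id`, one column per trait, `n_records`, `birth_year`, `role`.
#' @export
trait_observations <- function(sample_id, y, n_records, birth_year, role) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  if (is.null(dim(y))) y <- matrix(y, ncol = 1L, dimnames = list(NULL, "y"))
  y <- as.data.frame(y)
  if (nrow(y) != length(sample_id)) stop("'y' and 'sample_id' lengths differ")
  if (any(n_records < 1) || any(n_records != round(n_records))) {
    stop("'n_records' must be positive integers")
  }
  role <- match.arg(role, c("train", "validation"), several.ok = TRUE)
  if (length(role) == 1L) role <- rep(role, length(sample_id))
  out <- cbind(data.frame(sample_id = sample_id, stringsAsFactors = FALSE),
               y,
               data.frame(n_records = as.integer(n_records),
                          birth_year = as.integer(birth_year),
                          role = role, stringsAsFactors = FALSE))
  class(out) <- c("trait_observations", "data.frame")
  out
}

#' Read / write a phenotype table
#'
#' Tab-separated file with columns `sample_id`, one column per trait,
#' `n_records`, `birth_year`, `role`.
#'
#' @param path file path.
#' @return `read_phenotypes()` returns a `trait_observations` data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character"))
  need <- c("sample_id", "n_records", "birth_year", "role")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  }
  traits <- setdiff(names(df), need)
  trait_observations(df$sample_id, df[, traits, drop = FALSE],
                     df$n_records, df$birth_year, df$role)
}

#' @rdname read_phenotypes
#' @param obs a `trait_observations` data.frame.
#' @export
write_phenotypes <- function(obs, path) {
  write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trait columns of a phenotype table
#' @param obs a `trait_observations` data.frame.
#' @return Character vector of trait column names.
#' @export
trait_names <- function(obs) {
  setdiff(names(obs), c("sample_id", "n_records", "birth_year", "role"))
}

#' Read / write per-trait variance components (YAML)
#'
#' YAML layout: one block per trait with fields `genetic`,
#' `permanent_environment`, `residual`.
#'
#' @param path file path.
#' @return `read_varcomp()` returns a named list of [variance_components()].
#' @export
read_varcomp <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(b) {
    variance_components(b$genetic, b$permanent_environment, b$residual)
  })
}

#' @rdname read_varcomp
#' @param vcs named list of [variance_components()].
#' @export
write_varcomp <- function(vcs, path) {
  yaml::write_yaml(lapply(vcs, function(v) {
    list(genetic = v$sigma2_g, permanent_environment = v$sigma2_pe,
         residual = v$sigma2_e)
  }), path)
  invisible(path)
}
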