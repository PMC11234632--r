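# Rotated (spectral) representation of the null model
#   y = mu + g + e,  g ~ N(0, G sigma2_g),  e ~ N(0, R sigma2_e),  R = diag(1/w)
# With sw = sqrt(w) and G* = diag(sw) G diag(sw) = U S U', the transform
# t(U) %*% diag(sw) makes V diagonal: v_i = S_i sigma2_g + sigma2_e.
rotate_null <- function(y, G, w = NULL) {
  ids <- names(y)
  if (is.null(ids)) stop("'y' must be named by sample id")
  if (!all(ids %in% G$ids)) stop("training ids not all present in G")
  if (is.null(w)) w <- setNames(rep(1, length(y)), ids)
  w <- as_weight_vector(w)[ids]
  if (anyNA(w)) stop("weights missing for some training ids")
  Gtt <- G$values[ids, ids, drop = FALSE]
  sw <- sqrt(w)
  Gs <- Gtt * tcrossprod(sw)
  eg <- eigen(Gs, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values), 1)) {
    stop("G is not positive semidefinite on the training block")
  }
  list(ids = ids, w = w, sw = sw, U = eg$vectors, S = pmax(eg$values, 0),
       ytil = drop(crossprod(eg$vectors, sw * y)),
       xtil = drop(crossprod(eg$vectors, sw)),  # rotated intercept column
       logdetR = -sum(log(w)))
}

# restricted log-likelihood and GLS pieces at (sg, se) in rotated coordinates
reml_ll_parts <- function(rot, sg, se) {
  v <- rot$S * sg + se
  if (any(v <= 0)) return(NULL)
  xvx <- sum(rot$xtil^2 / v)
  xvy <- sum(rot$xtil * rot$ytil / v)
  beta <- xvy / xvx
  py <- (rot$ytil - rot$xtil * beta) / v  # P y
  ypy <- sum(rot$ytil * py)
  n <- length(v)
  ll <- -0.5 * (rot$logdetR + sum(log(v)) + log(xvx) + ypy +
                  (n - 1) * log(2 * pi))
  list(v = v, xvx = xvx, beta = beta, py = py, ypy = ypy, ll = ll)
}

#' REML estimation of genetic and residual variance
#'
#' Average-information REML for the null model `y = mu + g + e` with
#' `g ~ N(0, G sigma2_g)` and `e ~ N(0, R sigma2_e)`, `R = diag(1/w)`.
#' A one-time spectral decomposition of the (weight-scaled) training block of
#' `G` makes each iteration O(n). When an AI step proposes a non-positive
#' component, an EM-type ratio step (always positive) is taken instead; steps
#' that would decrease the restricted likelihood are halved, so the accepted
#' likelihood trace is non-decreasing.
#'
#' @param y named numeric vector of training phenotypes (names = sample ids).
#' @param G a [build_grm()] result covering at least the training ids.
#' @param w optional named observation weights (default all 1).
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the relative parameter change
#'   (default 1e-6).
#' @return Object of class `reml_estimate`: `sigma2_g`, `sigma2_e`,
#'   `se` (approximate standard errors from the AI matrix), `h2_model`
#'   (`sigma2_g / (sigma2_g + sigma2_e)` of the fitted model), `loglik`
#'   (trace of accepted restricted log-likelihoods), `converged`,
#'   `iterations`.
#' @export
reml_estimate <- function(y, G, w = NULL, max_iter = 100, tol = 1e-6) {
  rot <- rotate_null(y, G, w)
  n <- length(y)
  if (n < 30) warning("fewer than 30 training animals; REML may be unstable")
  vy <- var(rot$sw * y) # variance on the homogeneous-residual scale
  theta <- c(sg = vy / 2, se = vy / 2)
  floor_theta <- 1e-8 * vy
  parts <- reml_ll_parts(rot, theta[1], theta[2])
  ll_trace <- parts$ll
  converged <- FALSE
  iter <- 0
  AI <- diag(2)
  while (iter < max_iter) {
    iter <- iter + 1
    v <- parts$v
    xvx <- parts$xvx
    py <- parts$py
    # tr(P Vdot) for Vdot = diag(S) and I
    trPS <- sum(rot$S / v) - sum(rot$xtil^2 * rot$S / v^2) / xvx
    trPI <- sum(1 / v) - sum(rot$xtil^2 / v^2) / xvx
    u_g <- rot$S * py
    u_e <- py
    Pu <- function(u) u / parts$v - rot$xtil / parts$v *
      (sum(rot$xtil * u / parts$v) / parts$xvx)
    pug <- Pu(u_g); pue <- Pu(u_e)
    score <- c(-0.5 * (trPS - sum(u_g * py)), -0.5 * (trPI - sum(u_e * py)))
    AI <- 0.5 * matrix(c(sum(u_g * pug), sum(u_g * pue),
                         sum(u_g * pue), sum(u_e * pue)), 2, 2)
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    proposal <- if (!is.null(step)) theta + step else NULL
    if (is.null(proposal) || any(proposal <= 0)) {
      # EM-type fallback: positive ratio update with the same fixed point
      proposal <- theta * c(sum(u_g * py) / max(trPS, .Machine$double.eps),
                            sum(u_e * py) / max(trPI, .Machine$double.eps))
      proposal <- pmax(proposal, floor_theta)
    }
    # backtracking: only accept non-decreasing restricted likelihood
    accepted <- FALSE
    for (bt in 0:10) {
      cand <- theta + (proposal - theta) / 2^bt
      cand <- pmax(cand, floor_theta)
      cand_parts <- reml_ll_parts(rot, cand[1], cand[2])
      if (!is.null(cand_parts) && cand_parts$ll >= ll_trace[length(ll_trace)] - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    rel_change <- max(abs(cand - theta) / pmax(abs(theta), floor_theta))
    theta <- cand
    parts <- cand_parts
    ll_trace <- c(ll_trace, parts$ll)
    if (rel_change < tol) {
      converged <- TRUE
      break
    }
  }
  se_theta <- tryCatch(sqrt(diag(solve(AI))), error = function(e) c(NA_real_, NA_real_))
  structure(list(sigma2_g = unname(theta[1]), sigma2_e = unname(theta[2]),
                 se = setNames(se_theta, c("sigma2_g", "sigma2_e")),
                 ai_matrix = AI,
                 h2_model = unname(theta[1] / sum(theta)),
                 loglik = ll_trace, converged = converged, iterations = iter),
            class = "reml_estimate")
}

#' @export
print.reml_estimate <- function(x, ...) {
  cat("REML: sigma2_g =", signif(x$sigma2_g, 5), "(se", signif(x$se[1], 3), ")",
      " sigma2_e =", signif(x$sigma2_e, 5), "(se", signif(x$se[2], 3), ")\n")
  cat("  h2_model =", signif(x$h2_model, 4), "; converged:", x$converged,
      "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the restricted log-likelihood of the null model at
#' `(sigma2_g, sigma2_e)`; useful for profiling and for cross-checking the
#' optimiser.
#'
#' @inheritParams reml_estimate
#' @param sigma2_g,sigma2_e variance components, > 0.
#' @return Restricted log-likelihood value.
#' @export
reml_loglik <- function(y, G, sigma2_g, sigma2_e, w = NULL) {
  rot <- rotate_null(y, G, w)
  parts <- reml_ll_parts(rot, sigma2_g, sigma2_e)
  if (is.null(parts)) stop("variance components give a non-PD V")
  parts$ll
}

as_varcomp_pair <- function(varcomp) {
  if (inherits(varcomp, "reml_estimate")) {
    return(list(sigma2_g = varcomp$sigma2_g, sigma2_e = varcomp$sigma2_e))
  }
  if (inherits(varcomp, "variance_components")) {
    # the residual of the yield-deviation model absorbs the permanent
    # environment: an animal with n records has residual variance
    # (sigma2_pe + sigma2_e) / w_i under the Eq.-1 weights
    return(list(sigma2_g = varcomp$sigma2_g,
                sigma2_e = varcomp$sigma2_pe + varcomp$sigma2_e))
  }
  if (is.list(varcomp) && all(c("sigma2_g", "sigma2_e") %in% names(varcomp))) {
    return(varcomp[c("sigma2_g", "sigma2_e")])
  }
  stop("'varcomp' must supply sigma2_g and sigma2_e")
}

#' GBLUP prediction of genetic values
#'
#' Solves `y = mu + g + e` with `g ~ N(0, G sigma2_g)`,
#' `e ~ N(0, R sigma2_e)`, `R = diag(1/w)`, by generalised least squares for
#' `mu` and BLUP for `g`:
#' `ghat = sigma2_g G[, train] V^-1 (y - mu)` with
#' `V = G_tt sigma2_g + R sigma2_e`. Animals in `G` without phenotypes
#' (validation animals) are predicted through the cross-covariance block,
#' which is equivalent to including them as data-free equations.
#'
#' @param y named numeric vector of training phenotypes.
#' @param G a [build_grm()] result over all animals (train + validation).
#' @param varcomp a [variance_components()], [reml_estimate()], or list with
#'   `sigma2_g`, `sigma2_e`.
#' @param w optional named observation weights for the training animals.
#' @param solver `"chol"` (direct, default) or `"cg"` (conjugate gradient,
#'   tolerance 1e-8) for large n.
#' @param fit_mean fit the overall mean by GLS (default TRUE; FALSE fixes
#'   `mu = 0` for pre-centred data).
#' @return Object of class `gblup_fit`: `mu`, `gebv` (named, for every id in
#'   `G`), `varcomp`, `solver`, `residual_norm`.
#' @export
gblup_solve <- function(y, G, varcomp, w = NULL, solver = c("chol", "cg"),
                        fit_mean = TRUE) {
  solver <- match.arg(solver)
  vc <- as_varcomp_pair(varcomp)
  if (vc$sigma2_g < 0 || vc$sigma2_e <= 0) stop("variance components must be positive")
  ids <- names(y)
  if (is.null(ids) || !all(ids %in% G$ids)) stop("'y' must be named by ids present in G")
  if (is.null(w)) w <- setNames(rep(1, length(y)), ids)
  w <- as_weight_vector(w)[ids]
  Vtt <- G$values[ids, ids, drop = FALSE] * vc$sigma2_g +
    diag(vc$sigma2_e / w, length(ids))
  one <- rep(1, length(ids))
  if (solver == "chol") {
    ch <- tryCatch(chol(Vtt), error = function(e) {
      stop("singular mixed-model system; inspect grm_diagnostics(G)")
    })
    solveV <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  } else {
    solveV <- function(b) cg_solve(Vtt, b, tol = 1e-8)
  }
  Viy <- solveV(y)
  if (fit_mean) {
    Vi1 <- solveV(one)
    mu <- sum(one * Viy) / sum(one * Vi1)
    a <- Viy - Vi1 * mu  # V^-1 (y - mu)
  } else {
    mu <- 0
    a <- Viy
  }
  gebv <- drop(vc$sigma2_g * G$values[, ids, drop = FALSE] %*% a)
  names(gebv) <- G$ids
  resid_norm <- sqrt(sum((Vtt %*% a - (y - mu))^2)) / max(1, sqrt(sum((y - mu)^2)))
  structure(list(mu = mu, gebv = gebv, varcomp = vc, solver = solver,
                 residual_norm = resid_norm, train_ids = ids),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("gblup_fit:", length(x$train_ids), "training animals,",
      length(x$gebv), "predicted; mu =", signif(x$mu, 5),
      "; solver", x$solver, "\n")
  invisible(x)
}

# preconditioned conjugate gradient (Jacobi) for SPD systems
cg_solve <- function(A, b, tol = 1e-8, max_iter = 10 * length(b)) {
  x <- numeric(length(b))
  r <- b
  Minv <- 1 / diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  b_norm <- sqrt(sum(b^2))
  for (k in seq_len(max_iter)) {
    Ap <- drop(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * b_norm) break
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

#' SNP-BLUP (weighted ridge) solution
#'
#' Solves the SNP-effect formulation of the weighted GBLUP model: effects
#' `b_j` with prior variance `sigma2_g D_jj / sum_j 2 p_j (1 - p_j) D_jj`
#' and an overall mean, through the mixed-model equations on the training
#' animals. The resulting genetic values `X b` are identical to the
#' [gblup_solve()] values built from the same weights (GBLUP/SNP-BLUP
#' equivalence); SNPs with `D_jj = 0` get an exact zero effect.
#'
#' @param X a [center_genotypes()] result (all animals).
#' @param D per-SNP weights (default uniform).
#' @param varcomp as in [gblup_solve()].
#' @param y named training phenotypes.
#' @param w optional named observation weights.
#' @param fit_mean include the overall mean column (default TRUE).
#' @return List of class `snpblup_fit`: `mu`, `effects` (length m), `gebv`
#'   (named, all animals), `denominator`.
#' @export
snpblup_solve <- function(X, D = NULL, varcomp, y, w = NULL, fit_mean = TRUE) {
  vc <- as_varcomp_pair(varcomp)
  m <- ncol(X$X)
  if (is.null(D)) D <- rep(1, m)
  if (length(D) != m || any(D < 0)) stop("'D' must be m non-negative weights")
  ids <- names(y)
  if (is.null(ids) || !all(ids %in% rownames(X$X))) {
    stop("'y' must be named by ids present in X")
  }
  if (is.null(w)) w <- setNames(rep(1, length(y)), ids)
  w <- as_weight_vector(w)[ids]
  denom <- sum(2 * X$p * (1 - X$p) * D)
  if (denom <= 0) stop("zero denominator: all weight on monomorphic SNPs")
  use <- which(D > 0)
  Xt <- X$X[ids, use, drop = FALSE]
  A <- if (fit_mean) cbind(mu = 1, Xt) else Xt
  C <- crossprod(A * w, A) / vc$sigma2_e
  ridge <- c(if (fit_mean) 0 else NULL, denom / (vc$sigma2_g * D[use]))
  diag(C) <- diag(C) + ridge
  rhs <- drop(crossprod(A * w, y)) / vc$sigma2_e
  sol <- tryCatch(solve(C, rhs), error = function(e) {
    stop("singular SNP-BLUP system; inspect the genotype matrix")
  })
  mu <- if (fit_mean) sol[1] else 0
  effects <- numeric(m)
  effects[use] <- if (fit_mean) sol[-1] else sol
  gebv <- drop(X$X %*% effects)
  names(gebv) <- rownames(X$X)
  structure(list(mu = unname(mu), effects = effects, gebv = gebv,
                 denominator = denom), class = "snpblup_fit")
}

#' Write predicted genetic values to TSV
#'
#' @param fit a `gblup_fit`, `snpblup_fit` or `bayesgc_fit`.
#' @param path output path.
#' @param roles optional named character vector of roles per sample id.
#' @return The path, invisibly.
#' @export
write_gebv <- function(fit, path, roles = NULL) {
  ids <- names(fit$gebv)
  df <- data.frame(sample_id = ids,
                   role = if (is.null(roles)) NA_character_ else roles[ids],
                   gebv = unname(fit$gebv), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
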