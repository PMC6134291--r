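#' Convert between p-values and LOD scores
#'
#' The package's global bridge between the two significance scales is the
#' 1-df chi-square quantile: lod = qchisq(1 - p, 1) / (2 ln 10), so LOD 3
#' corresponds to a two-sided p of about 2.0e-4 and the multi-locus LOD > 3
#' rule is commensurable with p thresholds.
#'
#' @param p p-value(s) in (0, 1\].
#' @param lod LOD score(s) >= 0.
#' @return `pval_to_lod` returns LOD scores (Inf, with a warning, for
#'   p = 0); `lod_to_pval` returns p-values.
#' @export
pval_to_lod <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must be in [0, 1]")
  if (any(p == 0, na.rm = TRUE)) warning("p = 0 mapped to LOD = Inf")
  qchisq(p, df = 1, lower.tail = FALSE) / (2 * log(10))
}

#' @rdname pval_to_lod
#' @export
lod_to_pval <- function(lod) {
  if (any(lod < 0, na.rm = TRUE)) stop("lod must be >= 0")
  pchisq(2 * log(10) * lod, df = 1, lower.tail = FALSE)
}

# Assemble an association_result data.frame for marker indices `idx`.
make_assoc_result <- function(panel, idx, trait, method, effect, se,
                              p_value, lod, vy, significant) {
  map <- panel$map[idx, , drop = FALSE]
  vx <- if (length(idx)) col_vars(panel$dosage[, idx, drop = FALSE])
        else numeric(0)
  out <- data.frame(
    trait = rep_len(trait, length(idx)), marker_id = map$marker_id,
    chrom = map$chrom, pos = map$pos,
    alleles = if (length(idx)) paste0(map$ref, "/", map$alt) else character(0),
    method = rep_len(method, length(idx)), effect = effect, se = se,
    p_value = p_value, lod = lod,
    pve = if (length(idx)) pmin(effect^2 * vx / vy, 1) else numeric(0),
    significant = significant
  )
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}

# Vectorized fixed-effect (GLM) scan of every marker with covariates C.
# Returns per-marker effect, se, t, p; constant/collinear markers get p = 1.
glm_scan_core <- function(y, C, G) {
  n <- length(y)
  qrC <- qr(C)
  Q <- qr.Q(qrC)
  yr <- y - Q %*% crossprod(Q, y)
  Gr <- G - Q %*% crossprod(Q, G)
  ss <- colSums(Gr^2)
  ok <- ss > 1e-10 * n
  b <- se <- tv <- p <- rep(NA_real_, ncol(G))
  df <- n - qrC$rank - 1
  syy <- sum(yr^2)
  b[ok] <- colSums(Gr[, ok, drop = FALSE] * as.vector(yr)) / ss[ok]
  rss <- pmax(syy - b[ok]^2 * ss[ok], 0)
  se[ok] <- sqrt(rss / df / ss[ok])
  tv[ok] <- b[ok] / se[ok]
  p[ok] <- 2 * pt(-abs(tv[ok]), df)
  b[!ok] <- 0; p[!ok] <- 1
  list(effect = b, se = se, t = tv, p = p, df = df)
}

# Restricted log-likelihood of the fixed-effects-only model (no polygenic
# term), on the same constant convention as reml_full_loglik.
ols_reml_loglik <- function(y, X) {
  qx <- qr(X)
  n <- length(y); p <- qx$rank
  res <- qr.resid(qx, y)
  s2 <- sum(res^2) / (n - p)
  R <- qr.R(qx)
  -0.5 * ((n - p) * log(2 * pi * s2) + (n - p) + 2 * sum(log(abs(diag(R)))))
}

#' FarmCPU-style iterative fixed/random association scan
#'
#' Alternates (a) a fixed-effect scan of every marker with the current
#' pseudo-QTNs and the structure covariates as fixed covariates (a marker
#' is never its own covariate, and pseudo-QTN covariates in LD r2 > 0.7
#' with the tested marker are dropped for that test), and (b) selection of
#' a new pseudo-QTN set: markers are binned by position at several bin
#' sizes, the best marker of each top bin is a candidate, and the candidate
#' set maximizing the restricted likelihood of a random-effect model whose
#' relationship matrix is built from the candidate markers themselves is
#' kept (an empty set, i.e. the fixed-effects-only model, is always a
#' candidate). Iteration stops when the pseudo-QTN set repeats or after
#' `max_iter` rounds; the reported p-values are those of the final
#' fixed-effect scan, with significance at p < 1/m.
#'
#' @param y phenotype vector.
#' @param X structure covariates including intercept.
#' @param panel complete [genotype_panel()].
#' @param max_iter maximum number of iterations (default 10).
#' @param bin_sizes position bin sizes in bp (published defaults 0.5, 5 and
#'   50 Mb).
#' @param n_qtn_candidates numbers of top bins tried (published defaults 5,
#'   10, 15).
#' @param ld_r2_max covariate LD exclusion threshold (default 0.7).
#' @param sig_threshold significance threshold (default 1/m).
#' @param trait trait name for the results.
#' @return `association_result` with one row per marker; attributes
#'   `pseudo_qtns` (marker ids of the final set), `converged`, and
#'   `pseudo_qtn_history`.
#' @export
scan_farmcpu <- function(y, X, panel, max_iter = 10,
                         bin_sizes = c(5e5, 5e6, 5e7),
                         n_qtn_candidates = c(5, 10, 15),
                         ld_r2_max = 0.7, sig_threshold = NULL,
                         trait = "trait") {
  G <- panel$dosage
  if (anyNA(G)) stop("panel must be imputed before scanning")
  X <- as.matrix(X)
  m <- ncol(G)
  if (is.null(sig_threshold)) sig_threshold <- 1 / m
  pseudo <- integer(0)
  history <- list()
  converged <- FALSE
  scan <- NULL
  for (iter in seq_len(max_iter)) {
    scan <- farmcpu_scan_once(y, X, G, pseudo, ld_r2_max)
    new_pseudo <- farmcpu_select(y, X, G, panel$map, scan$p,
                                 bin_sizes, n_qtn_candidates)
    if (identical(new_pseudo, pseudo) ||
        any(vapply(history, identical, logical(1), y = new_pseudo))) {
      converged <- TRUE
      break
    }
    history <- c(history, list(pseudo))
    pseudo <- new_pseudo
  }
  out <- make_assoc_result(panel, seq_len(m), trait, "farmcpu",
                           scan$effect, scan$se, scan$p,
                           pval_to_lod(scan$p), var(y),
                           scan$p < sig_threshold)
  attr(out, "pseudo_qtns") <- panel$map$marker_id[pseudo]
  attr(out, "converged") <- converged
  attr(out, "pseudo_qtn_history") <-
    lapply(history, function(i) panel$map$marker_id[i])
  out
}

# One fixed-effect scan with pseudo-QTN covariates and the LD exclusion rule.
farmcpu_scan_once <- function(y, X, G, pseudo, ld_r2_max) {
  C <- if (length(pseudo)) cbind(X, G[, pseudo, drop = FALSE]) else X
  base <- glm_scan_core(y, C, G)
  if (!length(pseudo)) return(base)
  # markers whose test must drop some covariate: the marker itself and any
  # pseudo-QTN in strong LD with it
  r2 <- suppressWarnings(cor(G[, pseudo, drop = FALSE], G))^2
  r2[is.na(r2)] <- 0
  drop_any <- r2 > ld_r2_max
  drop_any[cbind(seq_along(pseudo), pseudo)] <- TRUE
  affected <- which(colSums(drop_any) > 0)
  n <- length(y)
  for (j in affected) {
    keep <- pseudo[!drop_any[, j]]
    Cj <- if (length(keep)) cbind(X, G[, keep, drop = FALSE]) else X
    fit <- glm_scan_core(y, Cj, G[, j, drop = FALSE])
    base$effect[j] <- fit$effect[1]
    base$se[j] <- fit$se[1]
    base$t[j] <- fit$t[1]
    base$p[j] <- fit$p[1]
  }
  base
}

# Candidate pseudo-QTN selection by position binning + restricted-likelihood
# model comparison. Returns sorted marker indices (possibly empty).
farmcpu_select <- function(y, X, G, map, pvals, bin_sizes, n_qtn_candidates) {
  sets <- list(integer(0))
  for (bs in bin_sizes) {
    bin <- map$chrom * 1e15 + floor(map$pos / bs)
    best_in_bin <- tapply(seq_along(pvals), bin, function(i) i[which.min(pvals[i])])
    bin_p <- vapply(best_in_bin, function(i) pvals[i], numeric(1))
    ord <- order(bin_p)
    for (tq in n_qtn_candidates) {
      take <- head(ord, tq)
      sets <- c(sets, list(sort(unname(unlist(best_in_bin[take])))))
    }
  }
  sets <- unique(sets)
  ll <- vapply(sets, function(s) {
    if (!length(s)) return(ols_reml_loglik(y, X))
    W <- tryCatch(standardize_dosage(G[, s, drop = FALSE]),
                  warning = function(w) suppressWarnings(
                    standardize_dosage(G[, s, drop = FALSE])))
    if (ncol(W) == 0) return(ols_reml_loglik(y, X))
    Ks <- tcrossprod(W) / ncol(W)
    tryCatch(fit_null_mlm(y, X, (Ks + t(Ks)) / 2)$loglik_reml,
             error = function(e) -Inf)
  }, numeric(1))
  sets[[which.max(ll)]]
}

#' Two-stage EM empirical-Bayes multi-locus scan
#'
#' FASTmrEMMA-style engine. Stage 1: phenotype, covariates and markers are
#' whitened by the null polygenic covariance (K + delta I from
#' [fit_null_mlm()]); each marker is then tested as a single random effect
#' whose variance has a closed-form restricted-likelihood-ratio test
#' (boundary-corrected half chi-square), and markers with stage-1 p below
#' `stage1_alpha` are retained. Stage 2: the retained markers enter one
#' multi-locus model with independent normal priors on their effects whose
#' variances are estimated by an expectation-maximization empirical-Bayes
#' loop (convergence when the largest relative parameter change is below
#' 1e-6, at most 1000 iterations). Each retained marker's LOD is the
#' likelihood ratio of dropping its variance component from the fitted
#' model; significance at LOD > `lod_threshold`.
#'
#' @inheritParams scan_single_locus
#' @param stage1_alpha stage-1 retention threshold (default 0.005).
#' @param lod_threshold significance LOD (default 3).
#' @param max_retained cap on the stage-1 set (default n/3, smallest
#'   p-values kept).
#' @return `association_result` with one row per retained marker (possibly
#'   zero rows); attributes `stage1_pvalues` (named vector over all
#'   markers), `em_converged`, `null_fit`.
#' @export
scan_fastmremma <- function(y, X, K, panel, stage1_alpha = 0.005,
                            lod_threshold = 3, max_retained = NULL,
                            trait = "trait", eig = NULL, UtG = NULL) {
  G <- panel$dosage
  if (anyNA(G)) stop("panel must be imputed before scanning")
  X <- as.matrix(X)
  n <- length(y)
  if (n < 10) stop("need at least 10 lines")
  e <- eig %||% kinship_eigen(K)
  fit <- fit_null_mlm(y, X, e)
  if (is.null(UtG)) UtG <- crossprod(e$vectors, G)
  s <- 1 / sqrt(e$values + fit$delta)
  ys <- s * crossprod(e$vectors, y)
  Xs <- s * crossprod(e$vectors, X)
  Zs <- UtG * s

  # stage 1: closed-form restricted LRT for one random marker effect
  qrX <- qr(Xs)
  Q <- qr.Q(qrX)
  r <- as.vector(ys - Q %*% crossprod(Q, ys))
  Zt <- Zs - Q %*% crossprod(Q, Zs)
  a <- colSums(Zt^2)
  bb <- as.vector(crossprod(Zt, r))^2
  s2 <- sum(r^2)
  nu <- n - qrX$rank
  denom <- a * (a * s2 - bb)
  gam <- ifelse(a > 1e-12 & denom > 0, pmax(0, (nu * bb - a * s2) / denom), 0)
  qq <- s2 - bb * gam / (1 + gam * a)
  lrt <- pmax(nu * log(s2 / qq) - log(1 + gam * a), 0)
  p1 <- ifelse(lrt <= 0, 1, 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE))
  names(p1) <- panel$map$marker_id

  if (is.null(max_retained)) max_retained <- max(floor(n / 3), 1)
  sel <- which(p1 <= stage1_alpha)
  if (length(sel) > max_retained) {
    sel <- sel[order(p1[sel])][seq_len(max_retained)]
    sel <- sort(sel)
  }
  if (!length(sel)) {
    out <- make_assoc_result(panel, integer(0), trait, "fastmremma",
                             numeric(0), numeric(0), numeric(0),
                             numeric(0), var(y), logical(0))
    attr(out, "stage1_pvalues") <- p1
    attr(out, "em_converged") <- TRUE
    attr(out, "null_fit") <- fit
    return(out)
  }

  em <- emeb_fit(ys, Xs, Zs[, sel, drop = FALSE])
  lod <- emeb_lod(ys, Xs, Zs[, sel, drop = FALSE], em)
  pv <- lod_to_pval(lod)
  out <- make_assoc_result(panel, sel, trait, "fastmremma",
                           em$u, sqrt(pmax(em$u_var, 0)), pv, lod, var(y),
                           lod > lod_threshold)
  attr(out, "stage1_pvalues") <- p1
  attr(out, "em_converged") <- em$converged
  attr(out, "null_fit") <- fit
  out
}

# EM empirical-Bayes fit of y = X beta + Z u + e with u_j ~ N(0, sigma_j^2),
# e ~ N(0, sigma_e^2), on (already whitened) data. Returns posterior means,
# posterior variances and the estimated variance components.
emeb_fit <- function(y, X, Z, tol = 1e-6, max_iter = 1000) {
  n <- length(y); k <- ncol(Z)
  XtX <- crossprod(X)
  ZtZ <- crossprod(Z)
  beta <- qr.coef(qr(X), y)
  res0 <- y - X %*% beta
  se2 <- max(var(as.vector(res0)), 1e-8)
  sj2 <- pmax((as.vector(crossprod(Z, res0)) / pmax(diag(ZtZ), 1e-8))^2 / 2,
              1e-6)
  floor_sj <- 1e-10 * se2
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    old <- c(sj2, se2)
    S <- solve(ZtZ / se2 + diag(1 / pmax(sj2, floor_sj), k))
    mu <- as.vector(S %*% crossprod(Z, y - X %*% beta)) / se2
    beta <- solve(XtX, crossprod(X, y - Z %*% mu))
    sj2 <- mu^2 + diag(S)
    resid <- as.vector(y - X %*% beta - Z %*% mu)
    se2 <- (sum(resid^2) + sum(ZtZ * S)) / n
    new <- c(sj2, se2)
    if (max(abs(new - old) / pmax(abs(old), 1e-12)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(u = mu, u_var = diag(S), beta = as.vector(beta), sigma_j2 = sj2,
       sigma_e2 = se2, converged = converged)
}

# Gaussian marginal ML log-likelihood of y ~ N(X beta_hat, V) with beta
# profiled by GLS.
gauss_profile_loglik <- function(y, X, V) {
  n <- length(y)
  R <- chol(V)
  Vi_y <- backsolve(R, backsolve(R, y, transpose = TRUE))
  Vi_X <- backsolve(R, backsolve(R, X, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  resid <- y - X %*% beta
  Vi_r <- backsolve(R, backsolve(R, resid, transpose = TRUE))
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(resid * Vi_r))
}

# Per-marker LOD: likelihood ratio of zeroing one marker's prior variance
# with all other variance parameters held at the EM solution.
emeb_lod <- function(y, X, Z, em) {
  n <- length(y); k <- ncol(Z)
  base_V <- diag(em$sigma_e2, n) +
    Z %*% (em$sigma_j2 * t(Z))
  l_full <- gauss_profile_loglik(y, X, base_V)
  vapply(seq_len(k), function(j) {
    Vj <- base_V - em$sigma_j2[j] * tcrossprod(Z[, j])
    max((l_full - gauss_profile_loglik(y, X, Vj)) / log(10), 0)
  }, numeric(1))
}

#' L1-penalised multi-locus scan with a Wald significance test
#'
#' The structure covariates are projected out of the phenotype and the
#' (internally standardized) markers; the lasso path is then fit by cyclic
#' coordinate descent and the penalty is chosen by k-fold cross-validation
#' (minimum mean squared prediction error, seeded fold split). For markers
#' with nonzero effects, an approximate effect variance comes from a
#' ridge-type curvature at the solution restricted to the active set,
#' Var = sigma_e^2 (H + lambda n I)^-1 H (H + lambda n I)^-1 with
#' H = Xs' Xs, and a Wald z gives the p-value and LOD; significance at
#' LOD > `lod_threshold`.
#'
#' @inheritParams scan_farmcpu
#' @param cv_folds number of cross-validation folds (default 5).
#' @param seed seed for the fold split.
#' @param n_lambda length of the penalty path (default 30).
#' @param lambda_min_ratio smallest penalty as a fraction of the smallest
#'   penalty that zeroes every coefficient (default 0.05).
#' @param lod_threshold significance LOD (default 3).
#' @return `association_result` with one row per active-set marker
#'   (possibly zero rows); attributes `lambda`, `lambda_path`, `cv_mse`.
#' @export
scan_lasso <- function(y, X, panel, cv_folds = 5, seed = 1L, n_lambda = 30,
                       lambda_min_ratio = 0.05, lod_threshold = 3,
                       trait = "trait") {
  G <- panel$dosage
  if (anyNA(G)) stop("panel must be imputed before scanning")
  X <- as.matrix(X)
  n <- length(y)
  Q <- qr.Q(qr(X))
  yr <- as.vector(y - Q %*% crossprod(Q, y))
  Gr <- G - Q %*% crossprod(Q, G)
  sdv <- sqrt(colSums(Gr^2) / n)
  keep <- sdv > 1e-8
  Gs <- sweep(Gr[, keep, drop = FALSE], 2, sdv[keep], "/")
  midx <- which(keep)
  lam_max <- max(abs(crossprod(Gs, yr))) / n
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))

  folds <- with_seed(seed, sample(rep(seq_len(cv_folds), length.out = n)))
  mse <- matrix(NA_real_, cv_folds, n_lambda)
  for (f in seq_len(cv_folds)) {
    tr <- folds != f
    ytr <- yr[tr] - mean(yr[tr])
    B <- lasso_path_cpp(Gs[tr, , drop = FALSE], ytr, lambdas)
    pred <- Gs[!tr, , drop = FALSE] %*% B
    err <- (yr[!tr] - mean(yr[tr])) - pred
    mse[f, ] <- colMeans(err^2)
  }
  cv_mse <- colMeans(mse)
  lam <- lambdas[which.min(cv_mse)]
  beta <- as.vector(lasso_path_cpp(Gs, yr, lambdas)[, which.min(cv_mse)])
  active <- which(beta != 0)
  if (!length(active)) {
    out <- make_assoc_result(panel, integer(0), trait, "lasso", numeric(0),
                             numeric(0), numeric(0), numeric(0), var(y),
                             logical(0))
    attr(out, "lambda") <- lam
    attr(out, "lambda_path") <- lambdas
    attr(out, "cv_mse") <- cv_mse
    return(out)
  }
  Xs <- Gs[, active, drop = FALSE]
  H <- crossprod(Xs)
  M <- solve(H + diag(lam * n, length(active)))
  resid <- yr - Xs %*% beta[active]
  dfres <- max(n - length(active) - ncol(X), 1)
  sig2 <- sum(resid^2) / dfres
  vb <- sig2 * diag(M %*% H %*% M)
  z <- beta[active] / sqrt(pmax(vb, 1e-300))
  pv <- 2 * pnorm(-abs(z))
  lod <- pval_to_lod(pv)
  sel <- midx[active]
  out <- make_assoc_result(panel, sel, trait, "lasso",
                           beta[active] / sdv[sel],
                           sqrt(pmax(vb, 0)) / sdv[sel],
                           pv, lod, var(y), lod > lod_threshold)
  attr(out, "lambda") <- lam
  attr(out, "lambda_path") <- lambdas
  attr(out, "cv_mse") <- cv_mse
  out
}

#' Fit a lasso at fixed penalty by coordinate descent
#'
#' Low-level access to the in-package coordinate-descent solver: solves
#' min_b 1/(2n) ||y - X b||^2 + lambda ||b||_1 on the supplied design
#' as-is (no internal centring or scaling).
#'
#' @param Xmat design matrix (centre the columns, and the response, before
#'   calling if the model has an intercept).
#' @param y centred response.
#' @param lambda penalty (scalar or decreasing vector).
#' @param tol coordinate-wise convergence tolerance (default 1e-7).
#' @return matrix of coefficients, one column per lambda.
#' @export
fit_lasso <- function(Xmat, y, lambda, tol = 1e-7) {
  lasso_path_cpp(as.matrix(Xmat), as.numeric(y), as.numeric(lambda), tol)
}
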