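# Checked eigendecomposition of a kinship matrix; eigenvalues below -1e-8
# are an error, small negative ones are clamped to zero.
kinship_eigen <- function(K) {
  K <- as.matrix(K)
  if (max(abs(K - t(K))) > 1e-10) stop("kinship matrix is not symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -1e-8) stop("kinship matrix is not positive semi-definite")
  list(values = pmax(e$values, 0), vectors = e$vectors)
}

# Rotated REML profile pieces at a given delta. Returns the criterion to
# maximize plus the ingredients of the full restricted log-likelihood.
reml_pieces <- function(Uty, UtX, lam, delta) {
  w <- 1 / (lam + delta)
  Xw <- UtX * w
  A <- crossprod(UtX, Xw)
  b <- crossprod(Xw, Uty)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  z <- backsolve(R, b, transpose = TRUE)
  yPy <- sum(w * Uty^2) - sum(z^2)
  if (!is.finite(yPy) || yPy <= 0) return(NULL)
  n <- length(Uty); p <- ncol(UtX)
  logdetA <- 2 * sum(log(diag(R)))
  sumlog <- sum(log(lam + delta))
  list(crit = -0.5 * ((n - p) * log(yPy) + sumlog + logdetA),
       yPy = yPy, logdetA = logdetA, sumlog = sumlog,
       beta = backsolve(R, z), R = R, n = n, p = p)
}

# Full restricted log-likelihood at delta with sigma_g^2 profiled out.
reml_full_loglik <- function(pieces) {
  n <- pieces$n; p <- pieces$p
  sg2 <- pieces$yPy / (n - p)
  -0.5 * ((n - p) * log(2 * pi * sg2) + pieces$sumlog + pieces$logdetA +
            (n - p))
}

#' Restricted log-likelihood of the rotated mixed model at a given delta
#'
#' Profile REML value of y ~ N(X beta, sigma_g^2 (K + delta I)) with
#' sigma_g^2 profiled out, using the convention
#' l = -1/2 ( (n-p) log(2 pi sigma_g^2) + log|K + delta I| +
#' log|X'(K+delta I)^-1 X| + (n-p) ). Exposed so the eigen-rotated value
#' can be checked against dense-matrix computations.
#'
#' @param y phenotype vector.
#' @param X covariate matrix (with intercept).
#' @param K kinship matrix.
#' @param delta variance ratio sigma_e^2 / sigma_g^2.
#' @return log-likelihood value (scalar).
#' @export
reml_profile_loglik <- function(y, X, K, delta) {
  e <- kinship_eigen(K)
  pieces <- reml_pieces(crossprod(e$vectors, y), crossprod(e$vectors, X),
                        e$values, delta)
  if (is.null(pieces)) stop("REML likelihood undefined at this delta")
  reml_full_loglik(pieces)
}

#' Fit the null mixed model by REML
#'
#' Eigendecomposes the kinship matrix once, rotates phenotype and
#' covariates, and maximizes the restricted likelihood over the variance
#' ratio delta = sigma_e^2/sigma_g^2 on \[1e-5, 1e5\] (100-point log grid
#' followed by Brent refinement in the bracketing interval). sigma_g^2 and
#' sigma_e^2 are recovered from the profiled optimum.
#'
#' @param y phenotype vector (length n).
#' @param X covariate matrix including the intercept (n x p, full column
#'   rank).
#' @param K kinship matrix (n x n PSD), or a precomputed eigendecomposition
#'   from the internal cache.
#' @return list of class `mixed_model_fit`: `delta`, `sigma_g2`,
#'   `sigma_e2`, `loglik_reml`, `beta`, and `eigen` (the cached
#'   eigendecomposition).
#' @export
fit_null_mlm <- function(y, X, K) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  if (qr(X)$rank < ncol(X)) stop("covariate matrix X is rank deficient")
  e <- if (is.list(K) && !is.null(K$vectors)) K else kinship_eigen(K)
  stopifnot(length(y) == length(e$values))
  Uty <- crossprod(e$vectors, y)
  UtX <- crossprod(e$vectors, X)
  grid <- seq(-5, 5, length.out = 100)
  crit <- vapply(grid, function(g) {
    p <- reml_pieces(Uty, UtX, e$values, 10^g)
    if (is.null(p)) -Inf else p$crit
  }, numeric(1))
  i <- which.max(crit)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(function(g) {
    p <- reml_pieces(Uty, UtX, e$values, 10^g)
    if (is.null(p)) -Inf else p$crit
  }, c(lo, hi), maximum = TRUE, tol = 1e-10)
  delta <- 10^opt$maximum
  pieces <- reml_pieces(Uty, UtX, e$values, delta)
  sg2 <- pieces$yPy / (pieces$n - pieces$p)
  structure(list(
    delta = delta, sigma_g2 = sg2, sigma_e2 = delta * sg2,
    loglik_reml = reml_full_loglik(pieces),
    beta = drop(pieces$beta), eigen = e,
    n = pieces$n, p = pieces$p
  ), class = "mixed_model_fit")
}

#' Exact single-locus mixed-model association scan
#'
#' GEMMA-style scan: the kinship matrix is eigendecomposed once and for
#' every marker the variance ratio delta is re-optimized on the rotated
#' data (an exact per-marker test, not the population-parameters-
#' previously-determined approximation). The marker effect is tested with a
#' two-sided Wald t test on n - p degrees of freedom; significance uses the
#' multiple-test-free rule p < 1/m.
#'
#' @param y phenotype vector.
#' @param X covariate matrix including intercept (defaults are built by
#'   [gwas_covariates()]).
#' @param K kinship matrix.
#' @param panel complete [genotype_panel()].
#' @param trait trait name recorded in the results.
#' @param sig_threshold significance threshold on the p-value (default
#'   `1/m`).
#' @param eig optional precomputed [kinship_eigen] list (internal reuse).
#' @param UtG optional precomputed rotated genotype matrix (internal
#'   reuse).
#' @return data.frame of class `association_result`: one row per marker
#'   with `trait`, `marker_id`, `chrom`, `pos`, `alleles`, `method`,
#'   `effect`, `se`, `p_value`, `lod`, `pve`, `significant`. Constant
#'   markers get effect 0 and p 1.
#' @export
scan_single_locus <- function(y, X, K, panel, trait = "trait",
                              sig_threshold = NULL, eig = NULL, UtG = NULL) {
  d <- panel$dosage
  if (anyNA(d)) stop("panel must be imputed before scanning")
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix X is rank deficient")
  m <- ncol(d)
  if (is.null(sig_threshold)) sig_threshold <- 1 / m
  e <- eig %||% kinship_eigen(K)
  if (is.null(UtG)) UtG <- crossprod(e$vectors, d)
  res <- scan_mlm_cpp(crossprod(e$vectors, X), crossprod(e$vectors, y),
                      UtG, e$values)
  ok <- res$ok == 1L
  p_value <- rep(1, m)
  p_value[ok] <- 2 * pt(-abs(res$t[ok]), df = res$df)
  effect <- ifelse(ok, res$effect, 0)
  se <- ifelse(ok, res$se, NA_real_)
  vx <- col_vars(d)
  vy <- var(y)
  out <- data.frame(
    trait = trait, marker_id = panel$map$marker_id,
    chrom = panel$map$chrom, pos = panel$map$pos,
    alleles = paste0(panel$map$ref, "/", panel$map$alt),
    method = "single_mlm", effect = effect, se = se,
    p_value = p_value, lod = pval_to_lod(p_value),
    pve = pmin(effect^2 * vx / vy, 1),
    significant = p_value < sig_threshold
  )
  rownames(out) <- NULL
  class(out) <- c("association_result", "data.frame")
  out
}

#' Default GWAS covariates: intercept plus leading PC scores
#'
#' @param pcs a `pc_result` from [compute_pca()].
#' @param n_pcs number of PCs used for structure control (default 5).
#' @return n x (1 + n_pcs) matrix.
#' @export
gwas_covariates <- function(pcs, n_pcs = 5) {
  cbind(intercept = 1, pcs$scores[, seq_len(n_pcs), drop = FALSE])
}
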