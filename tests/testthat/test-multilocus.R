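test_that("the p-value / LOD bridge is the 1-df chi-square and inverts cleanly", {
  expect_equal(pval_to_lod(1), 0)
  expect_equal(lod_to_pval(3), 2.0e-4, tolerance = 0.01)
  for (p in c(1e-2, 1e-6)) {
    expect_equal(lod_to_pval(pval_to_lod(p)), p, tolerance = 1e-12)
  }
  expect_warning(pval_to_lod(0), "Inf")
  expect_error(pval_to_lod(-0.1))
  expect_error(lod_to_pval(-1))
})

test_that("unpenalised coordinate descent reproduces least squares", {
  set.seed(4)
  X <- scale(matrix(rnorm(50 * 5), 50, 5))
  y <- as.vector(X %*% c(1, -0.5, 0, 0.3, 0)) + rnorm(50)
  y <- y - mean(y)
  b <- fit_lasso(X, y, 0)
  expect_equal(as.vector(b), unname(coef(lm(y ~ X - 1))), tolerance = 1e-6)
})

test_that("lasso solutions satisfy the KKT conditions and match an independent solver", {
  skip_if_not_installed("glmnet")
  for (i in 1:5) {
    set.seed(40 + i)
    n <- 50; m <- 20
    X <- matrix(rnorm(n * m), n, m)
    X <- scale(X) * sqrt(n / (n - 1))      # unit n-variance columns
    y <- as.vector(X[, 1:3] %*% c(1, -1, 0.5)) + rnorm(n)
    y <- y - mean(y)
    lam <- 0.2
    b <- as.vector(fit_lasso(X, y, lam))
    expect_lt(lasso_kkt_gap(X, y, b, lam), 1e-6)
    g <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                        intercept = FALSE, thresh = 1e-12)
    expect_equal(b, as.vector(g$beta), tolerance = 1e-4)
  }
})

test_that("lasso shrinks relative to least squares on its active set", {
  set.seed(77)
  n <- 200; m <- 20
  X <- matrix(sample(c(0, 2), n * m, replace = TRUE), n, m)
  Xs <- scale(X) * sqrt(n / (n - 1))
  y <- as.vector(Xs[, 1] * 0.8 + Xs[, 5] * -0.6) + rnorm(n)
  y <- y - mean(y)
  lam <- 0.1
  b <- as.vector(fit_lasso(Xs, y, lam))
  act <- which(b != 0)
  ols <- coef(lm(y ~ Xs[, act] - 1))
  expect_true(all(abs(b[act]) <= abs(ols) + 1e-8))
})

test_that("the lasso scan finds a strong QTL and is quiet on null phenotypes", {
  qt <- data.frame(chrom = 3, pos = 8e6, maf = 0.3, effect = 1,
                   target_pve = 0.20)
  p <- simulate_genotype_panel(n = 230, m = 600, required_positions = qt,
                               seed = 29)
  K <- compute_kinship(p); pc <- compute_pca(p, 5)
  X <- gwas_covariates(pc)
  des <- simulation_design(qtls = qt, seed = 71)
  found <- 0
  for (i in 1:10) {
    des$seed <- 71 + i
    tr <- simulate_phenotypes(p, des, K, pc, n_reps = 1)
    res <- scan_lasso(tr[[1]]$phenotype, X, p, seed = i)
    hit <- res[res$significant & res$chrom == 3 & res$pos == 8e6, ]
    if (nrow(hit) == 1) found <- found + 1
  }
  expect_gte(found, 8)
  # null phenotypes: rarely anything at LOD > 3
  set.seed(99)
  nsig <- sum(vapply(1:8, function(i) {
    y <- rnorm(230)
    sum(scan_lasso(y, X, p, seed = i)$significant)
  }, numeric(1)))
  expect_lte(nsig, 2)
})

test_that("EM empirical Bayes detects a 20%-PVE QTL and controls null findings", {
  qt <- data.frame(chrom = 4, pos = 9e6, maf = 0.35, effect = 1,
                   target_pve = 0.20)
  p <- simulate_genotype_panel(n = 230, m = 600, required_positions = qt,
                               seed = 37)
  K <- compute_kinship(p); pc <- compute_pca(p, 5)
  X <- gwas_covariates(pc)
  des <- simulation_design(qtls = qt, seed = 81)
  found <- 0
  for (i in 1:10) {
    des$seed <- 81 + i
    tr <- simulate_phenotypes(p, des, K, pc, n_reps = 1)
    res <- scan_fastmremma(tr[[1]]$phenotype, X, K, p)
    hit <- res[res$significant & res$chrom == 4 & res$pos == 9e6, ]
    if (nrow(hit) == 1) found <- found + 1
  }
  expect_gte(found, 9)
  # null phenotypes: LOD > 3 findings are rare
  set.seed(7)
  nsig <- vapply(1:10, function(i) {
    sum(scan_fastmremma(rnorm(230), X, K, p)$significant)
  }, numeric(1))
  expect_lte(mean(nsig), 0.5)
  # stage-1 p-values cover all markers and empty retention is not an error
  res <- scan_fastmremma(rnorm(230), X, K, p, stage1_alpha = 1e-12)
  expect_equal(nrow(res), 0)
  expect_length(attr(res, "stage1_pvalues"), 600)
})

test_that("the iterative fixed/random scan equals a plain GLM+PC scan at iteration one", {
  p <- simulate_genotype_panel(n = 120, m = 150, n_subpops = 2, seed = 41)
  pc <- compute_pca(p, 3)
  X <- gwas_covariates(pc, 3)
  set.seed(15)
  y <- rnorm(120) + pc$scores[, 1]
  res <- scan_farmcpu(y, X, p, max_iter = 1)
  for (j in c(1, 40, 77, 150)) {
    cf <- summary(lm(y ~ X - 1 + p$dosage[, j]))$coefficients
    expect_equal(res$p_value[j], cf[nrow(cf), 4], tolerance = 1e-10)
  }
})

test_that("the iterative scan recovers two unlinked QTL as pseudo-QTNs", {
  qt <- data.frame(chrom = c(1, 6), pos = c(5e6, 7e6), maf = c(0.3, 0.4),
                   effect = c(1, 1), target_pve = c(0.10, 0.10))
  p <- simulate_genotype_panel(n = 230, m = 600, required_positions = qt,
                               seed = 43)
  K <- compute_kinship(p); pc <- compute_pca(p, 5)
  X <- gwas_covariates(pc)
  des <- simulation_design(qtls = qt, seed = 91)
  both <- 0
  for (i in 1:10) {
    des$seed <- 91 + i
    tr <- simulate_phenotypes(p, des, K, pc, n_reps = 1)
    res <- scan_farmcpu(tr[[1]]$phenotype, X, p)
    pq <- attr(res, "pseudo_qtns")
    if (all(c("SNP_1_5000000", "SNP_6_7000000") %in% pq)) both <- both + 1
  }
  expect_gte(both, 7)
})

test_that("all engines agree on the sign of a dominant QTL", {
  qt <- data.frame(chrom = 5, pos = 6e6, maf = 0.4, effect = -1,
                   target_pve = 0.25)
  p <- simulate_genotype_panel(n = 230, m = 500, required_positions = qt,
                               seed = 47)
  K <- compute_kinship(p); pc <- compute_pca(p, 5)
  X <- gwas_covariates(pc)
  des <- simulation_design(qtls = qt, seed = 101)
  tr <- simulate_phenotypes(p, des, K, pc, n_reps = 1)
  y <- tr[[1]]$phenotype
  mid <- "SNP_5_6000000"
  signs <- c()
  for (fn in list(
    function() scan_single_locus(y, X, K, p),
    function() scan_fastmremma(y, X, K, p),
    function() scan_farmcpu(y, X, p),
    function() scan_lasso(y, X, p, seed = 2))) {
    res <- fn()
    row <- res[res$marker_id == mid & res$significant, ]
    if (nrow(row)) signs <- c(signs, sign(row$effect))
  }
  expect_gte(length(signs), 3)
  expect_equal(length(unique(signs)), 1L)
  expect_equal(unique(signs), -1)
})

test_that("multi-locus engines report far fewer markers than naive per-marker testing", {
  p <- simulate_genotype_panel(n = 150, m = 400, seed = 53)
  K <- compute_kinship(p); pc <- compute_pca(p, 3)
  X <- gwas_covariates(pc, 3)
  set.seed(31)
  y <- rnorm(150)
  naive <- sum(vapply(seq_len(400), function(j) {
    cf <- summary(lm(y ~ X - 1 + p$dosage[, j]))$coefficients
    cf[nrow(cf), 4] < 0.05
  }, logical(1)))
  n_eb <- nrow(scan_fastmremma(y, X, K, p))
  n_l1 <- nrow(scan_lasso(y, X, p, seed = 3))
  expect_lt(n_eb, naive)
  expect_lt(n_l1, naive)
})
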