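test_that("rotated REML equals dense-matrix REML on a 30-line toy", {
  p <- simulate_genotype_panel(n = 30, m = 300, n_subpops = 2, seed = 17)
  K <- compute_kinship(p)
  set.seed(5)
  y <- as.vector(chol(K + 0.5 * diag(30)) %*% rnorm(30)) + rnorm(30)
  X <- cbind(1, rnorm(30))
  fit <- fit_null_mlm(y, X, K)
  expect_equal(fit$loglik_reml,
               dense_reml_loglik(y, X, K, fit$delta, fit$sigma_g2),
               tolerance = 1e-6)
  # agreement holds along the delta profile, not just at the optimum
  for (d in c(0.1, 1, 10)) {
    pieces_val <- reml_profile_loglik(y, X, K, d)
    sg2 <- local({
      e <- eigen(K, symmetric = TRUE)
      w <- 1 / (pmax(e$values, 0) + d)
      Uty <- crossprod(e$vectors, y); UtX <- crossprod(e$vectors, X)
      A <- crossprod(UtX, UtX * w)
      b <- crossprod(UtX * w, Uty)
      drop(sum(w * Uty^2) - t(b) %*% solve(A, b)) / (30 - 2)
    })
    expect_equal(pieces_val, dense_reml_loglik(y, X, K, d, sg2),
                 tolerance = 1e-6)
  }
  # delta maximises the restricted likelihood against a 50-point log grid
  grid_ll <- vapply(seq(-5, 5, length.out = 50), function(g)
    reml_profile_loglik(y, X, K, 10^g), numeric(1))
  expect_gte(fit$loglik_reml + 1e-8, max(grid_ll))
  expect_gte(fit$sigma_g2, 0)
  expect_gte(fit$sigma_e2, 0)
  expect_error(fit_null_mlm(y, cbind(rep(1, 30), rep(1, 30)), K), "rank")
})

test_that("with K = I the mixed-model scan collapses to ordinary regression", {
  p <- simulate_genotype_panel(n = 60, m = 40, seed = 3)
  set.seed(9)
  y <- rnorm(60) + 0.8 * p$dosage[, 5]
  X <- matrix(1, 60, 1)
  sc <- scan_single_locus(y, X, diag(60), p)
  for (j in c(1, 5, 20, 40)) {
    cf <- summary(lm(y ~ p$dosage[, j]))$coefficients
    expect_equal(sc$p_value[j], cf[2, 4], tolerance = 1e-8)
    expect_equal(sc$effect[j], cf[2, 1], tolerance = 1e-8)
  }
})

test_that("independent noise on a structured kinship yields near-zero heritability", {
  p <- simulate_genotype_panel(n = 150, m = 800, n_subpops = 3, seed = 21)
  K <- compute_kinship(p)
  h2s <- vapply(1:10, function(i) {
    set.seed(10 + i)
    fit <- fit_null_mlm(rnorm(150), matrix(1, 150, 1), K)
    fit$sigma_g2 * mean(diag(K)) /
      (fit$sigma_g2 * mean(diag(K)) + fit$sigma_e2)
  }, numeric(1))
  expect_lt(mean(h2s), 0.1)
  # a good share of fits land on the sigma_g ~ 0 boundary
  expect_gte(sum(h2s < 0.01), 3)
})

test_that("variance-ratio estimates concentrate near truth under the generative model", {
  p <- simulate_genotype_panel(n = 230, m = 1000, seed = 25)
  K <- compute_kinship(p)
  e <- eigen(K, symmetric = TRUE)
  gs <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  ds <- vapply(1:25, function(i) {
    set.seed(200 + i)
    y <- as.vector(gs %*% rnorm(230)) + rnorm(230)  # sigma_g2 = sigma_e2 = 1
    fit_null_mlm(y, matrix(1, 230, 1), K)$delta
  }, numeric(1))
  # delta = 1 truth: the estimator is noisy at n = 230 but centred right
  expect_gte(mean(ds > 1 / 3 & ds < 3), 0.7)
  expect_true(median(ds) > 0.4 && median(ds) < 2.5)
})

test_that("line order does not change the scan and effect signs track the coding", {
  p <- simulate_genotype_panel(n = 80, m = 60, n_subpops = 2, seed = 7)
  K <- compute_kinship(p)
  pc <- compute_pca(p, 2)
  X <- gwas_covariates(pc, 2)
  set.seed(13)
  y <- rnorm(80) + 0.9 * p$dosage[, 10]
  sc <- scan_single_locus(y, X, K, p)
  # permute lines everywhere
  perm <- sample(80)
  p2 <- make_panel(p$dosage[perm, ], chrom = p$map$chrom, pos = p$map$pos)
  sc2 <- scan_single_locus(y[perm], X[perm, ], K[perm, perm], p2)
  # permuting lines re-runs the eigendecomposition on a reordered matrix, so
  # agreement is to optimizer/eigen floating-point resolution
  expect_equal(sc2$p_value, sc$p_value, tolerance = 1e-6)
  # positive effect means the alternate allele raises the trait
  expect_gt(sc$effect[10], 0)
  expect_lt(sc$p_value[10], 0.01)
  # flipping the coding flips the sign coherently
  p3 <- make_panel(2 - p$dosage, chrom = p$map$chrom, pos = p$map$pos)
  sc3 <- scan_single_locus(y, X, K, p3)
  expect_equal(sc3$effect, -sc$effect, tolerance = 1e-6)
  expect_equal(sc3$p_value, sc$p_value, tolerance = 1e-6)
})

test_that("a strong causal marker is the top hit and significance uses 1/m", {
  qt <- data.frame(chrom = 2, pos = 5e6, maf = 0.3, effect = 1,
                   target_pve = 0.10)
  p <- simulate_genotype_panel(n = 230, m = 500, required_positions = qt,
                               seed = 10)
  K <- compute_kinship(p); pc <- compute_pca(p, 5)
  des <- simulation_design(qtls = qt, seed = 55)
  hits <- 0
  for (i in 1:10) {
    tr <- simulate_phenotypes(p, des, K, pc, n_reps = 1)
    des$seed <- des$seed + 1
    sc <- scan_single_locus(tr[[1]]$phenotype, gwas_covariates(pc), K, p)
    j <- which(p$map$chrom == 2 & p$map$pos == 5e6)
    if (which.min(sc$p_value) == j) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # the significance rule is p < 1/m
  sc <- scan_single_locus(rnorm(230), gwas_covariates(pc), K, p)
  expect_identical(sc$significant, sc$p_value < 1 / 500)
})
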