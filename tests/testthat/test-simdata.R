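test_that("generated panels respect coding, required positions, MAF targets and determinism", {
  qt <- benchmark_qtl_table()[c(1, 8), ]
  p <- simulate_genotype_panel(n = 150, m = 400, maf_range = c(0.05, 0.5),
                               n_subpops = 2, required_positions = qt,
                               seed = 31)
  expect_silent(validate_panel(p))
  expect_true(all(p$dosage %in% c(0, 2)))
  idx <- match(paste(qt$chrom, qt$pos), paste(p$map$chrom, p$map$pos))
  expect_false(anyNA(idx))
  expect_true(all(abs(p$maf[idx] - qt$maf) <= 0.05))
  expect_true(all(p$maf >= 0.05 - 1e-12))
  # positions strictly increasing within chromosomes
  expect_true(all(unlist(tapply(p$map$pos, p$map$chrom, diff)) > 0))
  p2 <- simulate_genotype_panel(n = 150, m = 400, maf_range = c(0.05, 0.5),
                                n_subpops = 2, required_positions = qt,
                                seed = 31)
  expect_identical(p$dosage, p2$dosage)
  expect_identical(p$map, p2$map)
  # parameter validation
  expect_error(simulate_genotype_panel(n = 1, m = 10), "n >= 2")
  expect_error(simulate_genotype_panel(n = 5, m = 5, maf_range = c(0, 0.6)),
               "maf_range")
  expect_error(
    simulate_genotype_panel(n = 5, m = 5,
                            required_positions = data.frame(chrom = 1, pos = 1e10)),
    "outside chromosome")
})

test_that("MAF computation: symmetric dosage counts give 0.5", {
  p <- make_panel(cbind(c(0, 0, 2, 2)))
  expect_equal(p$maf, c(SNP_1_100000 = 0.5))
})

test_that("matched-PVE calibration reproduces the variance budget algebra", {
  qt <- benchmark_qtl_table()
  p <- simulate_genotype_panel(n = 230, m = 800, required_positions = qt,
                               seed = 11)
  K <- compute_kinship(p)
  des <- simulation_design(seed = 3)
  cal <- calibrate_qtl_effects(p, des, K)
  # independent algebra: T (1 - sum pve - s) = sigma_g^2 mean(diag K) + sigma_e^2
  T_expected <- (mean(diag(K)) + 1) / (1 - sum(qt$target_pve) - 0.10)
  expect_equal(cal$total_var, T_expected, tolerance = 1e-12)
  expect_equal(cal$structure_var, 0.10 * T_expected, tolerance = 1e-12)
  # with mean(diag K) ~= 1 this is the 0.34 T = 2 budget, T ~= 5.88
  expect_equal(cal$total_var, 5.88, tolerance = 0.01)
  # each calibrated QTL explains exactly its target share of T on this panel
  realized <- cal$effects^2 * cal$marker_var / cal$total_var
  expect_equal(unname(realized), qt$target_pve, tolerance = 1e-10)
  # a zero-PVE QTL gets a zero effect
  qt0 <- qt
  qt0$target_pve[1] <- 0
  cal0 <- calibrate_qtl_effects(p, simulation_design(qtls = qt0, seed = 3), K)
  expect_identical(cal0$effects[1], 0)
  # infeasible budget errors
  qt_bad <- qt
  qt_bad$target_pve <- rep(0.12, 8)
  expect_error(simulation_design(qtls = qt_bad), "< 1")
  # missing QTL position errors
  p_small <- simulate_genotype_panel(n = 50, m = 20, seed = 1)
  expect_error(calibrate_qtl_effects(p_small, des), "missing from panel")
})

test_that("printed-effects mode realized PVE matches a direct variance-ratio oracle", {
  qt <- benchmark_qtl_table()
  p <- simulate_genotype_panel(n = 230, m = 600, required_positions = qt,
                               seed = 19)
  K <- compute_kinship(p)
  pc <- compute_pca(p, 5)
  des <- simulation_design(effect_mode = "printed_effects", seed = 23)
  tr <- simulate_phenotypes(p, des, K, pc, n_reps = 5)
  idx <- match(paste(qt$chrom, qt$pos), paste(p$map$chrom, p$map$pos))
  for (t in tr) {
    y <- t$phenotype
    direct <- vapply(seq_len(8), function(j) {
      var(p$dosage[, idx[j]] * qt$effect[j]) / var(y)
    }, numeric(1))
    expect_equal(t$qtl$realized_pve, direct, tolerance = 1e-10)
    expect_equal(t$qtl$effect, qt$effect)
  }
})

test_that("phenotype variance components add up and replicates are reproducible", {
  p <- simulate_genotype_panel(n = 400, m = 600, seed = 5)
  K <- compute_kinship(p)
  pc <- compute_pca(p, 5)
  # null design: no QTL variance, no structure
  qt <- benchmark_qtl_table()[1, ]
  qt$target_pve <- 0
  # required marker present so calibration can find it
  p <- simulate_genotype_panel(n = 400, m = 600, required_positions = qt,
                               seed = 5)
  K <- compute_kinship(p); pc <- compute_pca(p, 5)
  des <- simulation_design(qtls = qt, structure_pve = 0, seed = 41)
  tr <- simulate_phenotypes(p, des, K, pc, n_reps = 30)
  vy <- mean(vapply(tr, function(t) var(t$phenotype), numeric(1)))
  expected <- mean(diag(K)) * 1 + 1
  expect_lt(abs(vy - expected) / expected, 0.05)
  # zero-QTL phenotypes carry no QTL variance
  expect_true(all(vapply(tr, function(t) t$realized_total_pve, numeric(1)) == 0))
  # per-replicate seeding: regenerating the set reproduces any replicate
  tr2 <- simulate_phenotypes(p, des, K, pc, n_reps = 30)
  expect_identical(tr[[17]]$phenotype, tr2[[17]]$phenotype)
})

test_that("sigma_g = 0 phenotypes are independent noise, uncorrelated with structure", {
  qt <- benchmark_qtl_table()[1, ]
  qt$target_pve <- 0
  p <- simulate_genotype_panel(n = 300, m = 500, required_positions = qt,
                               seed = 13)
  K <- compute_kinship(p); pc <- compute_pca(p, 5)
  des <- simulation_design(qtls = qt, polygenic_var = 0, residual_var = 1,
                           structure_pve = 0, seed = 2)
  tr <- simulate_phenotypes(p, des, K, pc, n_reps = 20)
  cors <- vapply(tr, function(t) cor(t$phenotype, pc$scores[, 1]), numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
  expect_lt(mean(abs(cors)), 0.1)
})

test_that("trait-panel generator honours heritability and trait correlations", {
  p <- simulate_genotype_panel(n = 230, m = 50, seed = 3)
  # h2 = 1: replicates within a line are identical
  tt <- simulate_trait_panel(p, n_traits = 2, h2 = 1, n_reps_per_line = 3,
                             seed = 7)
  sp <- split(tt$trait1, tt$line_id)
  expect_true(all(vapply(sp, function(v) max(v) - min(v), numeric(1)) == 0))
  # identity trait_corr: small mean |off-diagonal| sample correlation
  tt2 <- simulate_trait_panel(p, n_traits = 7, h2 = 0.5, n_reps_per_line = 3,
                              seed = 8)
  ct <- trait_correlations(tt2)
  off <- ct$r[upper.tri(ct$r)]
  expect_lt(mean(abs(off)), 0.1)
  # non-PSD correlation matrix is rejected
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(simulate_trait_panel(p, 2, 0.5, trait_corr = bad),
               "semi-definite")
})

test_that("design configs round-trip through YAML", {
  des <- simulation_design(seed = 77, n_reps = 12,
                           effect_mode = "printed_effects")
  path <- tempfile(fileext = ".yml")
  write_design(des, path)
  des2 <- read_design(path)
  expect_equal(des$qtls, des2$qtls)
  expect_identical(des2$effect_mode, "printed_effects")
  expect_identical(des2$n_reps, 12L)
})

test_that("truth records export one row per replicate and QTL", {
  qt <- benchmark_qtl_table()
  p <- simulate_genotype_panel(n = 60, m = 100, required_positions = qt,
                               seed = 2)
  K <- compute_kinship(p); pc <- compute_pca(p, 5)
  tr <- simulate_phenotypes(p, simulation_design(seed = 4), K, pc, n_reps = 3)
  path <- tempfile(fileext = ".tsv")
  write_truth_tsv(tr, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 3 * 8)
  expect_true(all(tab$realized_pve >= 0 & tab$realized_pve <= 1))
})
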