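#' Maize-like default chromosome lengths
#'
#' Ten chromosomes with lengths (bp) on the scale of the maize B73 genome,
#' used as the default coordinate system for synthetic panels.
#'
#' @return numeric vector of 10 chromosome lengths in bp.
#' @export
default_chrom_lengths <- function() {
  c(301e6, 237e6, 232e6, 242e6, 217e6, 169e6, 176e6, 175e6, 157e6, 149e6)
}

#' The eight-QTL benchmark table
#'
#' The quantitative trait loci used by the Monte-Carlo power benchmark: one
#' QTL on each of chromosomes 1-8 with its position, target minor allele
#' frequency, additive allele-substitution effect (trait units per coded
#' allele copy under 0/2 dosage coding) and target fraction of phenotypic
#' variance. The per-QTL variance fractions are 4, 4, 6, 6, 8, 8, 10 and 10
#' percent, so the eight QTL jointly explain 56% of the phenotypic variance.
#'
#' @return data.frame with columns `chrom`, `pos`, `maf`, `effect`,
#'   `target_pve`.
#' @export
benchmark_qtl_table <- function() {
  data.frame(
    chrom = 1:8,
    pos = c(14898058, 19326559, 20532172, 13181343,
            15819352, 27154881, 16672999, 22685122),
    maf = c(0.335, 0.16, 0.307, 0.452, 0.204, 0.378, 0.085, 0.217),
    effect = c(0.569, 0.842, 1.041, 0.667, 0.935, 0.766, 1.564, 1.028),
    target_pve = c(0.04, 0.04, 0.06, 0.06, 0.08, 0.08, 0.10, 0.10)
  )
}

#' Specify a phenotype simulation design
#'
#' Bundles the QTL specification and variance components of the simulation
#' model y = sum_j x_j a_j + Q gamma + g + e, where g is a polygenic effect
#' with covariance sigma2_g K, e is independent residual noise, and Q holds
#' the leading principal-component scores of the genotype panel whose
#' contribution is scaled to a fixed fraction of the phenotypic variance.
#'
#' @param qtls data.frame like [benchmark_qtl_table()]; `target_pve` entries
#'   must lie in \[0,1\] and `maf` in (0, 0.5\].
#' @param polygenic_var polygenic variance sigma2_g (default 1).
#' @param residual_var residual variance sigma2_e (default 1).
#' @param structure_pcs number of PC-score columns carrying the structure
#'   effect (default 5).
#' @param structure_pve fraction of phenotypic variance contributed by the
#'   structure term (default 0.10).
#' @param n_reps number of simulation replicates (default 200).
#' @param seed master seed; per-replicate seeds are derived with
#'   [derive_seed()].
#' @param effect_mode `"matched_pve"` rescales each QTL effect so its
#'   realized variance fraction matches `target_pve`; `"printed_effects"`
#'   uses the `effect` column verbatim.
#' @return A `simulation_design` object (list).
#' @export
simulation_design <- function(qtls = benchmark_qtl_table(),
                              polygenic_var = 1, residual_var = 1,
                              structure_pcs = 5, structure_pve = 0.10,
                              n_reps = 200, seed = 1L,
                              effect_mode = c("matched_pve", "printed_effects")) {
  effect_mode <- match.arg(effect_mode)
  qtls <- as.data.frame(qtls)
  stopifnot(all(c("chrom", "pos", "maf", "effect", "target_pve") %in% names(qtls)))
  if (any(qtls$target_pve < 0 | qtls$target_pve > 1)) {
    stop("target_pve must be in [0,1]")
  }
  if (any(qtls$maf <= 0 | qtls$maf > 0.5)) stop("maf must be in (0, 0.5]")
  if (structure_pve < 0 || structure_pve >= 1) stop("structure_pve must be in [0,1)")
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (sum(qtls$target_pve) + structure_pve >= 1) {
    stop("sum of target_pve plus structure_pve must be < 1")
  }
  structure(list(
    qtls = qtls, polygenic_var = polygenic_var, residual_var = residual_var,
    structure_pcs = structure_pcs, structure_pve = structure_pve,
    n_reps = as.integer(n_reps), seed = as.integer(seed),
    effect_mode = effect_mode
  ), class = "simulation_design")
}

#' Read / write a simulation design as a YAML config
#'
#' @param design a `simulation_design`.
#' @param path file path.
#' @return `read_design` returns a `simulation_design`; `write_design`
#'   returns `path` invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "simulation_design"))
  x <- unclass(design)
  x$qtls <- as.list(as.data.frame(x$qtls))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- yaml::read_yaml(path)
  simulation_design(
    qtls = as.data.frame(x$qtls), polygenic_var = x$polygenic_var,
    residual_var = x$residual_var, structure_pcs = x$structure_pcs,
    structure_pve = x$structure_pve, n_reps = x$n_reps, seed = x$seed,
    effect_mode = x$effect_mode
  )
}

#' Simulate an inbred genotype panel
#'
#' Generates a biallelic SNP panel for `n` fully homozygous lines with three
#' statistical features of a diverse inbred association panel: population
#' structure (lines belong to `n_subpops` subgroups whose allele frequencies
#' are differentiated by a Balding-Nichols model with the given `fst`),
#' linkage disequilibrium that decays with physical distance (a Gaussian
#' copula chains neighbouring markers within `ld_block_len` with correlation
#' decreasing in distance), and a minor-allele-frequency floor.
#'
#' Markers listed in `required_positions` are generated without subgroup
#' differentiation and outside the LD chain, and their realized MAF is set
#' to the requested value to within rounding (1/2n); this makes them clean
#' causal-variant hosts for the simulation benchmark.
#'
#' @param n number of lines (>= 2).
#' @param m total number of markers (>= 1, including required ones).
#' @param maf_range length-2 vector (lo, hi) in (0, 0.5]; every marker's
#'   realized MAF is at least `lo`.
#' @param n_subpops number of subpopulations (>= 1).
#' @param ld_block_len LD length scale in bp: the distance by which the mean
#'   dosage r2 between chained markers decays to the background level.
#' @param chrom_lengths chromosome lengths in bp.
#' @param required_positions optional data.frame with columns `chrom`,
#'   `pos` and optionally `maf` (target MAF, default mid `maf_range`).
#' @param fst Balding-Nichols differentiation of subpopulation allele
#'   frequencies (default 0.12).
#' @param seed integer seed; identical seeds give bit-identical panels.
#' @return A [genotype_panel()] with complete (no missing) dosages.
#' @export
simulate_genotype_panel <- function(n, m, maf_range = c(0.05, 0.5),
                                    n_subpops = 3, ld_block_len = 250e3,
                                    chrom_lengths = default_chrom_lengths(),
                                    required_positions = NULL,
                                    fst = 0.12, seed = 1L) {
  if (n < 2 || m < 1) stop("need n >= 2 lines and m >= 1 markers")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5]")
  }
  req <- required_positions
  if (!is.null(req)) {
    req <- as.data.frame(req)
    if (is.null(req$maf)) req$maf <- mean(maf_range)
    if (any(req$chrom < 1 | req$chrom > length(chrom_lengths))) {
      stop("required position on unknown chromosome")
    }
    if (any(req$pos < 1 | req$pos > chrom_lengths[req$chrom])) {
      stop("required position outside chromosome bounds")
    }
    if (nrow(req) > m) stop("more required positions than markers requested")
  }
  with_seed(seed, {
    nc <- length(chrom_lengths)
    # deterministic largest-remainder allocation of markers to chromosomes
    frac <- m * chrom_lengths / sum(chrom_lengths)
    m_c <- floor(frac)
    rem <- m - sum(m_c)
    if (rem > 0) {
      extra <- order(frac - m_c, decreasing = TRUE)[seq_len(rem)]
      m_c[extra] <- m_c[extra] + 1L
    }
    subpop <- rep(seq_len(n_subpops), length.out = n)
    line_ids <- sprintf("L%03d", seq_len(n))
    # LD chain rate: thresholding the latent Gaussian to binary dosages
    # attenuates its correlation (to about 0.22 at zero distance for this
    # MAF spectrum), so the latent scale is set well above ld_block_len to
    # put the mean dosage r2 = 0.1 crossing at ld_block_len itself
    ld_scale <- ld_block_len * 2.5
    alleles <- c("A", "C", "G", "T")

    maps <- list(); dosages <- list()
    for (ch in seq_len(nc)) {
      req_ch <- if (is.null(req)) NULL else req[req$chrom == ch, , drop = FALSE]
      n_req <- if (is.null(req_ch)) 0L else nrow(req_ch)
      n_free <- max(m_c[ch] - n_req, 0L)
      pos_free <- sort(sample.int(chrom_lengths[ch], n_free))
      pos_free <- setdiff(pos_free, req_ch$pos)
      pos <- sort(c(pos_free, req_ch$pos))
      mm <- length(pos)
      if (mm == 0L) next
      is_req <- pos %in% req_ch$pos
      # target alternate-allele frequencies
      tmaf <- runif(mm, maf_range[1], maf_range[2])
      flip <- runif(mm) < 0.5
      p0 <- ifelse(flip, tmaf, 1 - tmaf)
      if (n_req > 0) p0[is_req] <- req_ch$maf[match(pos[is_req], req_ch$pos)]
      # subpopulation frequencies (Balding-Nichols); required markers undifferentiated
      pk <- matrix(0, n_subpops, mm)
      for (k in seq_len(n_subpops)) {
        a <- p0 * (1 - fst) / fst
        b <- (1 - p0) * (1 - fst) / fst
        pk[k, ] <- rbeta(mm, a, b)
      }
      if (any(is_req)) pk[, is_req] <- matrix(p0[is_req], n_subpops,
                                              sum(is_req), byrow = TRUE)
      pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
      # latent Gaussian chain over markers, per line
      Z <- matrix(0, n, mm)
      prev <- 0L
      for (j in seq_len(mm)) {
        e <- rnorm(n)
        if (is_req[j] || prev == 0L) {
          Z[, j] <- e
        } else {
          rho <- exp(-(pos[j] - pos[prev]) / ld_scale)
          Z[, j] <- rho * Z[, prev] + sqrt(1 - rho^2) * e
        }
        if (!is_req[j]) prev <- j
      }
      thr <- qnorm(t(pk[subpop, , drop = FALSE]))   # mm x n
      D <- 2 * (Z < t(thr))
      # MAF repair: floor for free markers, exact target for required markers
      cnt <- colSums(D) / 2
      lo_cnt <- ceiling(maf_range[1] * n)
      for (j in seq_len(mm)) {
        tgt <- NA
        if (is_req[j]) {
          tgt <- round(p0[j] * n)
        } else {
          mincnt <- min(cnt[j], n - cnt[j])
          if (mincnt < lo_cnt) {
            tgt <- if (cnt[j] <= n / 2) lo_cnt else n - lo_cnt
          }
        }
        if (!is.na(tgt)) {
          need <- tgt - cnt[j]
          if (need > 0) {
            from <- which(D[, j] == 0)
            D[sample(from, min(need, length(from))), j] <- 2
          } else if (need < 0) {
            from <- which(D[, j] == 2)
            D[sample(from, min(-need, length(from))), j] <- 0
          }
        }
      }
      ra <- t(vapply(seq_len(mm), function(j) sample(alleles, 2), character(2)))
      maps[[ch]] <- data.frame(chrom = ch, pos = pos,
                               ref = ra[, 1], alt = ra[, 2])
      dosages[[ch]] <- D
    }
    map <- do.call(rbind, maps)
    dosage <- do.call(cbind, dosages)
    # designated causal markers sit on different chromosomes, so the
    # simulation budget treats their contributions as additive and
    # independent; remove the spurious sample correlation a finite panel
    # would otherwise give them (allele counts are preserved exactly)
    if (!is.null(req) && nrow(req) > 1) {
      ridx <- which(paste(map$chrom, map$pos) %in% paste(req$chrom, req$pos))
      dosage[, ridx] <- decorrelate_markers(dosage[, ridx, drop = FALSE])
    }
    rownames(dosage) <- line_ids
    panel <- genotype_panel(dosage, map, line_ids)
    attr(panel, "subpop") <- subpop
    panel
  })
}

# Hill-climb line swaps (minor-allele counts fixed) so the pairwise sample
# correlations of the given dosage columns drop below `target`.
decorrelate_markers <- function(D, target = 0.02, max_swaps = 5000) {
  k <- ncol(D)
  if (k < 2) return(D)
  n <- nrow(D)
  for (j in 2:k) {
    prev <- scale(D[, 1:(j - 1), drop = FALSE])
    x <- D[, j]
    cscale <- 2 / ((n - 1) * sd(x))   # swap quantum on the correlation scale
    for (it in seq_len(max_swaps)) {
      r <- as.vector(crossprod(prev, scale(x)) / (n - 1))
      if (max(abs(r)) < target) break
      ones <- which(x == 2)
      zeros <- which(x == 0)
      if (!length(ones) || !length(zeros)) break
      # steepest-descent swap on sum(r^2): moving an allele from line i1 to
      # line i2 shifts r by cscale * (prev[i2,] - prev[i1,])
      proj <- as.vector(prev %*% r)
      i1 <- ones[which.max(proj[ones])]
      i2 <- zeros[which.min(proj[zeros])]
      rn <- r + cscale * (prev[i2, ] - prev[i1, ])
      if (sum(rn^2) >= sum(r^2) - 1e-12) break
      x[i1] <- 0
      x[i2] <- 2
    }
    D[, j] <- x
  }
  D
}

#' Calibrate QTL effects against a genotype panel
#'
#' Converts a simulation design into per-QTL allele-substitution effects on
#' the panel that will host them, together with the implied total phenotypic
#' variance and the variance of the population-structure term.
#'
#' In `matched_pve` mode each effect is a_j = sign(effect_j) *
#' sqrt(target_pve_j * T / Var(x_j)) with T the total phenotypic variance
#' solving T * (1 - sum(target_pve) - structure_pve) = sigma2_g * mean(diag K)
#' + sigma2_e, so each QTL explains exactly its target fraction on this
#' panel. In `printed_effects` mode the design's effects are used verbatim
#' and T is computed from their realized joint variance.
#'
#' @param panel a complete [genotype_panel()] containing a marker at every
#'   QTL position.
#' @param design a [simulation_design()].
#' @param kinship optional kinship matrix; its mean diagonal scales the
#'   polygenic variance contribution (taken as 1 when absent).
#' @return list with `effects`, `structure_var`, `total_var`, `qtl_index`,
#'   and `marker_var` (sample variance of each QTL marker's dosage).
#' @export
calibrate_qtl_effects <- function(panel, design, kinship = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(design, "simulation_design"))
  q <- design$qtls
  idx <- marker_index(panel, q$chrom, q$pos)
  if (anyNA(idx)) {
    stop(sprintf("QTL position(s) missing from panel: %s",
                 paste(sprintf("chr%d:%d", q$chrom[is.na(idx)],
                               q$pos[is.na(idx)]), collapse = ", ")))
  }
  X <- panel$dosage[, idx, drop = FALSE]
  if (anyNA(X)) stop("panel must be complete (imputed) at QTL markers")
  vx <- apply(X, 2, var)
  mK <- if (is.null(kinship)) 1 else mean(diag(as.matrix(kinship)))
  base <- design$polygenic_var * mK + design$residual_var
  s <- design$structure_pve
  if (design$effect_mode == "matched_pve") {
    spve <- sum(q$target_pve)
    if (spve + s >= 1) stop("target PVEs infeasible: sum + structure_pve >= 1")
    total_var <- base / (1 - spve - s)
    if (any(vx == 0 & q$target_pve > 0)) {
      stop("monomorphic marker at a QTL with nonzero target_pve")
    }
    eff <- ifelse(q$target_pve == 0, 0,
                  sign(ifelse(q$effect == 0, 1, q$effect)) *
                    sqrt(q$target_pve * total_var / vx))
  } else {
    eff <- q$effect
    vq <- var(as.vector(X %*% eff))
    total_var <- (vq + base) / (1 - s)
  }
  list(effects = eff, structure_var = s * total_var, total_var = total_var,
       qtl_index = idx, marker_var = vx)
}

#' Simulate benchmark phenotypes over replicates
#'
#' Draws `n_reps` phenotype vectors under the variance-component model of
#' the simulation design: QTL effects (fixed across replicates), a
#' population-structure term carried by the leading PC scores and rescaled
#' each replicate so its sample variance is exactly `structure_pve` of the
#' implied total variance, a polygenic effect with covariance
#' sigma2_g * K, and independent residual noise. Replicate r uses the seed
#' `derive_seed(design$seed, r)`, so any replicate is reproducible in
#' isolation.
#'
#' @param panel complete [genotype_panel()].
#' @param design a [simulation_design()].
#' @param kinship kinship matrix from [compute_kinship()].
#' @param pcs PC scores from [compute_pca()] of the same panel.
#' @param n_reps number of replicates (defaults to `design$n_reps`).
#' @return list of truth records; each has `replicate`, `seed`, `qtl`
#'   (chrom, pos, effect, realized_pve), `realized_total_pve` and
#'   `phenotype` (named n-vector).
#' @export
simulate_phenotypes <- function(panel, design, kinship, pcs,
                                n_reps = design$n_reps) {
  stopifnot(inherits(design, "simulation_design"))
  k <- design$structure_pcs
  if (design$structure_pve > 0 && k > ncol(pcs$scores)) {
    stop("structure_pcs exceeds the number of available PCs")
  }
  cal <- calibrate_qtl_effects(panel, design, kinship)
  n <- n_lines(panel)
  Xq <- panel$dosage[, cal$qtl_index, drop = FALSE]
  qtl_part <- as.vector(Xq %*% cal$effects)
  eK <- eigen(as.matrix(kinship), symmetric = TRUE)
  gscale <- sqrt(pmax(eK$values, 0) * design$polygenic_var)
  Q <- if (design$structure_pve > 0) {
    pcs$scores[, seq_len(k), drop = FALSE]
  } else NULL
  lapply(seq_len(n_reps), function(r) {
    sr <- derive_seed(design$seed, r)
    with_seed(sr, {
      g <- as.vector(eK$vectors %*% (gscale * rnorm(n)))
      e <- rnorm(n, sd = sqrt(design$residual_var))
      v <- 0
      if (!is.null(Q)) {
        v <- as.vector(Q %*% rnorm(k))
        sv <- var(v)
        v <- if (sv > 0) v * sqrt(cal$structure_var / sv) else v * 0
      }
      y <- qtl_part + v + g + e
      names(y) <- panel$line_ids
      vy <- var(y)
      per_qtl <- (cal$effects^2) * cal$marker_var / vy
      # the total is the sum of per-QTL fractions, as in the design budget
      # (4+4+6+6+8+8+10+10 = 56%); sample covariances between QTL markers
      # are not attributed to the QTL total
      list(replicate = r, seed = sr,
           qtl = data.frame(chrom = design$qtls$chrom, pos = design$qtls$pos,
                            effect = cal$effects, realized_pve = per_qtl),
           realized_total_pve = sum(per_qtl),
           phenotype = y)
    })
  })
}

#' Write a set of truth records to TSV
#'
#' One row per (replicate, QTL) with the realized effect and variance
#' fraction.
#'
#' @param truth list of truth records from [simulate_phenotypes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  rows <- do.call(rbind, lapply(truth, function(tr) {
    cbind(replicate = tr$replicate, tr$qtl)
  }))
  data.table::fwrite(rows, path, sep = "\t")
  invisible(path)
}

#' Simulate a replicate-level multi-trait table
#'
#' Fixture generator for the descriptive-statistics / heritability stages:
#' draws line-level genetic values and replicate-level residuals so that the
#' intraclass correlation of each trait equals `h2` and traits are
#' correlated according to `trait_corr` (applied to both components, hence
#' also the phenotypic correlation). It emulates the structure of a
#' replicated field trial (e.g. viscosity traits measured on three
#' biological replicates per line); trait values are on an arbitrary scale
#' with unit phenotypic variance.
#'
#' @param panel a [genotype_panel()]; only its line identifiers are used.
#' @param n_traits number of traits.
#' @param h2 per-trait broad-sense heritability in \[0,1\] (recycled).
#' @param trait_corr trait correlation matrix (symmetric PSD).
#' @param n_reps_per_line replicates per line (default 3).
#' @param seed integer seed.
#' @return data.frame with columns `line_id`, `rep_id`, `trait1..traitT`.
#' @export
simulate_trait_panel <- function(panel, n_traits, h2,
                                 trait_corr = diag(n_traits),
                                 n_reps_per_line = 3, seed = 1L) {
  h2 <- rep_len(h2, n_traits)
  if (any(h2 < 0 | h2 > 1)) stop("h2 entries must be in [0,1]")
  trait_corr <- as.matrix(trait_corr)
  if (max(abs(trait_corr - t(trait_corr))) > 1e-8) {
    stop("trait_corr must be symmetric")
  }
  ec <- eigen(trait_corr, symmetric = TRUE)
  if (min(ec$values) < -1e-8) stop("trait_corr must be positive semi-definite")
  Croot <- ec$vectors %*% (sqrt(pmax(ec$values, 0)) * t(ec$vectors))
  n <- n_lines(panel)
  with_seed(seed, {
    G <- matrix(rnorm(n * n_traits), n) %*% Croot
    G <- sweep(G, 2, sqrt(h2), "*")
    out <- do.call(rbind, lapply(seq_len(n_reps_per_line), function(rp) {
      E <- matrix(rnorm(n * n_traits), n) %*% Croot
      E <- sweep(E, 2, sqrt(1 - h2), "*")
      vals <- G + E
      colnames(vals) <- paste0("trait", seq_len(n_traits))
      data.frame(line_id = panel$line_ids, rep_id = rp, vals,
                 row.names = NULL)
    }))
    out[order(out$line_id, out$rep_id), , drop = FALSE]
  })
}
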