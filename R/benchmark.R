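#' Match significant detections to simulated QTL
#'
#' A detection matches a QTL when it lies on the same chromosome within
#' `window` bp (boundary inclusive, so a 1000-bp offset under the default
#' 1-kb window is still a hit). Each detection matches at most one QTL:
#' the nearest wins, with the lower-position QTL breaking exact ties.
#' Multiple detections inside one QTL's window collapse to a single hit
#' and none of them count as false positives; every unmatched detection is
#' a false positive.
#'
#' @param detections data.frame with `chrom` and `pos` columns (e.g. the
#'   significant rows of an `association_result`).
#' @param truth either a truth record from [simulate_phenotypes()] or a
#'   data.frame of QTL with `chrom` and `pos`.
#' @param window matching window in bp (default 1000).
#' @return list with `hit` (logical per QTL), `n_false_positives`, and
#'   `assignment` (per-detection QTL index or NA).
#' @export
match_detections <- function(detections, truth, window = 1000) {
  qtl <- if (is.data.frame(truth)) truth else truth$qtl
  nq <- nrow(qtl)
  nd <- if (is.null(detections)) 0 else nrow(detections)
  assignment <- rep(NA_integer_, nd)
  if (nd > 0 && nq > 0) {
    for (i in seq_len(nd)) {
      same <- which(qtl$chrom == detections$chrom[i])
      if (!length(same)) next
      dist <- abs(qtl$pos[same] - detections$pos[i])
      ok <- dist <= window
      if (!any(ok)) next
      cand <- same[ok]
      dd <- dist[ok]
      best <- cand[order(dd, qtl$pos[cand])][1]
      assignment[i] <- best
    }
  }
  hit <- seq_len(nq) %in% assignment
  list(hit = hit, n_false_positives = sum(is.na(assignment)) * (nd > 0),
       assignment = assignment)
}

#' Monte-Carlo power and Type-I-error benchmark
#'
#' Repeats the full simulation-and-scan cycle: each replicate simulates a
#' phenotype from the design on the fixed panel, runs every requested
#' association engine with its native significance rule (LOD > 3 for the
#' EM-empirical-Bayes and lasso engines; p < 1/m for the single-locus
#' mixed-model and iterative fixed/random engines), and matches the
#' significant markers to the simulated QTL within a 1-kb window. Power
#' for a QTL is the fraction of replicates in which it is hit; Type I
#' error is pooled over replicates as
#' total false positives / (replicates x non-QTL markers), with the
#' per-replicate mean rate also reported. Everything is seeded through
#' [derive_seed()], so any replicate can be reproduced in isolation.
#'
#' @param panel complete [genotype_panel()] hosting the design's QTL.
#' @param design a [simulation_design()].
#' @param methods subset of `c("single_mlm", "fastmremma", "farmcpu",
#'   "lasso")`.
#' @param reps number of replicates (default `design$n_reps`).
#' @param seed master seed (default `design$seed`).
#' @param window matching window in bp (default 1000).
#' @param lod_threshold LOD rule for the multi-locus LOD-based engines.
#' @return list of class `power_table`: `power` (QTL x method matrix of
#'   fractions), `type_i_error` (pooled, per method), `type_i_error_rep_mean`,
#'   `n_reps`, `thresholds`, and a per-replicate `detections` log.
#' @export
run_power_study <- function(panel, design,
                            methods = c("single_mlm", "fastmremma",
                                        "farmcpu", "lasso"),
                            reps = design$n_reps, seed = design$seed,
                            window = 1000, lod_threshold = 3) {
  known <- c("single_mlm", "fastmremma", "farmcpu", "lasso")
  if (!all(methods %in% known)) {
    stop(sprintf("unknown method(s): %s",
                 paste(setdiff(methods, known), collapse = ", ")))
  }
  if (reps < 1) stop("reps must be >= 1")
  d <- panel$dosage
  if (anyNA(d)) stop("panel must be imputed before benchmarking")
  m <- n_markers(panel)
  design$seed <- as.integer(seed)
  design$n_reps <- as.integer(reps)

  K <- compute_kinship(panel)
  eig <- kinship_eigen(K)
  pcs <- compute_pca(panel, k = max(design$structure_pcs, 2))
  X <- gwas_covariates(pcs, design$structure_pcs)
  UtG <- if (any(c("single_mlm", "fastmremma") %in% methods)) {
    crossprod(eig$vectors, d)
  } else NULL
  truth <- simulate_phenotypes(panel, design, K, pcs, n_reps = reps)

  nq <- nrow(design$qtls)
  hits <- matrix(0, nq, length(methods),
                 dimnames = list(paste0("QTL", seq_len(nq)), methods))
  fp <- setNames(numeric(length(methods)), methods)
  log_rows <- list()
  p_thresh <- 1 / m
  for (r in seq_len(reps)) {
    y <- truth[[r]]$phenotype
    for (mt in methods) {
      res <- switch(
        mt,
        single_mlm = scan_single_locus(y, X, K, panel, eig = eig, UtG = UtG,
                                       sig_threshold = p_thresh),
        fastmremma = scan_fastmremma(y, X, K, panel, eig = eig, UtG = UtG,
                                     lod_threshold = lod_threshold),
        farmcpu = scan_farmcpu(y, X, panel, sig_threshold = p_thresh),
        lasso = scan_lasso(y, X, panel,
                           seed = derive_seed(truth[[r]]$seed, 999),
                           lod_threshold = lod_threshold)
      )
      det <- res[res$significant, c("chrom", "pos"), drop = FALSE]
      mres <- match_detections(det, truth[[r]], window)
      hits[, mt] <- hits[, mt] + mres$hit
      fp[mt] <- fp[mt] + mres$n_false_positives
      if (nrow(det)) {
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(replicate = r, method = mt, chrom = det$chrom,
                     pos = det$pos,
                     matched_qtl = ifelse(is.na(mres$assignment), 0,
                                          mres$assignment))
      }
    }
  }
  denom <- reps * (m - nq)
  structure(list(
    power = hits / reps,
    type_i_error = fp / denom,
    type_i_error_rep_mean = fp / reps / (m - nq),
    n_false_positives = fp,
    n_reps = reps, n_markers = m,
    thresholds = list(p = p_thresh, lod = lod_threshold, window = window),
    detections = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(replicate = integer(0), method = character(0),
                 chrom = integer(0), pos = numeric(0),
                 matched_qtl = integer(0))
  ), class = "power_table")
}

#' @method print power_table
#' @export
print.power_table <- function(x, ...) {
  cat(sprintf("power_table: %d replicates, %d markers\n", x$n_reps,
              x$n_markers))
  tab <- rbind(round(100 * x$power, 1),
               `Type I error` = signif(x$type_i_error, 3))
  print(tab)
  invisible(x)
}

#' Write a power table to TSV
#'
#' One row per QTL (power in percent) plus a final `Type I error` row, one
#' column per method.
#'
#' @param pt a `power_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_power_tsv <- function(pt, path) {
  tab <- rbind(100 * pt$power, `Type I error` = pt$type_i_error)
  df <- data.frame(QTL = rownames(tab), tab, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
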