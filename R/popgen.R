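#' Genomic relationship (kinship) matrix
#'
#' Standardized (VanRaden-type) kinship K = W W' / m, where W is the
#' column-standardized dosage matrix (each marker centred and scaled to
#' unit sample variance). Zero-variance markers are excluded with a
#' warning. K is symmetric positive semi-definite and models the polygenic
#' covariance between lines in the mixed model.
#'
#' @param panel a complete (imputed) [genotype_panel()].
#' @return n x n matrix with line ids as dimnames, class `matrix`.
#' @export
compute_kinship <- function(panel) {
  d <- panel$dosage
  if (anyNA(d)) stop("panel must be imputed before computing kinship")
  W <- standardize_dosage(d)
  K <- tcrossprod(W) / ncol(W)
  K <- (K + t(K)) / 2
  dimnames(K) <- list(panel$line_ids, panel$line_ids)
  K
}

#' Principal components of the standardized genotype matrix
#'
#' PC scores are computed from the eigendecomposition of the kinship matrix
#' of the standardized dosages, so they reproduce K's top eigenvectors
#' exactly. Used to control population structure in all four association
#' engines (the first five PCs by default, following the scree-plot
#' convention for this panel type).
#'
#' @param panel a complete [genotype_panel()].
#' @param k number of components (default 5).
#' @return list of class `pc_result` with `scores` (n x k, columns
#'   orthogonal), `explained_var` (non-increasing eigenvalue shares of the
#'   per-line variance) and `values` (raw eigenvalues of K).
#' @export
compute_pca <- function(panel, k = 5) {
  if (k <= 0) stop("k must be positive")
  n <- n_lines(panel)
  if (k > n) stop("k exceeds the number of lines")
  K <- compute_kinship(panel)
  e <- eigen(K, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rownames(scores) <- panel$line_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 explained_var = ev[seq_len(k)] / sum(ev),
                 values = ev),
            class = "pc_result")
}

#' Pairwise LD decay table
#'
#' Composite linkage disequilibrium: r2 is the squared Pearson correlation
#' of dosage vectors (appropriate for unphased inbred genotypes), computed
#' for all same-chromosome marker pairs within `max_dist`, then averaged in
#' non-overlapping distance bins.
#'
#' @param panel complete [genotype_panel()].
#' @param max_dist largest pair distance considered (default 1 Mb).
#' @param bin_width bin width in bp (default 5 kb).
#' @return data.frame of class `ld_decay_table` with `bin_start`,
#'   `bin_end`, `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(panel, max_dist = 1e6, bin_width = 5e3) {
  d <- panel$dosage
  if (anyNA(d)) stop("panel must be imputed before LD computation")
  nb <- ceiling(max_dist / bin_width)
  sums <- numeric(nb)
  cnts <- numeric(nb)
  for (ch in unique(panel$map$chrom)) {
    sel <- which(panel$map$chrom == ch)
    if (length(sel) < 2) next
    pos <- panel$map$pos[sel]
    X <- scale(d[, sel, drop = FALSE])
    keep <- !is.na(colSums(X))
    X <- X[, keep, drop = FALSE]; pos <- pos[keep]
    m <- length(pos)
    nl <- nrow(X)
    j_hi <- 1L
    for (i in seq_len(m - 1)) {
      while (j_hi < m && pos[j_hi + 1] - pos[i] <= max_dist) j_hi <- j_hi + 1L
      if (j_hi <= i) next
      jj <- (i + 1L):j_hi
      r <- crossprod(X[, i], X[, jj, drop = FALSE]) / (nl - 1)
      b <- pmin(ceiling((pos[jj] - pos[i]) / bin_width), nb)
      r2 <- as.vector(r)^2
      for (u in unique(b)) {
        w <- b == u
        sums[u] <- sums[u] + sum(r2[w])
        cnts[u] <- cnts[u] + sum(w)
      }
    }
  }
  if (all(cnts == 0)) stop("no marker pairs within max_dist")
  out <- data.frame(
    bin_start = (seq_len(nb) - 1) * bin_width,
    bin_end = seq_len(nb) * bin_width,
    bin_mid = (seq_len(nb) - 0.5) * bin_width,
    mean_r2 = ifelse(cnts > 0, sums / cnts, NA_real_),
    n_pairs = cnts
  )
  out <- out[cnts > 0, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ld_decay_table", "data.frame")
  out
}

#' LD decay distance at an r2 cutoff
#'
#' Smooths the binned mean r2 with a rolling median over three bins and
#' returns the midpoint of the first bin at which the smoothed curve falls
#' below `cutoff`. When the curve never crosses, the largest bin midpoint
#' is returned with attribute `crossed = FALSE`.
#'
#' @param table an `ld_decay_table` from [ld_decay()].
#' @param cutoff r2 cutoff (default 0.1).
#' @return distance in bp (numeric scalar, attribute `crossed`).
#' @export
decay_distance <- function(table, cutoff = 0.1) {
  r2 <- table$mean_r2
  sm <- if (length(r2) >= 3) stats::runmed(r2, 3) else r2
  below <- which(sm < cutoff)
  if (!length(below)) {
    return(structure(max(table$bin_mid), crossed = FALSE))
  }
  structure(table$bin_mid[below[1]], crossed = TRUE)
}

#' Write kinship / PC / LD tables to TSV
#'
#' @param x object to write (kinship matrix, `pc_result`, or
#'   `ld_decay_table`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_popgen_tsv <- function(x, path) {
  if (inherits(x, "pc_result")) {
    df <- data.frame(line_id = rownames(x$scores), x$scores)
    data.table::fwrite(df, path, sep = "\t")
  } else if (inherits(x, "ld_decay_table")) {
    data.table::fwrite(as.data.frame(x), path, sep = "\t")
  } else {
    df <- data.frame(line_id = rownames(x), as.data.frame(x))
    data.table::fwrite(df, path, sep = "\t")
  }
  invisible(path)
}
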