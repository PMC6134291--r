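# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no binary fixtures.

# A hand-built panel from an explicit dosage matrix (markers in columns).
make_panel <- function(dosage, chrom = rep(1, ncol(dosage)),
                       pos = seq(1e5, by = 1e5, length.out = ncol(dosage))) {
  map <- data.frame(chrom = chrom, pos = pos,
                    ref = rep("A", ncol(dosage)), alt = rep("G", ncol(dosage)))
  genotype_panel(as.matrix(dosage), map)
}

# Dense-matrix restricted log-likelihood (no eigen rotation): the oracle for
# the rotated REML implementation. Same constant convention as the package:
# l = -1/2 [ (n-p) log 2pi + log|V| + log|X'V^-1 X| + r'V^-1 r ].
dense_reml_loglik <- function(y, X, K, delta, sigma_g2) {
  n <- length(y)
  V <- sigma_g2 * (K + delta * diag(n))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - ncol(X)) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r))
}

# Closed-form REML log-likelihood for the balanced one-way random-effects
# model (a lines, r reps), used as a grid-search oracle for the variance
# components. Constants independent of (vg, ve) are dropped.
balanced_oneway_reml <- function(sse, ssa, a, r, vg, ve) {
  lam <- ve + r * vg
  -0.5 * (a * (r - 1) * log(ve) + (a - 1) * log(lam) +
            sse / ve + ssa / lam)
}

# KKT (subgradient) residual of a lasso solution for
# min 1/(2n)||y - X b||^2 + lambda ||b||_1.
lasso_kkt_gap <- function(X, y, b, lambda) {
  n <- nrow(X)
  g <- as.vector(crossprod(X, y - X %*% b)) / n
  active <- b != 0
  gap_active <- if (any(active)) {
    max(abs(g[active] - lambda * sign(b[active])))
  } else 0
  gap_inactive <- if (any(!active)) max(0, max(abs(g[!active])) - lambda) else 0
  max(gap_active, gap_inactive)
}

# Small GFF3 written to a temp file; genes given as (chrom, start, end, id).
write_toy_gff3 <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chrom, genes$start, genes$end, genes$id))
  writeLines(lines, path)
  path
}

# A minimal hand-written VCF with given genotype strings (markers x lines).
write_toy_vcf <- function(gt, chrom, pos, line_ids,
                          ref = "A", alt = "G",
                          path = tempfile(fileext = ".vcf")) {
  ref <- rep_len(ref, nrow(gt)); alt <- rep_len(alt, nrow(gt))
  rows <- vapply(seq_len(nrow(gt)), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", line_ids), collapse = "\t"),
               rows), path)
  path
}

# Fake association_result rows for the report-module tests.
fake_assoc <- function(trait, marker_id, chrom, pos, method, effect,
                       significant = TRUE, pve = 0.05) {
  out <- data.frame(trait = trait, marker_id = marker_id, chrom = chrom,
                    pos = pos, alleles = "A/G", method = method,
                    effect = effect, se = abs(effect) / 4,
                    p_value = ifelse(significant, 1e-6, 0.5),
                    lod = ifelse(significant, 5, 0.1), pve = pve,
                    significant = significant)
  class(out) <- c("association_result", "data.frame")
  out
}
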