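#' Genotype panel container
#'
#' A `genotype_panel` holds biallelic SNP genotypes for a panel of inbred
#' lines. Because the lines are fully homozygous, coded allele dosages take
#' only the values 0 (homozygous reference) and 2 (homozygous alternate);
#' missing calls are `NA`. Under this coding a marker with alternate-allele
#' frequency p has variance 4p(1-p), which is the convention every effect
#' size downstream of this container uses.
#'
#' @param dosage numeric matrix, lines x markers, entries in \{0, 2, NA\}.
#' @param map data.frame with columns `chrom` (integer), `pos` (1-based bp),
#'   `ref`, `alt` (allele symbols). Positions must be strictly increasing
#'   within each chromosome.
#' @param line_ids character vector of line identifiers (defaults to the
#'   rownames of `dosage`).
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `line_ids`, `map` (with a `marker_id` column `SNP_<chrom>_<pos>`),
#'   `dosage`, and `maf` (per-marker minor allele frequency over non-missing
#'   calls).
#' @export
genotype_panel <- function(dosage, map, line_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(line_ids)) line_ids <- sprintf("L%03d", seq_len(nrow(dosage)))
  stopifnot(nrow(map) == ncol(dosage), length(line_ids) == nrow(dosage))
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(map))) {
    stop("map must have columns chrom, pos, ref, alt")
  }
  bad <- !(dosage %in% c(0, 2) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 2 or NA (inbred homozygotes)")
  map <- as.data.frame(map)[, req]
  map$chrom <- as.integer(map$chrom)
  map$pos <- as.numeric(map$pos)
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
  }
  d <- unlist(tapply(map$pos, map$chrom, function(p) diff(c(-Inf, p))))
  if (any(d <= 0)) stop("positions must be strictly increasing within chromosome")
  map$marker_id <- sprintf("SNP_%d_%d", map$chrom, as.integer(map$pos))
  rownames(map) <- NULL
  dimnames(dosage) <- list(line_ids, map$marker_id)
  obj <- structure(
    list(line_ids = line_ids, map = map, dosage = dosage,
         maf = panel_maf(dosage)),
    class = "genotype_panel"
  )
  obj
}

#' Minor allele frequency from a dosage matrix
#'
#' @param dosage lines x markers matrix with entries 0/2/NA.
#' @return numeric vector of per-marker MAF in \[0, 0.5\], computed on
#'   non-missing calls.
#' @export
panel_maf <- function(dosage) {
  p <- colMeans(dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

# Vectorized per-column sample variance.
col_vars <- function(d) {
  n <- nrow(d)
  mu <- colMeans(d)
  (colSums(d * d) - n * mu^2) / (n - 1)
}

#' @method print genotype_panel
#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d lines x %d markers on %d chromosome(s)\n",
    length(x$line_ids), nrow(x$map), length(unique(x$map$chrom))
  ))
  cat(sprintf("  MAF range %.3f-%.3f; missing calls: %d\n",
              min(x$maf), max(x$maf), sum(is.na(x$dosage))))
  invisible(x)
}

#' @method dim genotype_panel
#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Number of lines / markers in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_lines <- function(panel) nrow(panel$dosage)

#' @rdname n_lines
#' @export
n_markers <- function(panel) ncol(panel$dosage)

#' Validate the internal invariants of a genotype panel
#'
#' Checks dosage coding, agreement of the stored MAF with the dosage matrix
#' (to 1e-12), and strictly increasing positions within chromosomes.
#'
#' @param panel a `genotype_panel`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  bad <- !(panel$dosage %in% c(0, 2) | is.na(panel$dosage))
  if (any(bad)) stop("invalid dosage entries")
  if (max(abs(panel$maf - panel_maf(panel$dosage))) > 1e-12) {
    stop("stored maf does not match dosage")
  }
  d <- unlist(tapply(panel$map$pos, panel$map$chrom, function(p) diff(c(-Inf, p))))
  if (any(d <= 0)) stop("positions not strictly increasing within chromosome")
  invisible(TRUE)
}

# Column index of the marker at (chrom, pos); NA when absent.
marker_index <- function(panel, chrom, pos) {
  match(paste(chrom, pos), paste(panel$map$chrom, panel$map$pos))
}

# Column-standardize a complete dosage matrix; zero-variance markers dropped.
standardize_dosage <- function(dosage) {
  mu <- colMeans(dosage)
  sdv <- apply(dosage, 2, sd)
  keep <- sdv > 0
  if (!all(keep)) {
    warning(sprintf("%d zero-variance marker(s) excluded from standardization",
                    sum(!keep)))
  }
  W <- sweep(dosage[, keep, drop = FALSE], 2, mu[keep], "-")
  W <- sweep(W, 2, sdv[keep], "/")
  attr(W, "kept") <- which(keep)
  W
}
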