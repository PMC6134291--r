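#' Read genotypes from VCF or the plain TSV dialect
#'
#' VCF 4.x files are parsed with `vcfR`; only biallelic SNP records are
#' accepted. Genotype calls are mapped to inbred dosages: `0/0 -> 0`,
#' `1/1 -> 2`, `./. -> NA`. Heterozygous calls are rejected or set missing
#' according to `het_action`, and multi-allelic records are an error or are
#' skipped with a warning according to `multiallelic`.
#'
#' The TSV dialect is one row per marker with columns
#' `chrom  pos  ref  alt  <line 1> ... <line n>` and dosage entries 0, 2 or
#' `NA`.
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`; guessed from the file extension when
#'   omitted.
#' @param het_action what to do with heterozygous calls: `"error"`
#'   (default) or `"missing"`.
#' @param multiallelic `"error"` (default) or `"skip"`.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           het_action = c("error", "missing"),
                           multiallelic = c("error", "skip")) {
  format <- match.arg(format)
  het_action <- match.arg(het_action)
  multiallelic <- match.arg(multiallelic)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
    if (any(multi)) {
      if (multiallelic == "error") {
        stop(sprintf("%d non-biallelic-SNP record(s); first at %s:%s",
                     sum(multi), fix$CHROM[multi][1], fix$POS[multi][1]))
      }
      warning(sprintf("skipping %d non-biallelic-SNP record(s)", sum(multi)))
    }
    keep <- !multi
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    gt <- gsub("|", "/", gt, fixed = TRUE)
    d <- matrix(NA_real_, nrow(gt), ncol(gt))
    d[gt == "0/0"] <- 0
    d[gt == "1/1"] <- 2
    het <- !is.na(gt) & gt %in% c("0/1", "1/0")
    if (any(het)) {
      if (het_action == "error") {
        stop(sprintf("%d heterozygous call(s) in an inbred panel", sum(het)))
      }
      d[het] <- NA_real_
    }
    map <- data.frame(chrom = as.integer(gsub("^chr", "", fix$CHROM[keep])),
                      pos = as.numeric(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep])
    genotype_panel(t(d), map, line_ids = colnames(gt))
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            na.strings = c("NA", "."))
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(dt))) {
      stop("TSV genotype file must start with columns chrom, pos, ref, alt")
    }
    line_ids <- setdiff(names(dt), c("chrom", "pos", "ref", "alt"))
    d <- t(as.matrix(dt[, line_ids, with = FALSE]))
    map <- as.data.frame(dt[, c("chrom", "pos", "ref", "alt")])
    genotype_panel(d, map, line_ids = line_ids)
  }
}

#' Write a genotype panel to VCF or the TSV dialect
#'
#' The VCF writer emits homozygous diploid calls (`0/0`, `1/1`, missing as
#' `./.`) under VCF 4.2; the TSV writer emits the dialect documented in
#' [read_genotypes()]. Both round-trip exactly through [read_genotypes()].
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @param format `"vcf"` or `"tsv"` (guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.vcf$", path)) "vcf" else "tsv"
  stopifnot(inherits(panel, "genotype_panel"))
  if (format == "vcf") {
    gt <- matrix("./.", n_markers(panel), n_lines(panel))
    d <- t(panel$dosage)
    gt[!is.na(d) & d == 0] <- "0/0"
    gt[!is.na(d) & d == 2] <- "1/1"
    body <- cbind(panel$map$chrom, as.integer(panel$map$pos),
                  panel$map$marker_id, panel$map$ref, panel$map$alt,
                  ".", "PASS", ".", "GT", gt)
    lines <- c(
      "##fileformat=VCFv4.2",
      "##source=starchgwas",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", panel$line_ids), collapse = "\t"),
      apply(body, 1, paste, collapse = "\t")
    )
    writeLines(lines, path)
  } else {
    dt <- data.table::data.table(
      chrom = panel$map$chrom, pos = as.integer(panel$map$pos),
      ref = panel$map$ref, alt = panel$map$alt)
    dt <- cbind(dt, data.table::as.data.table(t(panel$dosage)))
    data.table::setnames(dt, c("chrom", "pos", "ref", "alt", panel$line_ids))
    data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(path)
}

#' Read a replicate-level phenotype table
#'
#' Expects a TSV with a `line_id` column, an optional `rep_id` column, and
#' one numeric column per trait.
#'
#' @param path input TSV.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Apply the marker quality-control filters
#'
#' Retains markers with MAF strictly above `maf_min` (computed on
#' non-missing calls) and missing-call fraction strictly below
#' `missing_max`; both bounds read literally as exclusive ("above 2%",
#' "below 20%").
#'
#' @param panel a [genotype_panel()].
#' @param maf_min MAF threshold (default 0.02).
#' @param missing_max missing-rate threshold (default 0.20).
#' @return list with `panel` (filtered) and `report`, a one-row data.frame
#'   with `n_input_markers`, `n_failed_maf`, `n_failed_missing`,
#'   `n_retained` (markers failing both filters are counted in both
#'   `n_failed_*` columns but removed once).
#' @export
filter_markers <- function(panel, maf_min = 0.02, missing_max = 0.20) {
  stopifnot(maf_min >= 0, maf_min <= 1, missing_max >= 0, missing_max <= 1)
  miss <- colMeans(is.na(panel$dosage))
  fail_maf <- !(panel$maf > maf_min)
  fail_miss <- !(miss < missing_max)
  keep <- !(fail_maf | fail_miss)
  report <- data.frame(
    n_input_markers = n_markers(panel),
    n_failed_maf = sum(fail_maf),
    n_failed_missing = sum(fail_miss),
    n_retained = sum(keep)
  )
  if (!any(keep)) {
    warning("all markers removed by QC filters; returning an empty panel")
    out <- panel
    out$map <- panel$map[keep, , drop = FALSE]
    out$dosage <- panel$dosage[, keep, drop = FALSE]
    out$maf <- panel$maf[keep]
    return(list(panel = out, report = report))
  }
  out <- genotype_panel(panel$dosage[, keep, drop = FALSE],
                        panel$map[keep, c("chrom", "pos", "ref", "alt")],
                        line_ids = panel$line_ids)
  list(panel = out, report = report)
}

#' Mean-impute missing dosage calls
#'
#' Replaces each missing call with the marker's mean dosage over observed
#' calls (so the marker mean is preserved). The association engines require
#' a complete matrix; mean imputation is deliberately isolated here so an
#' alternative scheme can be swapped in.
#'
#' @param panel a [genotype_panel()].
#' @return A `genotype_panel` with no missing entries. The dosage matrix may
#'   contain fractional values after imputation; `maf` is recomputed from
#'   the imputed dosages.
#' @export
impute_missing <- function(panel) {
  d <- panel$dosage
  nmiss <- colSums(is.na(d))
  if (!any(nmiss > 0)) return(panel)
  allmiss <- which(nmiss == nrow(d))
  if (length(allmiss)) {
    stop(sprintf("marker(s) with all calls missing: %s",
                 paste(panel$map$marker_id[allmiss], collapse = ", ")))
  }
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  out <- panel
  out$dosage <- d
  out$maf <- {
    p <- colMeans(d) / 2
    pmin(p, 1 - p)
  }
  class(out) <- class(panel)
  out
}
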