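#' Call QTNs across traits and methods
#'
#' Collects the significant rows of any number of association results (one
#' per method/trait combination) into one call per (trait, marker), keeping
#' each detecting method's effect and variance fraction, and flags
#' pleiotropic markers (the same marker called for two or more traits).
#'
#' @param results a single `association_result`, or a list of them.
#' @return data.frame of class `qtn_calls`: `trait`, `marker_id`, `chrom`,
#'   `pos`, `alleles`, `methods_detected` (comma-separated), `n_methods`,
#'   `effects` / `pves` (comma-separated, same order as the methods),
#'   `sign_consistent`, `pleiotropic`.
#' @export
call_qtns <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  all_res <- do.call(rbind, lapply(results, as.data.frame))
  if (is.null(all_res) || !nrow(all_res)) {
    return(empty_qtn_calls())
  }
  chk <- unique(all_res[, c("marker_id", "chrom", "pos")])
  if (anyDuplicated(chk$marker_id)) {
    stop("inconsistent marker maps across methods: same marker_id, different coordinates")
  }
  sig <- all_res[all_res$significant, , drop = FALSE]
  if (!nrow(sig)) return(empty_qtn_calls())
  sig <- sig[order(sig$trait, sig$chrom, sig$pos, sig$method), , drop = FALSE]
  key <- paste(sig$trait, sig$marker_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(sig)), key), function(ii) {
    s <- sig[ii, , drop = FALSE]
    ef <- s$effect
    data.frame(
      trait = s$trait[1], marker_id = s$marker_id[1], chrom = s$chrom[1],
      pos = s$pos[1], alleles = s$alleles[1],
      methods_detected = paste(s$method, collapse = ","),
      n_methods = nrow(s),
      effects = paste(signif(ef, 6), collapse = ","),
      pves = paste(signif(s$pve, 6), collapse = ","),
      sign_consistent = length(unique(sign(ef[ef != 0]))) <= 1
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$trait, out$chrom, out$pos), , drop = FALSE]
  dup <- table(out$marker_id)
  out$pleiotropic <- out$marker_id %in% names(dup[dup >= 2])
  rownames(out) <- NULL
  class(out) <- c("qtn_calls", "data.frame")
  out
}

empty_qtn_calls <- function() {
  out <- data.frame(trait = character(0), marker_id = character(0),
                    chrom = integer(0), pos = numeric(0),
                    alleles = character(0), methods_detected = character(0),
                    n_methods = integer(0), effects = character(0),
                    pves = character(0), sign_consistent = logical(0),
                    pleiotropic = logical(0))
  class(out) <- c("qtn_calls", "data.frame")
  out
}

#' Cross-method overlap summary
#'
#' Counts calls per method, tabulates co-detection (markers called by two
#' or more methods for the same trait), and reports whether the effect
#' signs of co-detected QTNs agree across methods.
#'
#' @param calls a `qtn_calls` data.frame from [call_qtns()].
#' @return list with `per_method_counts` (named integer vector),
#'   `co_detected` (subset of `calls` with `n_methods >= 2`), and
#'   `n_sign_inconsistent`.
#' @export
cross_method_overlap <- function(calls) {
  methods <- unlist(strsplit(calls$methods_detected, ","))
  per_method <- if (length(methods)) table(methods) else table(character(0))
  co <- calls[calls$n_methods >= 2, , drop = FALSE]
  list(per_method_counts = c(per_method),
       co_detected = co,
       n_sign_inconsistent = sum(!co$sign_consistent))
}

#' Candidate genes around called QTNs
#'
#' Annotates each QTN call with the genes whose span intersects the closed
#' interval \[pos - window, pos + window\] on the QTN's chromosome
#' (GFF3 coordinates are 1-based inclusive). Genes are sorted by distance
#' from the QTN (zero when the gene spans the QTN itself).
#'
#' @param calls a `qtn_calls` data.frame.
#' @param gff3_path path to a GFF3 annotation.
#' @param window half-width of the search window in bp (default 250 kb,
#'   i.e. 250 kb downstream and upstream).
#' @param feature_type GFF3 feature type(s) to use (default `"gene"`).
#' @return data.frame with one row per (QTN, gene): `trait`, `marker_id`,
#'   `chrom`, `pos`, `gene_id`, `gene_start`, `gene_end`, `distance`.
#' @export
candidate_genes <- function(calls, gff3_path, window = 250000,
                            feature_type = "gene") {
  gff <- tryCatch(rtracklayer::import(gff3_path, format = "gff3"),
                  error = function(e) {
                    stop(sprintf("failed to parse GFF3 '%s': %s", gff3_path,
                                 conditionMessage(e)))
                  })
  gff <- gff[as.character(gff$type) %in% feature_type]
  ids <- gff$ID
  if (is.null(ids)) ids <- gff$Name
  if (is.null(ids)) ids <- as.character(seq_along(gff))
  ids[is.na(ids)] <- as.character(which(is.na(ids)))
  gchrom <- sub("^[Cc]hr", "", as.character(GenomicRanges::seqnames(gff)))
  gstart <- GenomicRanges::start(gff)
  gend <- GenomicRanges::end(gff)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    ch <- as.character(calls$chrom[i])
    pos <- calls$pos[i]
    sel <- which(gchrom == ch & gstart <= pos + window & gend >= pos - window)
    if (!length(sel)) return(NULL)
    distance <- pmax(pmax(gstart[sel] - pos, pos - gend[sel]), 0)
    ord <- order(distance, gstart[sel])
    data.frame(trait = calls$trait[i], marker_id = calls$marker_id[i],
               chrom = calls$chrom[i], pos = pos,
               gene_id = ids[sel][ord],
               gene_start = gstart[sel][ord], gene_end = gend[sel][ord],
               distance = distance[ord])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(trait = character(0), marker_id = character(0),
                      chrom = integer(0), pos = numeric(0),
                      gene_id = character(0), gene_start = integer(0),
                      gene_end = integer(0), distance = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Write association results or QTN calls to TSV
#'
#' @param x an `association_result` or `qtn_calls` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t")
  invisible(path)
}
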