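#' Per-SNP absolute allele-frequency difference
#'
#' `delta_af = |af_target - af_control|` per SNP, from an allele-frequency
#' table produced by [allele_frequencies()]. SNPs with an undefined frequency
#' in either population are skipped (count recorded in attribute
#' `n_skipped`).
#'
#' @param af_table data.frame from [allele_frequencies()].
#' @param target,control population labels.
#' @return data.frame: `chrom`, `pos`, `af_target`, `af_control`,
#'   `delta_af`.
#' @export
compute_delta_af <- function(af_table, target, control) {
  tcol <- paste0("af_", target)
  ccol <- paste0("af_", control)
  for (col in c(tcol, ccol)) {
    if (!col %in% names(af_table)) {
      stop("population not in AF table: ", sub("^af_", "", col))
    }
  }
  ok <- !is.na(af_table[[tcol]]) & !is.na(af_table[[ccol]])
  out <- data.frame(
    chrom = af_table$chrom[ok],
    pos = af_table$pos[ok],
    af_target = af_table[[tcol]][ok],
    af_control = af_table[[ccol]][ok],
    stringsAsFactors = FALSE
  )
  out$delta_af <- abs(out$af_target - out$af_control)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Population-specific near-fixation screen
#'
#' A SNP passes iff `af_target > hi` and `af_control < lo` (strict
#' inequalities; defaults mirror the "> 80% and < 20%" rule). The minimum
#' attainable delta_af of a passing SNP is therefore strictly > hi - lo.
#'
#' @param records data.frame from [compute_delta_af()].
#' @param hi lower bound (exclusive) on the target frequency (default 0.80).
#' @param lo upper bound (exclusive) on the control frequency (default
#'   0.20).
#' @return `records` with a logical `passes_screen` column.
#' @export
population_specific_screen <- function(records, hi = 0.80, lo = 0.20) {
  records$passes_screen <- records$af_target > hi & records$af_control < lo
  records
}

#' Assign screened SNPs to genes
#'
#' A SNP is assigned to every gene whose flanked span
#' (`start - updown_bp` .. `end + updown_bp`) contains it.
#'
#' @param snps data.frame with `chrom`, `pos`.
#' @param genes list of gene models from [load_gff()] (or a data.frame with
#'   `gene_id`, `chrom`, `start`, `end`).
#' @param updown_bp flank added on both sides (default 1000).
#' @return data.frame `gene_id`, `chrom`, `pos` (one row per assignment).
#' @export
snps_to_genes <- function(snps, genes, updown_bp = 1000) {
  gtab <- gene_table(genes)
  res <- lapply(unique(snps$chrom), function(ch) {
    s <- snps[snps$chrom == ch, , drop = FALSE]
    g <- gtab[gtab$chrom == ch, , drop = FALSE]
    if (!nrow(s) || !nrow(g)) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = s$pos, width = 1),
      IRanges::IRanges(start = pmax(1L, g$start - updown_bp),
                       end = g$end + updown_bp)
    )
    if (!length(hits)) return(NULL)
    data.frame(
      gene_id = g$gene_id[S4Vectors::subjectHits(hits)],
      chrom = ch,
      pos = s$pos[S4Vectors::queryHits(hits)],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      pos = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Normalize gene input (list of gene models or plain data.frame) to a table
# of gene spans.
gene_table <- function(genes) {
  if (is.data.frame(genes)) {
    stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
    return(genes)
  }
  do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom,
               start = g$start, end = g$end, stringsAsFactors = FALSE)
  }))
}
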