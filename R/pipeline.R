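#' Run the full selection-scan pipeline
#'
#' Orchestrates the stages in dependency order — hard filters, cohort QC,
#' allele frequencies, windowed Fst / theta-pi-ratio scan, joint top-quantile
#' outlier intersection, region merging, the delta-AF near-fixation screen,
#' and (when gene models are given) region-gene mapping and gene-set
#' enrichment — writing every stage's table plus a YAML manifest (parameters,
#' input checksums, stage counts) into `out_dir`.
#'
#' @param gm a `genotype_matrix` (parsed VCF), pre-filter.
#' @param popmap named character vector (sample -> population).
#' @param target target population label.
#' @param control control population label.
#' @param chrom_lengths named vector of chromosome lengths for windowing
#'   (defaults to the maximum observed position per chromosome).
#' @param out_dir output directory (created if absent).
#' @param genes optional gene models from [load_gff()].
#' @param gene_sets optional named list of gene sets (see [read_gmt()]).
#' @param window,step window and step size in bp.
#' @param min_snps minimum SNPs per window.
#' @param quantile joint outlier quantile.
#' @param maf_min,call_rate_min,max_missing QC thresholds.
#' @param hi,lo delta-AF screen bounds.
#' @param updown_bp gene-assignment flank in bp.
#' @param vcf_path optional path of the input VCF, recorded (with checksum)
#'   in the manifest.
#' @return Invisibly, a list with the stage outputs and a `counts` report.
#' @export
run_scan_pipeline <- function(gm, popmap, target, control,
                              chrom_lengths = NULL,
                              out_dir = tempfile("scan_run_"),
                              genes = NULL, gene_sets = NULL,
                              window = 100000, step = 10000, min_snps = 10,
                              quantile = 0.95, maf_min = 0.05,
                              call_rate_min = 0.90, max_missing = 0.20,
                              hi = 0.80, lo = 0.20, updown_bp = 1000,
                              vcf_path = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  check_popmap(gm, popmap, min_pops = 2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  counts <- list(sites_in = nrow(gm$sites))

  filtered <- apply_hard_filters(gm)
  tsv(attr(filtered, "removal_report"), "hard_filter_report.tsv")
  counts$sites_hard_filtered <- nrow(filtered$sites)

  filtered <- qc_filter(filtered, maf_min = maf_min,
                        call_rate_min = call_rate_min,
                        max_missing = max_missing)
  tsv(attr(filtered, "qc_report"), "qc_report.tsv")
  counts$sites_qc <- nrow(filtered$sites)
  if (counts$sites_qc == 0) stop("stage qc_filter: no sites left")

  af <- allele_frequencies(filtered, popmap)
  tsv(af, "allele_frequencies.tsv")

  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(filtered$sites$pos, filtered$sites$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }
  windows <- make_windows(chrom_lengths, size = window, step = step)
  stats_df <- windowed_stats(filtered, popmap, target, control, windows,
                             min_snps = min_snps)
  tsv(stats_df, "window_stats.tsv")
  counts$windows_scanned <- nrow(stats_df)

  if (quantile >= 1) {
    outliers <- stats_df[0, , drop = FALSE]
    thresholds <- c(fst = NA_real_, ratio = NA_real_)
  } else {
    sel <- select_outliers(stats_df, q = quantile)
    outliers <- sel$outliers
    thresholds <- c(fst = sel$fst_threshold, ratio = sel$ratio_threshold)
  }
  tsv(outliers, "outlier_windows.tsv")
  counts$outlier_windows <- nrow(outliers)

  regions <- merge_regions(outliers)
  tsv(regions, "candidate_regions.tsv")
  write_bed(regions, file.path(out_dir, "candidate_regions.bed"))
  counts$regions <- nrow(regions)

  daf <- compute_delta_af(af, target, control)
  daf <- population_specific_screen(daf, hi = hi, lo = lo)
  tsv(daf, "delta_af.tsv")
  counts$screen_snps <- sum(daf$passes_screen)

  region_genes <- NULL
  enrich <- NULL
  if (!is.null(genes)) {
    region_genes <- genes_in_regions(regions, genes)
    tsv(data.frame(gene_id = region_genes$genes), "region_genes.tsv")
    counts$region_genes <- length(region_genes$genes)
    gmap <- snps_to_genes(daf[daf$passes_screen, , drop = FALSE], genes,
                          updown_bp = updown_bp)
    tsv(gmap, "screen_snp_genes.tsv")
    if (!is.null(gene_sets) && length(region_genes$genes)) {
      enrich <- hypergeom_enrich(region_genes$genes, gene_sets,
                                 universe = names(genes))
      tsv(enrich, "enrichment.tsv")
    }
  }

  params <- list(target = target, control = control, window = window,
                 step = step, min_snps = min_snps, quantile = quantile,
                 maf_min = maf_min, call_rate_min = call_rate_min,
                 max_missing = max_missing, hi = hi, lo = lo,
                 updown_bp = updown_bp)
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest[.]yaml$", outputs)]
  manifest <- list(
    parameters = params,
    thresholds = as.list(thresholds),
    counts = counts,
    inputs = if (!is.null(vcf_path)) {
      list(vcf = vcf_path,
           md5 = unname(tools::md5sum(vcf_path)))
    } else list(),
    output_md5 = as.list(tools::md5sum(outputs))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(filtered = filtered, allele_freqs = af,
                 window_stats = stats_df, outliers = outliers,
                 thresholds = thresholds, regions = regions,
                 delta_af = daf, region_genes = region_genes,
                 enrichment = enrich, counts = counts, out_dir = out_dir))
}
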