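#' GATK-style per-site hard filters
#'
#' Keeps a site iff every *available* metric satisfies its bound:
#' QUAL > 30, QD > 5.0, FS < 60.0, MQ > 40.0, MQRankSum > -12.5,
#' ReadPosRankSum > -8.0. A metric absent from the record (NA) does not fail
#' the site, mirroring GATK's treatment of un-annotated sites. Bounds are
#' strict.
#'
#' @param gm a `genotype_matrix` (or a data.frame of sites with the metric
#'   columns).
#' @param thresholds named list overriding the default bounds.
#' @return For a `genotype_matrix`: the filtered matrix, with attribute
#'   `removal_report` (data.frame criterion/count; sites may count under
#'   several criteria). For a data.frame: a list with `kept` and `report`.
#' @export
apply_hard_filters <- function(gm,
                               thresholds = list(qual = 30, QD = 5.0,
                                                 FS = 60.0, MQ = 40.0,
                                                 MQRankSum = -12.5,
                                                 ReadPosRankSum = -8.0)) {
  is_gm <- inherits(gm, "genotype_matrix")
  sites <- if (is_gm) gm$sites else as.data.frame(gm)
  n <- nrow(sites)
  get <- function(col) {
    if (col %in% names(sites)) sites[[col]] else rep(NA_real_, n)
  }
  # fail = metric present AND violating its bound
  fails <- cbind(
    QUAL = !is.na(get("qual")) & get("qual") <= thresholds$qual,
    QD = !is.na(get("QD")) & get("QD") <= thresholds$QD,
    FS = !is.na(get("FS")) & get("FS") >= thresholds$FS,
    MQ = !is.na(get("MQ")) & get("MQ") <= thresholds$MQ,
    MQRankSum = !is.na(get("MQRankSum")) & get("MQRankSum") <= thresholds$MQRankSum,
    ReadPosRankSum = !is.na(get("ReadPosRankSum")) &
      get("ReadPosRankSum") <= thresholds$ReadPosRankSum
  )
  keep <- rowSums(fails) == 0
  report <- data.frame(criterion = colnames(fails),
                       count = colSums(fails),
                       row.names = NULL)
  if (!is_gm) {
    return(list(kept = sites[keep, , drop = FALSE], report = report))
  }
  out <- subset_genotypes(gm, sites = which(keep))
  attr(out, "removal_report") <- report
  out
}

#' Cohort-level QC filter
#'
#' Removes sites with pooled minor allele frequency below `maf_min`
#' (strictly: MAF = `maf_min` is kept), call rate below `call_rate_min`,
#' or missing-genotype fraction above `max_missing`. MAF is computed over all
#' samples pooled; site order is preserved. Idempotent.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min minimum pooled minor allele frequency (default 0.05).
#' @param call_rate_min minimum fraction of called genotypes (default 0.90).
#' @param max_missing maximum fraction of missing genotypes (default 0.20).
#' @return Filtered `genotype_matrix` with attribute `qc_report`.
#' @export
qc_filter <- function(gm, maf_min = 0.05, call_rate_min = 0.90,
                      max_missing = 0.20) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$sites) > 0)
  d <- gm$dosage
  n_called <- rowSums(!is.na(d))
  n <- ncol(d)
  call_rate <- n_called / n
  miss_rate <- 1 - call_rate
  ac <- rowSums(d, na.rm = TRUE)
  af <- ifelse(n_called > 0, ac / (2 * n_called), NA_real_)
  maf <- pmin(af, 1 - af)

  fail_maf <- is.na(maf) | maf < maf_min
  fail_call <- call_rate < call_rate_min
  fail_miss <- miss_rate > max_missing
  keep <- !(fail_maf | fail_call | fail_miss)
  report <- data.frame(
    criterion = c("MAF", "call_rate", "missing_rate"),
    count = c(sum(fail_maf), sum(fail_call), sum(fail_miss))
  )
  if (!any(keep)) {
    warning("qc_filter removed all sites")
    out <- gm
    out$sites <- gm$sites[0, , drop = FALSE]
    out$dosage <- gm$dosage[0, , drop = FALSE]
  } else {
    out <- subset_genotypes(gm, sites = which(keep))
  }
  attr(out, "qc_report") <- report
  out
}
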