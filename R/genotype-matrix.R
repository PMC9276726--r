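#' Construct a genotype matrix
#'
#' The central container for all downstream statistics: a sites x samples
#' matrix of alternate-allele dosages (0, 1, 2 or `NA` for a missing call)
#' together with per-site metadata.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `qual`, `QD`, `FS`, `MQ`, `MQRankSum`,
#'   `ReadPosRankSum`.
#' @param dosage integer matrix, `nrow(sites)` x `length(samples)`;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples character vector of sample identifiers (column order of
#'   `dosage`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, dosage, samples) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    is.matrix(dosage),
    nrow(dosage) == nrow(sites),
    ncol(dosage) == length(samples)
  )
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("dosages must be 0, 1, 2 or NA")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosage <- dosage[ord, , drop = FALSE]
  if (anyDuplicated(sites[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) sites")
  }
  rownames(sites) <- NULL
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(NULL, samples)
  structure(
    list(sites = sites, dosage = dosage, samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d sites x %d samples (%d chromosome%s)\n",
    nrow(x$sites), length(x$samples),
    length(unique(x$sites$chrom)),
    if (length(unique(x$sites$chrom)) == 1) "" else "s"
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by site index and/or sample names
#'
#' @param gm a `genotype_matrix`.
#' @param sites integer or logical index into rows.
#' @param samples character vector of sample names to keep.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, sites = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- if (is.null(sites)) seq_len(nrow(gm$sites)) else sites
  sa <- if (is.null(samples)) gm$samples else samples
  missing <- setdiff(sa, gm$samples)
  if (length(missing)) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "))
  }
  genotype_matrix(gm$sites[si, , drop = FALSE],
                  gm$dosage[si, match(sa, gm$samples), drop = FALSE],
                  sa)
}

#' Read a population map
#'
#' Two-column TSV (`sample<TAB>population`, no header) assigning every sample
#' to one population label.
#'
#' @param path path to the TSV file.
#' @return Named character vector: `names` are samples, values population
#'   labels.
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "population"),
                          colClasses = "character")
  if (anyDuplicated(df$sample)) stop("duplicate sample in population map")
  stats::setNames(df$population, df$sample)
}

#' Write a population map
#'
#' @param popmap named character vector (sample -> population).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(
    data.frame(sample = names(popmap), population = unname(popmap)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Check that every matrix sample carries a label; >= 2 labels needed for any
# pairwise statistic.
check_popmap <- function(gm, popmap, min_pops = 1) {
  unlabeled <- setdiff(gm$samples, names(popmap))
  if (length(unlabeled)) {
    stop("samples without population label: ",
         paste(unlabeled, collapse = ", "))
  }
  labs <- unique(unname(popmap[gm$samples]))
  if (length(labs) < min_pops) {
    stop("need at least ", min_pops, " distinct population labels")
  }
  invisible(popmap[gm$samples])
}
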