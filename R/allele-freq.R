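#' Per-population alternate-allele frequencies
#'
#' For every site and population: AltAF = (sum of dosages over called
#' samples) / (2 x called samples). Missing genotypes drop out of both
#' numerator and denominator; a population with zero called samples at a
#' site gets `NA` (flagged undefined).
#'
#' @param gm a `genotype_matrix`.
#' @param popmap named character vector (sample -> population); every matrix
#'   sample must be labeled.
#' @return data.frame with `chrom`, `pos`, then per population `af_<pop>`
#'   and `n_called_<pop>` (called *alleles*, i.e. 2 x called samples).
#' @export
allele_frequencies <- function(gm, popmap) {
  stopifnot(inherits(gm, "genotype_matrix"))
  labels <- check_popmap(gm, popmap)
  pops <- unique(unname(labels))
  out <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    stringsAsFactors = FALSE)
  for (p in pops) {
    d <- gm$dosage[, labels == p, drop = FALSE]
    n_called <- rowSums(!is.na(d))
    ac <- rowSums(d, na.rm = TRUE)
    out[[paste0("af_", p)]] <- ifelse(n_called > 0, ac / (2 * n_called),
                                      NA_real_)
    out[[paste0("n_called_", p)]] <- 2L * n_called
  }
  out
}

#' Summarize annotation category counts as percentages
#'
#' @param category_counts named numeric vector of non-negative counts.
#' @return data.frame (`category`, `count`, `percent`) with percent =
#'   100 * count / total rounded to 2 decimals, plus a `total` attribute.
#' @export
summarize_annotation_counts <- function(category_counts) {
  counts <- unlist(as.list(category_counts))  # accepts vector, list, table
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("category counts must be named")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  out <- data.frame(
    category = names(counts),
    count = unname(counts),
    percent = round(100 * unname(counts) / total, 2),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- total
  out
}
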