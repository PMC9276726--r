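#' Parse a VCF into a genotype matrix
#'
#' Reads a VCF (plain or gzipped) with vcfR, keeps biallelic SNP records only,
#' and converts diploid GT fields to alternate-allele dosages. Multiallelic
#' sites and non-SNP records (indels, symbolic alleles) are excluded and
#' counted. Missing genotypes (`./.` or `.`) become `NA`.
#'
#' @param path VCF file path.
#' @param sample_subset optional character vector restricting the samples
#'   (and column order) of the result.
#' @param verbose print the exclusion count via `message()`.
#' @return A `genotype_matrix` with attribute `excluded` giving the number of
#'   records dropped as multiallelic/non-SNP.
#' @export
parse_vcf <- function(path, sample_subset = NULL, verbose = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  gt <- v@gt
  samples <- colnames(gt)[-1]
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    if (length(missing)) {
      stop("samples not in VCF header: ", paste(missing, collapse = ", "))
    }
    samples <- sample_subset
  }

  nuc <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nuc & fix$ALT %in% nuc
  n_excluded <- sum(!keep)
  if (verbose && n_excluded > 0) {
    message(n_excluded, " multiallelic/non-SNP record(s) excluded")
  }
  if (!any(keep)) stop("no biallelic SNP records in ", path)

  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]

  gt_fields <- gt[, "FORMAT"]
  gt_idx <- vapply(strsplit(gt_fields, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) stop("VCF record without GT field")

  gtm <- gt[, samples, drop = FALSE]
  dos <- matrix(NA_integer_, nrow(gtm), ncol(gtm))
  # dosage lookup over normalized diploid GT strings; anything containing a
  # "." stays NA
  dosage_of <- function(g) {
    g[is.na(g)] <- "."         # vcfR reports missing calls as NA
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g == "0/1" | g == "1/0"] <- 1L
    out[g == "1/1"] <- 2L
    bad <- is.na(out) & !grepl(".", g, fixed = TRUE)
    if (any(bad)) stop("unsupported genotype string: ", g[bad][1])
    out
  }
  for (j in seq_len(ncol(gtm))) {
    cell <- gtm[, j]
    g <- character(length(cell))
    simple <- gt_idx == 1L
    g[simple] <- sub(":.*", "", cell[simple])
    if (any(!simple)) {
      g[!simple] <- vapply(which(!simple), function(i) {
        strsplit(cell[i], ":", fixed = TRUE)[[1]][gt_idx[i]]
      }, character(1))
    }
    dos[, j] <- dosage_of(g)
  }

  info <- fix$INFO
  info[is.na(info)] <- "."
  parse_info_num <- function(key) {
    out <- rep(NA_real_, length(info))
    hit <- regexpr(paste0("(^|;)", key, "=[^;]+"), info)
    val <- rep(NA_character_, length(info))
    ok <- hit > 0
    val[ok] <- sub(paste0(".*", key, "="), "", regmatches(info, hit))
    suppressWarnings(out[ok] <- as.numeric(val[ok]))
    out
  }

  sites <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    QD = parse_info_num("QD"),
    FS = parse_info_num("FS"),
    MQ = parse_info_num("MQ"),
    MQRankSum = parse_info_num("MQRankSum"),
    ReadPosRankSum = parse_info_num("ReadPosRankSum"),
    stringsAsFactors = FALSE
  )

  gm <- genotype_matrix(sites, dos, samples)
  attr(gm, "excluded") <- n_excluded
  gm
}

#' Write a genotype matrix to a VCF 4.2 file
#'
#' Emits a plain-text VCF with GT genotypes (`0/0`, `0/1`, `1/1`, `./.`),
#' site QUAL, and any available INFO metrics (QD, FS, MQ, MQRankSum,
#' ReadPosRankSum). Round-trips through [parse_vcf()].
#'
#' @param gm a `genotype_matrix`.
#' @param path output path (`.vcf`).
#' @param chrom_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, chrom_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  s <- gm$sites
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  ), con)
  if (!is.null(chrom_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>",
                       names(chrom_lengths), as.integer(chrom_lengths)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples), collapse = "\t"), con)

  fmt1 <- function(x) formatC(x, format = "g", digits = 6)
  info_keys <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  info_cols <- lapply(info_keys, function(k) {
    if (k %in% names(s)) s[[k]] else rep(NA_real_, nrow(s))
  })
  info_str <- vapply(seq_len(nrow(s)), function(i) {
    vals <- vapply(info_cols, function(col) col[i], numeric(1))
    ok <- !is.na(vals)
    if (!any(ok)) return(".")
    paste(paste0(info_keys[ok], "=", fmt1(vals[ok])), collapse = ";")
  }, character(1))

  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gts <- matrix("./.", nrow(gm$dosage), ncol(gm$dosage))
  idx <- !is.na(gm$dosage)
  gts[idx] <- gt_code[as.character(gm$dosage[idx])]

  qual <- if ("qual" %in% names(s)) {
    ifelse(is.na(s$qual), ".", fmt1(s$qual))
  } else rep(".", nrow(s))

  body <- paste(
    s$chrom, s$pos, ".", s$ref, s$alt, qual, "PASS", info_str, "GT",
    apply(gts, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(body, con)
  invisible(path)
}
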