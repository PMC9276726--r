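#' Load gene models from a GFF3 file
#'
#' Builds per-transcript gene models (exons, CDS, UTRs; 1-based inclusive
#' intervals) from `gene` / `mRNA` / `exon` / `CDS` / UTR features linked by
#' `ID`/`Parent` attributes.
#'
#' @param path GFF3 file path.
#' @return Named list of gene models sorted by (chrom, start). Each model:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, and `transcripts` (a named
#'   list with `tx_id`, `exons`, `cds`, `utr5`, `utr3` interval data.frames
#'   and optional `cds_seq`).
#' @export
load_gff <- function(path) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  attr_val <- function(attrs, key) {
    hit <- regexpr(paste0("(^|;)", key, "=[^;]+"), attrs)
    out <- rep(NA_character_, length(attrs))
    ok <- hit > 0
    out[ok] <- sub(paste0("^.*", key, "="), "", regmatches(attrs, hit))
    out
  }
  gff$ID <- attr_val(gff$attributes, "ID")
  gff$Parent <- attr_val(gff$attributes, "Parent")

  genes <- gff[gff$type == "gene", , drop = FALSE]
  txs <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  parts <- gff[gff$type %in% c("exon", "CDS", "five_prime_UTR",
                               "three_prime_UTR"), , drop = FALSE]

  orphan_tx <- setdiff(txs$Parent, genes$ID)
  if (length(orphan_tx)) {
    stop("transcript Parent not found: ", paste(orphan_tx, collapse = ", "))
  }
  orphan_part <- setdiff(parts$Parent, txs$ID)
  if (length(orphan_part)) {
    stop("feature Parent not found: ", paste(orphan_part, collapse = ", "))
  }

  iv <- function(df) {
    if (!nrow(df)) {
      return(data.frame(start = integer(), end = integer()))
    }
    out <- data.frame(start = df$start, end = df$end)
    out[order(out$start), , drop = FALSE]
  }
  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gtx <- txs[txs$Parent == g$ID, , drop = FALSE]
    tr <- lapply(seq_len(nrow(gtx)), function(j) {
      t <- gtx[j, ]
      p <- parts[parts$Parent == t$ID, , drop = FALSE]
      exons <- iv(p[p$type == "exon", , drop = FALSE])
      cds <- iv(p[p$type == "CDS", , drop = FALSE])
      if (nrow(cds)) {
        inside <- vapply(seq_len(nrow(cds)), function(k) {
          any(exons$start <= cds$start[k] & cds$end[k] <= exons$end)
        }, logical(1))
        if (!all(inside)) stop("CDS outside exon in transcript ", t$ID)
      }
      list(tx_id = t$ID,
           strand = as.character(t$strand),
           chrom = as.character(t$seqid),
           exons = exons,
           cds = cds,
           utr5 = iv(p[p$type == "five_prime_UTR", , drop = FALSE]),
           utr3 = iv(p[p$type == "three_prime_UTR", , drop = FALSE]),
           cds_seq = NULL)
    })
    names(tr) <- gtx$ID
    list(gene_id = g$ID,
         chrom = as.character(g$seqid),
         strand = as.character(g$strand),
         start = g$start, end = g$end,
         transcripts = tr)
  })
  names(models) <- genes$ID
  ord <- order(vapply(models, `[[`, character(1), "chrom"),
               vapply(models, `[[`, numeric(1), "start"))
  models[ord]
}

#' Attach spliced CDS sequences to gene models
#'
#' @param models gene models from [load_gff()].
#' @param fasta path to a FASTA of spliced CDS sequences keyed by transcript
#'   id (coding strand, ATG..stop).
#' @return The models with `cds_seq` filled in where a sequence is present.
#' @export
attach_cds_sequences <- function(models, fasta) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  nm <- sub("\\s.*", "", names(seqs))
  for (gi in seq_along(models)) {
    for (ti in seq_along(models[[gi]]$transcripts)) {
      id <- models[[gi]]$transcripts[[ti]]$tx_id
      k <- match(id, nm)
      if (!is.na(k)) {
        models[[gi]]$transcripts[[ti]]$cds_seq <- as.character(seqs[[k]])
      }
    }
  }
  models
}

# precedence ranks (smaller = higher precedence)
.cat_rank <- c(exonic = 1, splicing = 2, UTR5 = 3, UTR3 = 3,
               intronic = 4, upstream = 5, downstream = 5, intergenic = 6)

in_iv <- function(pos, iv) {
  nrow(iv) > 0 && any(iv$start <= pos & pos <= iv$end)
}

# category of one position against one transcript (NA if farther than the
# flank)
tx_category <- function(pos, tx, updown_bp, splice_bp) {
  span <- c(min(tx$exons$start), max(tx$exons$end))
  if (pos >= span[1] && pos <= span[2]) {
    if (in_iv(pos, tx$cds)) return("exonic")
    if (in_iv(pos, tx$exons)) {
      if (in_iv(pos, tx$utr5)) return("UTR5")
      if (in_iv(pos, tx$utr3)) return("UTR3")
      return("exonic")  # exon outside annotated CDS/UTR
    }
    # intronic; splice-site if within splice_bp of an exon edge
    d <- min(abs(pos - c(tx$exons$start, tx$exons$end)))
    if (d <= splice_bp) return("splicing")
    return("intronic")
  }
  # flanks, measured from transcript ends on the coding strand
  if (pos < span[1] && span[1] - pos <= updown_bp) {
    return(if (tx$strand == "+") "upstream" else "downstream")
  }
  if (pos > span[2] && pos - span[2] <= updown_bp) {
    return(if (tx$strand == "+") "downstream" else "upstream")
  }
  NA_character_
}

#' ANNOVAR-style functional category of a SNP
#'
#' Precedence: exonic > splicing > UTR5/UTR3 > intronic >
#' upstream/downstream > intergenic. A SNP that is UTR5 of one transcript
#' and UTR3 of another gets the combined label `"UTR5;UTR3"`; upstream of
#' one gene and downstream of another gives `"upstream/downstream"`.
#'
#' @param chrom,pos site coordinate (1-based).
#' @param genes gene models from [load_gff()].
#' @param updown_bp flank width for upstream/downstream (default 1000).
#' @param splice_bp intronic distance from an exon boundary that counts as
#'   splicing (default 2).
#' @return A single category string.
#' @export
classify_site <- function(chrom, pos, genes, updown_bp = 1000,
                          splice_bp = 2) {
  cats <- character(0)
  for (g in genes) {
    if (g$chrom != chrom) next
    if (pos < g$start - updown_bp || pos > g$end + updown_bp) next
    for (tx in g$transcripts) {
      cc <- tx_category(pos, tx, updown_bp, splice_bp)
      if (!is.na(cc)) cats <- c(cats, cc)
    }
  }
  if (!length(cats)) return("intergenic")
  best <- min(.cat_rank[cats])
  top <- unique(cats[.cat_rank[cats] == best])
  if (best == 3 && all(c("UTR5", "UTR3") %in% top)) return("UTR5;UTR3")
  if (best == 5 && all(c("upstream", "downstream") %in% top)) {
    return("upstream/downstream")
  }
  top[1]
}

#' Classify many SNPs
#'
#' @param sites data.frame with `chrom`, `pos`.
#' @inheritParams classify_site
#' @return Character vector of categories, one per row of `sites`.
#' @export
classify_sites <- function(sites, genes, updown_bp = 1000, splice_bp = 2) {
  vapply(seq_len(nrow(sites)), function(i) {
    classify_site(sites$chrom[i], sites$pos[i], genes, updown_bp, splice_bp)
  }, character(1))
}

# 1-based CDS offset of a genomic position within a transcript's CDS, on the
# coding strand; NA if the position is not in the CDS.
cds_offset <- function(pos, tx) {
  cds <- tx$cds
  if (!nrow(cds)) return(NA_integer_)
  lens <- cds$end - cds$start + 1
  k <- which(cds$start <= pos & pos <= cds$end)
  if (!length(k)) return(NA_integer_)
  if (tx$strand == "+") {
    before <- if (k > 1) sum(lens[seq_len(k - 1)]) else 0
    before + (pos - cds$start[k]) + 1L
  } else {
    after <- if (k < nrow(cds)) sum(lens[(k + 1):nrow(cds)]) else 0
    after + (cds$end[k] - pos) + 1L
  }
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Coding effect of a SNP within a CDS
#'
#' Translates the affected codon with the reference vs alternate base
#' (reverse-complemented for minus-strand transcripts) under the standard
#' nuclear genetic code.
#'
#' @param chrom,pos,ref,alt the variant (genomic coordinates and alleles).
#' @param tx a transcript entry of a gene model, with `cds` intervals and
#'   `cds_seq`.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stopgain"`,
#'   `"stoploss"`, `"unknown"` (incomplete codon or reference
#'   inconsistency).
#' @export
coding_effect <- function(chrom, pos, ref, alt, tx) {
  if (is.null(tx$cds_seq)) stop("transcript has no CDS sequence")
  off <- cds_offset(pos, tx)
  if (is.na(off)) stop("position not in CDS of transcript ", tx$tx_id)
  seq <- strsplit(tx$cds_seq, "")[[1]]
  ref_c <- if (tx$strand == "+") ref else .complement[[ref]]
  alt_c <- if (tx$strand == "+") alt else .complement[[alt]]
  if (off > length(seq) || seq[off] != ref_c) return("unknown")
  codon_i <- (off - 1) %/% 3
  cstart <- codon_i * 3 + 1
  if (cstart + 2 > length(seq)) return("unknown")
  ref_codon <- paste(seq[cstart:(cstart + 2)], collapse = "")
  seq[off] <- alt_c
  alt_codon <- paste(seq[cstart:(cstart + 2)], collapse = "")
  code <- Biostrings::GENETIC_CODE
  ref_aa <- code[[ref_codon]]
  alt_aa <- code[[alt_codon]]
  if (ref_aa == alt_aa) return("synonymous")
  if (ref_aa != "*" && alt_aa == "*") return("stopgain")
  if (ref_aa == "*" && alt_aa != "*") return("stoploss")
  "nonsynonymous"
}

#' Genes overlapping candidate regions
#'
#' A gene overlaps a region iff their 1-based inclusive intervals intersect.
#'
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @param genes gene models (list) or gene span data.frame.
#' @return list: `per_region` (list of gene-id vectors, one per region row)
#'   and `genes` (de-duplicated union).
#' @export
genes_in_regions <- function(regions, genes) {
  gtab <- gene_table(genes)
  per <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    hit <- gtab$chrom == r$chrom & gtab$start <= r$end & gtab$end >= r$start
    gtab$gene_id[hit]
  })
  list(per_region = per, genes = unique(unlist(per)))
}

#' Venn-style intersection of named gene lists
#'
#' @param lists named list (>= 2) of character vectors of gene ids.
#' @return list: `membership` (data.frame gene x list logicals) and `cells`
#'   (named counts for every non-empty combination, names like `"A&B"` for
#'   genes in exactly A and B).
#' @export
intersect_gene_lists <- function(lists) {
  stopifnot(length(lists) >= 2, !is.null(names(lists)))
  genes <- sort(unique(unlist(lists)))
  mem <- as.data.frame(
    lapply(lists, function(l) genes %in% l),
    row.names = genes, optional = TRUE
  )
  names(mem) <- names(lists)
  k <- length(lists)
  cells <- numeric(0)
  for (m in 1:(2^k - 1)) {
    inc <- as.logical(bitwAnd(m, 2^(seq_len(k) - 1)))
    in_cell <- rowSums(as.matrix(mem[, inc, drop = FALSE])) == sum(inc) &
      rowSums(as.matrix(mem[, !inc, drop = FALSE])) == 0
    cells[paste(names(lists)[inc], collapse = "&")] <- sum(in_cell)
  }
  list(membership = mem, cells = cells)
}
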