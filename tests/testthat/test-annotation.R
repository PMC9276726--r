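# A hand-built two-exon plus-strand gene for classification cases:
# exon1 1001-1400, intron 1401-2400, exon2 2401-3200
# UTR5 1001-1200, CDS 1201-1400 + 2401-2900 (the CDS has length 700 here
# only for interval tests; sequence-level tests use simulated genes)
plus_gene <- function() {
  list(gene_id = "g1", chrom = "1", strand = "+", start = 1001, end = 3200,
       transcripts = list(t1 = list(
         tx_id = "t1", strand = "+", chrom = "1",
         exons = data.frame(start = c(1001, 2401), end = c(1400, 3200)),
         cds = data.frame(start = c(1201, 2401), end = c(1400, 2900)),
         utr5 = data.frame(start = 1001, end = 1200),
         utr3 = data.frame(start = 2901, end = 3200),
         cds_seq = NULL
       )))
}

test_that("site classification follows the precedence hierarchy", {
  genes <- list(g1 = plus_gene())
  expect_equal(classify_site("1", 1300, genes), "exonic")
  expect_equal(classify_site("1", 1100, genes), "UTR5")
  expect_equal(classify_site("1", 3000, genes), "UTR3")
  expect_equal(classify_site("1", 1402, genes), "splicing")  # 2 bp into intron
  expect_equal(classify_site("1", 1900, genes), "intronic")  # mid-intron
  expect_equal(classify_site("1", 500, genes), "upstream")   # 501 bp 5' of TSS
  expect_equal(classify_site("1", 3500, genes), "downstream")
  expect_equal(classify_site("1", 5000, genes), "intergenic")
  expect_equal(classify_site("2", 1300, genes), "intergenic")
})

test_that("flank direction tracks the coding strand", {
  g <- plus_gene()
  g$strand <- "-"
  g$transcripts$t1$strand <- "-"
  genes <- list(g1 = g)
  expect_equal(classify_site("1", 500, genes), "downstream")
  expect_equal(classify_site("1", 3500, genes), "upstream")
})

test_that("combined categories arise from conflicting gene contexts", {
  g2 <- plus_gene()
  g2$gene_id <- "g2"
  # shift g2 so that position 3500 is upstream of g2 but downstream of g1
  shift <- 3000
  g2$start <- g2$start + shift
  g2$end <- g2$end + shift
  g2$transcripts$t1$tx_id <- "t2"
  for (f in c("exons", "cds", "utr5", "utr3")) {
    g2$transcripts$t1[[f]]$start <- g2$transcripts$t1[[f]]$start + shift
    g2$transcripts$t1[[f]]$end <- g2$transcripts$t1[[f]]$end + shift
  }
  genes <- list(g1 = plus_gene(), g2 = g2)
  expect_equal(classify_site("1", 3500, genes), "upstream/downstream")

  # UTR5 of one transcript, UTR3 of the other
  g3 <- plus_gene()
  g3$gene_id <- "g3"
  g3$transcripts$t1$tx_id <- "t3"
  g3$transcripts$t1$utr3 <- data.frame(start = 1001, end = 1200)
  g3$transcripts$t1$utr5 <- data.frame(start = 2901, end = 3200)
  genes2 <- list(g1 = plus_gene(), g3 = g3)
  expect_equal(classify_site("1", 1100, genes2), "UTR5;UTR3")
})

test_that("every SNP gets exactly one category and counts partition the total", {
  set.seed(41)
  sim <- simulate_gene_models(c("1" = 3e5), n_genes = 20, seed = 41)
  pos <- sort(sample.int(3e5, 400))
  cats <- classify_sites(data.frame(chrom = "1", pos = pos), sim$models)
  expect_equal(length(cats), 400)
  expect_false(any(is.na(cats)))
  summ <- summarize_annotation_counts(table(cats))
  expect_equal(sum(summ$count), 400)
})

test_that("GFF3 written by the simulator reloads to identical gene models", {
  sim <- simulate_gene_models(c("1" = 2e5, "2" = 2e5), n_genes = 12,
                              seed = 7)
  path <- tempfile(fileext = ".gff3")
  write_gff3(sim$models, path)
  back <- load_gff(path)
  expect_equal(length(back), 12)
  expect_equal(names(back), names(sim$models))
  for (id in names(back)) {
    expect_equal(back[[id]]$chrom, sim$models[[id]]$chrom)
    expect_equal(back[[id]]$strand, sim$models[[id]]$strand)
    tx_b <- back[[id]]$transcripts[[1]]
    tx_s <- sim$models[[id]]$transcripts[[1]]
    expect_equal(tx_b$exons, tx_s$exons)
    expect_equal(tx_b$cds, tx_s$cds)
    expect_equal(tx_b$utr5, tx_s$utr5)
    expect_equal(tx_b$utr3, tx_s$utr3)
  }
  # CDS sequences reattach from the FASTA by transcript id
  fpath <- tempfile(fileext = ".fasta")
  write_fasta(sim$cds_seqs, fpath)
  with_seq <- attach_cds_sequences(back, fpath)
  expect_equal(with_seq[[1]]$transcripts[[1]]$cds_seq,
               sim$models[[1]]$transcripts[[1]]$cds_seq)
})

test_that("load_gff rejects orphan Parent references and CDS outside exons", {
  lines <- c(
    "##gff-version 3",
    "1\tx\tgene\t100\t500\t.\t+\t.\tID=gA",
    "1\tx\tmRNA\t100\t500\t.\t+\t.\tID=tA;Parent=gB"
  )
  p <- tempfile(fileext = ".gff3")
  writeLines(lines, p)
  expect_error(load_gff(p), "gB")

  lines2 <- c(
    "##gff-version 3",
    "1\tx\tgene\t100\t500\t.\t+\t.\tID=gA",
    "1\tx\tmRNA\t100\t500\t.\t+\t.\tID=tA;Parent=gA",
    "1\tx\texon\t100\t200\t.\t+\t.\tID=e1;Parent=tA",
    "1\tx\tCDS\t150\t300\t.\t+\t0\tID=c1;Parent=tA"
  )
  p2 <- tempfile(fileext = ".gff3")
  writeLines(lines2, p2)
  expect_error(load_gff(p2), "CDS outside exon")
})

test_that("coding effect matches codon-table expectations", {
  # + strand single-exon CDS: ATG GCT TGG TAA at 101..112
  tx <- list(tx_id = "t", strand = "+", chrom = "1",
             cds = data.frame(start = 101, end = 112),
             cds_seq = "ATGGCTTGGTAA")
  # GCT -> GCC : Ala -> Ala
  expect_equal(coding_effect("1", 106, "T", "C", tx), "synonymous")
  # GCT -> GTT : Ala -> Val
  expect_equal(coding_effect("1", 105, "C", "T", tx), "nonsynonymous")
  # TGG -> TGA : Trp -> stop
  expect_equal(coding_effect("1", 109, "G", "A", tx), "stopgain")
  # TAA -> CAA : stop -> Gln
  expect_equal(coding_effect("1", 110, "T", "C", tx), "stoploss")
  # inconsistent reference base
  expect_equal(coding_effect("1", 106, "A", "C", tx), "unknown")
  expect_error(coding_effect("1", 300, "A", "C", tx), "not in CDS")
})

test_that("coding effect is invariant under strand re-encoding", {
  # same CDS encoded on the minus strand: genomic sequence is the reverse
  # complement, so the genomic ref/alt bases complement and coordinates
  # mirror, but the codon-level effect is unchanged
  cds_seq <- "ATGGCTTGGTAA"
  plus <- list(tx_id = "p", strand = "+", chrom = "1",
               cds = data.frame(start = 101, end = 112), cds_seq = cds_seq)
  minus <- list(tx_id = "m", strand = "-", chrom = "1",
                cds = data.frame(start = 101, end = 112), cds_seq = cds_seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (off in 1:12) {
    base <- substr(cds_seq, off, off)
    for (alt in setdiff(c("A", "C", "G", "T"), base)) {
      eff_p <- coding_effect("1", 100 + off, base, alt, plus)
      # mirrored coordinate on the minus strand: CDS offset off maps to
      # genomic position 112 - off + 1; alleles complement
      eff_m <- coding_effect("1", 113 - off, comp[[base]], comp[[alt]],
                             minus)
      expect_equal(eff_m, eff_p, info = sprintf("off=%d alt=%s", off, alt))
    }
  }
})

test_that("coding effect agrees with the whole-CDS translation-diff oracle", {
  set.seed(43)
  sim <- simulate_gene_models(c("1" = 1.5e6), n_genes = 60, seed = 43)
  checks <- 0
  for (g in sim$models) {
    tx <- g$transcripts[[1]]
    seq <- strsplit(tx$cds_seq, "")[[1]]
    for (rep in 1:4) {
      off <- sample(length(seq), 1)
      ref_cds <- seq[off]
      alt_cds <- sample(setdiff(c("A", "C", "G", "T"), ref_cds), 1)
      # genomic position of CDS offset `off`
      cds_pos <- unlist(lapply(seq_len(nrow(tx$cds)),
                               function(i) tx$cds$start[i]:tx$cds$end[i]))
      gpos <- if (tx$strand == "+") cds_pos[off] else rev(cds_pos)[off]
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ref_g <- if (tx$strand == "+") ref_cds else comp[[ref_cds]]
      alt_g <- if (tx$strand == "+") alt_cds else comp[[alt_cds]]
      got <- coding_effect(g$chrom, gpos, ref_g, alt_g, tx)
      want <- translation_diff_oracle(tx$cds_seq, off, alt_cds)
      expect_equal(got, want,
                   info = sprintf("%s off=%d", tx$tx_id, off))
      checks <- checks + 1
    }
  }
  expect_equal(checks, 240)
})

test_that("gene-region overlap uses inclusive bounds and de-duplicates the union", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                      start = c(50000L, 110001L), end = c(60000L, 120000L))
  regions <- data.frame(chrom = "1", start = c(1L, 100001L),
                        end = c(110000L, 130000L))
  res <- genes_in_regions(regions, genes)
  expect_equal(res$per_region[[1]], "gA")          # gB starts 1 bp past end
  expect_equal(res$per_region[[2]], "gB")
  expect_equal(sort(res$genes), c("gA", "gB"))

  both <- genes_in_regions(
    data.frame(chrom = "1", start = c(1L, 55000L), end = c(52000L, 70000L)),
    genes
  )
  expect_equal(both$genes, "gA")                   # union counted once
})

test_that("gene-list intersection enumerates all Venn cells", {
  res <- intersect_gene_lists(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(unname(res$cells["A&B"]), 1)
  expect_equal(unname(res$cells["A"]), 1)
  expect_equal(unname(res$cells["B"]), 1)

  four <- intersect_gene_lists(list(A = paste0("g", 1:5),
                                    B = paste0("g", 1:5),
                                    C = paste0("g", 1:5),
                                    D = paste0("g", 1:5)))
  expect_equal(unname(four$cells["A&B&C&D"]), 5)
  expect_equal(sum(four$cells), 5)

  disjoint <- intersect_gene_lists(list(A = "g1", B = "g2"))
  expect_equal(unname(disjoint$cells["A&B"]), 0)
})
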