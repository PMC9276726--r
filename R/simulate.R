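#' Configuration for the cohort simulator
#'
#' Defaults emulate the study design the scan targets: five pig-breed-like
#' populations of 25 diploids each, diverged under the Balding-Nichols model,
#' with optional designated sweep intervals in which the target population's
#' allele frequencies are pushed toward fixation.
#'
#' @param populations named integer vector: population label -> diploid
#'   sample count.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param snp_density expected SNPs per bp (default 1/2000).
#' @param F Balding-Nichols divergence parameter in (0, 1) (default 0.05);
#'   expected pairwise Fst between two populations is approximately F.
#' @param sweep_intervals data.frame with `chrom`, `start`, `end`, `pop`,
#'   `s` (sweep strength in `[0, 1]`), or NULL for a neutral genome.
#' @param missing_rate per-genotype missing probability (default 0.02).
#' @param ld_block_bp if > 0, adjacent sites within blocks of this size
#'   share allele frequencies and partially copy genotypes, giving LD that
#'   decays with distance; 0 (default) simulates independent sites.
#' @param seed RNG seed; the simulation is fully deterministic given the
#'   config.
#' @return A `sweep_sim_config` list.
#' @export
sweep_sim_config <- function(populations = c(XP = 25, TT = 25, MS = 25,
                                             DU = 25, LW = 25),
                             chrom_lengths = c("1" = 10000000,
                                               "2" = 10000000),
                             snp_density = 1 / 2000,
                             F = 0.05,
                             sweep_intervals = NULL,
                             missing_rate = 0.02,
                             ld_block_bp = 0,
                             seed = 1) {
  stopifnot(F > 0, F < 1, snp_density > 0,
            missing_rate >= 0, missing_rate < 1,
            all(populations >= 1), !is.null(names(populations)))
  if (!is.null(sweep_intervals)) {
    stopifnot(all(c("chrom", "start", "end", "pop", "s") %in%
                    names(sweep_intervals)))
    bad_pop <- setdiff(sweep_intervals$pop, names(populations))
    if (length(bad_pop)) {
      stop("sweep interval references unknown population: ",
           paste(bad_pop, collapse = ", "))
    }
    bad_chrom <- setdiff(sweep_intervals$chrom, names(chrom_lengths))
    if (length(bad_chrom)) {
      stop("sweep interval on unknown chromosome: ",
           paste(bad_chrom, collapse = ", "))
    }
    for (i in seq_len(nrow(sweep_intervals))) {
      L <- chrom_lengths[[sweep_intervals$chrom[i]]]
      if (sweep_intervals$start[i] < 1 || sweep_intervals$end[i] > L) {
        stop("sweep interval outside chromosome bounds")
      }
    }
    stopifnot(all(sweep_intervals$s >= 0), all(sweep_intervals$s <= 1))
  }
  structure(
    list(populations = populations, chrom_lengths = chrom_lengths,
         snp_density = snp_density, F = F,
         sweep_intervals = sweep_intervals,
         missing_rate = missing_rate, ld_block_bp = ld_block_bp,
         seed = seed),
    class = "sweep_sim_config"
  )
}

#' Simulate a multi-population cohort with known sweep locations
#'
#' Neutral SNPs: ancestral frequency `p ~ Uniform(0.05, 0.95)`; each
#' population's frequency is a Beta draw with mean `p` and concentration
#' `(1 - F) / F` (the Balding-Nichols model); genotypes are
#' `Binomial(2, p_pop)` per diploid sample. Within a sweep interval the
#' target population's frequency is pushed toward fixation,
#' `p <- (1 - s) * p + s * round(p)`, so `s` near 1 yields near-fixed
#' alleles, reduced target diversity, and elevated Fst / delta-AF, while
#' control populations keep their neutral draws. Genotypes are then masked
#' missing uniformly at `missing_rate`.
#'
#' @param config a [sweep_sim_config()].
#' @param out_dir if non-NULL, writes `cohort.vcf`, `popmap.tsv`,
#'   `sweep_truth.bed` (0-based half-open) and `sweep_snps.tsv` there.
#' @param gene_models optional gene models from [simulate_gene_models()] or
#'   [load_gff()] with CDS sequences attached; SNPs landing in a CDS then
#'   get their reference allele from the coding sequence (strand-adjusted),
#'   so coding-effect calls are consistent.
#' @return list: `genotypes` (a `genotype_matrix`), `popmap` (named
#'   character vector), `truth` (list with `intervals` and per-interval
#'   simulated `snps`), `config`.
#' @export
simulate_cohort <- function(config, out_dir = NULL, gene_models = NULL) {
  stopifnot(inherits(config, "sweep_sim_config"))
  set.seed(config$seed)
  pops <- config$populations
  pop_labels <- rep(names(pops), times = pops)
  samples <- paste0(rep(names(pops), times = pops), "_",
                    unlist(lapply(pops, seq_len)))
  popmap <- stats::setNames(pop_labels, samples)

  nuc <- c("A", "C", "G", "T")
  conc <- (1 - config$F) / config$F

  all_sites <- list()
  all_dos <- list()
  truth_snps <- list()
  sw <- config$sweep_intervals

  for (ch in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[ch]]
    n_snp <- max(1L, round(L * config$snp_density))
    pos <- sort(sample.int(L, n_snp))
    use_ld <- config$ld_block_bp > 0
    block <- if (use_ld) (pos - 1L) %/% config$ld_block_bp else seq_len(n_snp) - 1L
    ublock <- unique(block)
    p_anc_b <- stats::runif(length(ublock), 0.05, 0.95)
    p_anc <- p_anc_b[match(block, ublock)]

    # per-population frequencies: one Beta draw per block (per site when
    # blocks are off)
    freq <- matrix(NA_real_, n_snp, length(pops),
                   dimnames = list(NULL, names(pops)))
    for (pp in names(pops)) {
      f_b <- stats::rbeta(length(ublock), p_anc_b * conc,
                          (1 - p_anc_b) * conc)
      freq[, pp] <- f_b[match(block, ublock)]
    }

    # sweep intervals override the target population's frequencies
    if (!is.null(sw)) {
      for (i in which(sw$chrom == ch)) {
        in_iv <- pos >= sw$start[i] & pos <= sw$end[i]
        if (!any(in_iv)) next
        tp <- sw$pop[i]
        s <- sw$s[i]
        freq[in_iv, tp] <- (1 - s) * freq[in_iv, tp] +
          s * round(freq[in_iv, tp])
        truth_snps[[length(truth_snps) + 1]] <- data.frame(
          chrom = ch, pos = pos[in_iv], interval = i,
          stringsAsFactors = FALSE
        )
      }
    }

    dos <- matrix(NA_integer_, n_snp, length(samples))
    col0 <- 0L
    for (pp in names(pops)) {
      n_s <- pops[[pp]]
      if (use_ld) {
        dos_p <- matrix(NA_integer_, n_snp, n_s)
        for (b in ublock) {
          rows <- which(block == b)
          anchor <- stats::rbinom(n_s, 2, freq[rows[1], pp])
          d0 <- pos[rows] - pos[rows[1]]
          rho <- exp(-3 * d0 / config$ld_block_bp)
          for (k in seq_along(rows)) {
            fresh <- stats::rbinom(n_s, 2, freq[rows[k], pp])
            copy <- stats::runif(n_s) < rho[k]
            dos_p[rows[k], ] <- ifelse(copy, anchor, fresh)
          }
        }
      } else {
        dos_p <- matrix(
          stats::rbinom(n_snp * n_s, 2, rep(freq[, pp], times = n_s)),
          nrow = n_snp
        )
      }
      dos[, col0 + seq_len(n_s)] <- dos_p
      col0 <- col0 + n_s
    }
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(dos)) < config$missing_rate
      dos[mask] <- NA_integer_
    }

    ref <- sample(nuc, n_snp, replace = TRUE)
    if (!is.null(gene_models)) {
      known <- genomic_cds_bases(gene_models, ch, pos)
      ref[!is.na(known)] <- known[!is.na(known)]
    }
    alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), character(1))
    sites <- data.frame(
      chrom = ch, pos = pos, ref = ref, alt = alt,
      qual = round(stats::runif(n_snp, 60, 1500), 1),
      QD = round(stats::runif(n_snp, 8, 35), 2),
      FS = round(stats::runif(n_snp, 0, 25), 2),
      MQ = round(stats::runif(n_snp, 45, 60), 2),
      MQRankSum = round(stats::runif(n_snp, -3, 3), 2),
      ReadPosRankSum = round(stats::runif(n_snp, -3, 3), 2),
      stringsAsFactors = FALSE
    )
    all_sites[[ch]] <- sites
    all_dos[[ch]] <- dos
  }

  gm <- genotype_matrix(do.call(rbind, all_sites),
                        do.call(rbind, all_dos), samples)
  truth <- list(
    intervals = if (is.null(sw)) {
      data.frame(chrom = character(), start = integer(), end = integer(),
                 pop = character(), s = numeric())
    } else sw,
    snps = if (length(truth_snps)) {
      do.call(rbind, truth_snps)
    } else {
      data.frame(chrom = character(), pos = integer(), interval = integer())
    }
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(gm, file.path(out_dir, "cohort.vcf"),
              chrom_lengths = config$chrom_lengths)
    write_popmap(popmap, file.path(out_dir, "popmap.tsv"))
    write_bed(truth$intervals, file.path(out_dir, "sweep_truth.bed"))
    utils::write.table(truth$snps, file.path(out_dir, "sweep_snps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(genotypes = gm, popmap = popmap, truth = truth, config = config)
}

# Reference-genome base at CDS positions, from a transcript's coding
# sequence (complemented back to the forward strand for minus-strand
# genes); NA outside any CDS.
genomic_cds_bases <- function(models, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (g in models) {
    if (g$chrom != chrom) next
    for (tx in g$transcripts) {
      if (is.null(tx$cds_seq)) next
      inside <- which(vapply(pos, function(p) {
        any(tx$cds$start <= p & p <= tx$cds$end)
      }, logical(1)))
      for (i in inside) {
        off <- cds_offset(pos[i], tx)
        base <- substr(tx$cds_seq, off, off)
        out[i] <- if (tx$strand == "+") base else comp[[base]]
      }
    }
  }
  out
}

#' Simulate gene models with frame-consistent CDS
#'
#' Packs non-overlapping multi-exon genes (with 5'/3' UTRs and a CDS that
#' starts with ATG, ends with a stop codon, has length divisible by 3, and
#' no internal stops) onto the given chromosomes, and groups genes into
#' random GMT sets plus one "sweep_set" enriched for genes inside sweep
#' intervals.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_genes number of genes to place.
#' @param seed RNG seed.
#' @param sweep_intervals optional data.frame (`chrom`, `start`, `end`) used
#'   to build the enriched sweep set.
#' @param n_sets number of random gene sets (default 10).
#' @param out_dir if non-NULL, writes `genes.gff3`, `cds.fasta`, `sets.gmt`.
#' @return list: `models` (same structure as [load_gff()], with `cds_seq`
#'   attached), `cds_seqs` (named character vector by transcript id),
#'   `sets` (named list for GMT).
#' @export
simulate_gene_models <- function(chrom_lengths, n_genes, seed = 1,
                                 sweep_intervals = NULL, n_sets = 10,
                                 out_dir = NULL) {
  set.seed(seed)
  sense_codons <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA")
  )
  stops <- c("TAA", "TAG", "TGA")

  # draw every gene's structure first so the free space can be spread as
  # random intergenic gaps across the whole genome
  structs <- lapply(seq_len(n_genes), function(gi) {
    n_exons <- sample(2:4, 1)
    n_codons <- sample(100:250, 1)
    cds_len <- 3L * n_codons
    utr5_len <- sample(50:200, 1)
    utr3_len <- sample(50:200, 1)
    tx_len <- utr5_len + cds_len + utr3_len
    cuts <- sort(sample(seq(60, tx_len - 60, by = 1), n_exons - 1))
    chunk_len <- diff(c(0, cuts, tx_len))
    introns <- sample(200:1000, n_exons - 1, replace = TRUE)
    list(n_exons = n_exons, n_codons = n_codons, utr5_len = utr5_len,
         utr3_len = utr3_len, cds_len = cds_len, tx_len = tx_len,
         chunk_len = chunk_len, introns = introns,
         g_len = tx_len + sum(introns))
  })

  # allocate genes to chromosomes proportionally to length, then place each
  # chromosome's genes with random gaps filling its free space
  share <- chrom_lengths / sum(chrom_lengths)
  quota <- diff(round(c(0, cumsum(share * n_genes))))
  names(quota) <- names(chrom_lengths)
  placement <- data.frame(chrom = character(n_genes),
                          start = integer(n_genes),
                          stringsAsFactors = FALSE)
  gi0 <- 0
  for (ch in names(chrom_lengths)) {
    k <- quota[[ch]]
    if (k == 0) next
    idx <- gi0 + seq_len(k)
    gi0 <- gi0 + k
    footprint <- sum(vapply(structs[idx], `[[`, numeric(1), "g_len"))
    free <- chrom_lengths[[ch]] - footprint
    if (free < 2 * (k + 1)) {
      stop("infeasible packing: ", n_genes,
           " genes do not fit the given chromosome lengths")
    }
    w <- stats::runif(k + 1)
    gaps <- as.integer(floor((free - (k + 1)) * w / sum(w))) + 1L
    at <- 1L
    for (j in seq_len(k)) {
      at <- at + gaps[j]
      placement$chrom[idx[j]] <- ch
      placement$start[idx[j]] <- at
      at <- at + structs[[idx[j]]]$g_len
    }
  }

  models <- vector("list", n_genes)
  cds_seqs <- character(0)
  for (gi in seq_len(n_genes)) {
    st <- structs[[gi]]
    n_exons <- st$n_exons
    n_codons <- st$n_codons
    utr5_len <- st$utr5_len
    cds_len <- st$cds_len
    tx_len <- st$tx_len
    chunk_len <- st$chunk_len
    introns <- st$introns
    ch <- placement$chrom[gi]
    g_start <- placement$start[gi]

    # genomic exon intervals
    ex_start <- integer(n_exons)
    ex_end <- integer(n_exons)
    at <- g_start
    for (e in seq_len(n_exons)) {
      ex_start[e] <- at
      ex_end[e] <- at + chunk_len[e] - 1L
      at <- ex_end[e] + 1L + if (e < n_exons) introns[e] else 0L
    }
    exons <- data.frame(start = ex_start, end = ex_end)
    g_end <- max(ex_end)
    strand <- sample(c("+", "-"), 1)

    # transcript-coordinate layout (coding strand): UTR5 | CDS | UTR3
    exonic <- unlist(lapply(seq_len(n_exons),
                            function(e) ex_start[e]:ex_end[e]))
    tx_to_gen <- if (strand == "+") exonic else rev(exonic)
    tx_interval_to_genomic <- function(a, b) {
      gp <- sort(tx_to_gen[a:b])
      runs <- cumsum(c(1L, as.integer(diff(gp) != 1L)))
      do.call(rbind, lapply(split(gp, runs), function(r) {
        data.frame(start = min(r), end = max(r))
      }))
    }
    utr5 <- tx_interval_to_genomic(1, utr5_len)
    cds <- tx_interval_to_genomic(utr5_len + 1, utr5_len + cds_len)
    utr3 <- tx_interval_to_genomic(utr5_len + cds_len + 1, tx_len)
    rownames(utr5) <- rownames(cds) <- rownames(utr3) <- NULL

    seq <- paste0("ATG",
                  paste(sample(sense_codons, n_codons - 2, replace = TRUE),
                        collapse = ""),
                  sample(stops, 1))
    gene_id <- sprintf("gene%04d", gi)
    tx_id <- sprintf("tx%04d", gi)
    cds_seqs[tx_id] <- seq
    models[[gi]] <- list(
      gene_id = gene_id, chrom = ch, strand = strand,
      start = g_start, end = g_end,
      transcripts = stats::setNames(list(list(
        tx_id = tx_id, strand = strand, chrom = ch,
        exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
        cds_seq = seq
      )), tx_id)
    )
  }
  names(models) <- vapply(models, `[[`, character(1), "gene_id")

  # gene sets: random sets plus one set enriched for sweep-interval genes
  gene_ids <- names(models)
  sets <- lapply(seq_len(n_sets), function(i) {
    sample(gene_ids, min(length(gene_ids), sample(5:20, 1)))
  })
  names(sets) <- sprintf("set%02d", seq_len(n_sets))
  if (!is.null(sweep_intervals) && nrow(sweep_intervals)) {
    hit <- genes_in_regions(sweep_intervals, models)$genes
    filler <- sample(setdiff(gene_ids, hit),
                     min(length(setdiff(gene_ids, hit)),
                         max(1, length(hit) %/% 3)))
    sets[["sweep_set"]] <- unique(c(hit, filler))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gff3(models, file.path(out_dir, "genes.gff3"))
    write_fasta(cds_seqs, file.path(out_dir, "cds.fasta"))
    write_gmt(sets, file.path(out_dir, "sets.gmt"))
  }
  list(models = models, cds_seqs = cds_seqs, sets = sets)
}

#' Write gene models as GFF3
#'
#' @param models gene-model list (see [load_gff()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  line <- function(chrom, type, start, end, strand, phase, attrs) {
    sprintf("%s\tsweepscan\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, start, end, strand, phase, attrs)
  }
  for (g in models) {
    writeLines(line(g$chrom, "gene", g$start, g$end, g$strand, ".",
                    paste0("ID=", g$gene_id)), con)
    for (tx in g$transcripts) {
      span <- c(min(tx$exons$start), max(tx$exons$end))
      writeLines(line(g$chrom, "mRNA", span[1], span[2], g$strand, ".",
                      paste0("ID=", tx$tx_id, ";Parent=", g$gene_id)), con)
      emit <- function(df, type, with_phase = FALSE) {
        if (!nrow(df)) return()
        if (with_phase) {
          # phase = bases to skip before the next codon start
          ord <- if (g$strand == "+") order(df$start) else order(-df$start)
          lens <- (df$end - df$start + 1)[ord]
          phase <- (3 - (cumsum(c(0, lens[-length(lens)])) %% 3)) %% 3
          phase <- phase[order(ord)]
        } else {
          phase <- rep(".", nrow(df))
        }
        for (i in seq_len(nrow(df))) {
          writeLines(line(g$chrom, type, df$start[i], df$end[i], g$strand,
                          as.character(phase[i]),
                          paste0("ID=", tx$tx_id, ":", type, i,
                                 ";Parent=", tx$tx_id)), con)
        }
      }
      emit(tx$exons, "exon")
      emit(tx$cds, "CDS", with_phase = TRUE)
      emit(tx$utr5, "five_prime_UTR")
      emit(tx$utr3, "three_prime_UTR")
    }
  }
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
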