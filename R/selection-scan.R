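#' Sliding windows over chromosomes
#'
#' Per chromosome, window starts run 1, 1+step, 1+2*step, ... while
#' start <= length; each window ends at `min(start + size - 1, length)`.
#'
#' @param chrom_lengths named integer vector, chromosome -> length in bp.
#' @param size window size in bp (default 100 kb).
#' @param step step size in bp (default 10 kb).
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive), sorted.
#' @export
make_windows <- function(chrom_lengths, size = 100000, step = 10000) {
  stopifnot(size >= step, step >= 1)
  if (any(chrom_lengths <= 0)) stop("non-positive chromosome length")
  res <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq.int(1L, L, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size - 1, L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Weir-Cockerham (1984) per-site variance components, two populations
#'
#' Returns the among-population (a), among-individual-within-population (b)
#' and within-individual (c) components for a biallelic site observed in two
#' populations, from per-population called sample sizes, alternate-allele
#' frequencies, and observed heterozygote fractions. Per-site
#' Fst = a / (a + b + c); the windowed ("weighted") estimator sums components
#' across sites before taking the ratio.
#'
#' All arguments are vectorized over sites.
#'
#' @param n1,n2 called diploid individuals per population (>= 1).
#' @param p1,p2 alternate-allele frequencies in `[0, 1]`.
#' @param h1,h2 observed heterozygote fractions in `[0, 1]`.
#' @return data.frame with columns `a`, `b`, `c`. Sites monomorphic for the
#'   same allele in both populations give a = b = c = 0.
#' @export
site_fst_components <- function(n1, p1, h1, n2, p2, h2) {
  stopifnot(all(n1 >= 1), all(n2 >= 1),
            all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2

  # monomorphic in the pooled sample: no information, contributes nothing
  mono <- (pbar == 0 | pbar == 1) & hbar == 0
  a[mono] <- 0
  b[mono] <- 0
  cc[mono] <- 0
  # single-individual edge (nbar == 1) is degenerate; treat as no information
  degen <- !is.finite(a) | !is.finite(b)
  a[degen] <- 0
  b[degen] <- 0
  cc[degen] <- 0
  data.frame(a = a, b = b, c = cc)
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site pi: the probability that two alleles drawn without
#' replacement differ, `2 * k * (n - k) / (n * (n - 1))` for `k` alternate
#' alleles among `n` called alleles.
#'
#' @param alt_count alternate-allele count (vectorized).
#' @param n_alleles total called alleles (>= 2; sites with fewer are `NA`).
#' @return numeric vector of per-site pi values.
#' @export
site_pi <- function(alt_count, n_alleles) {
  stopifnot(all(alt_count >= 0), all(alt_count <= n_alleles))
  out <- ifelse(
    n_alleles >= 2,
    2 * alt_count * (n_alleles - alt_count) / (n_alleles * (n_alleles - 1)),
    NA_real_
  )
  out
}

# Per-site summaries for one population: called n, alt count, het fraction.
pop_site_summary <- function(dosage) {
  n_called <- rowSums(!is.na(dosage))
  ac <- rowSums(dosage, na.rm = TRUE)
  het <- rowSums(dosage == 1L, na.rm = TRUE)
  list(n = n_called, ac = ac,
       p = ifelse(n_called > 0, ac / (2 * n_called), NA_real_),
       h = ifelse(n_called > 0, het / n_called, NA_real_))
}

#' Windowed Fst and theta-pi-ratio scan
#'
#' For a target/control population pair, computes per-window weighted
#' Weir-Cockerham Fst (sum of a over sum of a+b+c across sites), windowed
#' per-bp nucleotide diversity for each population (site-pi summed over the
#' window, divided by window length), and the diversity ratio
#' `pi_control / pi_target` (values > 1 mean reduced diversity in the
#' target). Windows with fewer than `min_snps` SNPs are discarded; windows
#' where `pi_target` is 0 get an infinite ratio (retained for Fst, excluded
#' from ratio quantiles downstream).
#'
#' @param gm a `genotype_matrix` (post-QC).
#' @param popmap named character vector (sample -> population).
#' @param target,control population labels to compare.
#' @param windows data.frame from [make_windows()].
#' @param min_snps minimum SNPs per window (default 10).
#' @return data.frame: `chrom`, `start`, `end`, `snp_count`, `fst`,
#'   `pi_target`, `pi_control`, `theta_pi_ratio`.
#' @export
windowed_stats <- function(gm, popmap, target, control, windows,
                           min_snps = 10) {
  stopifnot(inherits(gm, "genotype_matrix"), target != control)
  labels <- check_popmap(gm, popmap)
  if (!target %in% labels) stop("target population not present: ", target)
  if (!control %in% labels) stop("control population not present: ", control)

  t_sum <- pop_site_summary(gm$dosage[, labels == target, drop = FALSE])
  c_sum <- pop_site_summary(gm$dosage[, labels == control, drop = FALSE])

  # sites where either population has no called individuals are skipped
  usable <- t_sum$n >= 1 & c_sum$n >= 1
  comp <- data.frame(a = numeric(nrow(gm$sites)), b = 0, c = 0)
  comp[usable, ] <- site_fst_components(
    t_sum$n[usable], t_sum$p[usable], t_sum$h[usable],
    c_sum$n[usable], c_sum$p[usable], c_sum$h[usable]
  )
  abc <- comp$a + comp$b + comp$c
  informative <- usable & abc != 0

  pi_t <- ifelse(t_sum$n >= 1, site_pi(t_sum$ac, 2 * t_sum$n), 0)
  pi_c <- ifelse(c_sum$n >= 1, site_pi(c_sum$ac, 2 * c_sum$n), 0)
  pi_t[is.na(pi_t)] <- 0
  pi_c[is.na(pi_c)] <- 0

  res <- lapply(split(seq_len(nrow(windows)), windows$chrom), function(wi) {
    ch <- windows$chrom[wi[1]]
    on_ch <- which(gm$sites$chrom == ch)
    if (!length(on_ch)) return(NULL)
    pos <- gm$sites$pos[on_ch]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos, width = 1),
      IRanges::IRanges(start = windows$start[wi], end = windows$end[wi])
    )
    si <- on_ch[S4Vectors::queryHits(hits)]      # site row (global)
    wj <- wi[S4Vectors::subjectHits(hits)]       # window row (global)
    grp <- factor(wj, levels = wi)
    snp_count <- as.integer(table(grp))
    # rowsum drops empty levels: aggregate then zero-fill
    sum_by <- function(x) {
      out <- numeric(length(wi))
      if (length(si)) {
        agg <- rowsum(x, grp)
        out[match(rownames(agg), as.character(wi))] <- agg[, 1]
      }
      out
    }
    inf_here <- informative[si]
    data.frame(
      chrom = ch,
      start = windows$start[wi],
      end = windows$end[wi],
      snp_count = snp_count,
      sum_a = sum_by(comp$a[si] * inf_here),
      sum_abc = sum_by(abc[si] * inf_here),
      sum_pi_t = sum_by(pi_t[si]),
      sum_pi_c = sum_by(pi_c[si]),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res <- res[res$snp_count >= min_snps, , drop = FALSE]
  if (!nrow(res)) {
    warning("no window reaches min_snps = ", min_snps)
  }
  len <- res$end - res$start + 1
  out <- data.frame(
    chrom = res$chrom, start = res$start, end = res$end,
    snp_count = res$snp_count,
    fst = ifelse(res$sum_abc > 0, res$sum_a / res$sum_abc, NA_real_),
    pi_target = res$sum_pi_t / len,
    pi_control = res$sum_pi_c / len,
    stringsAsFactors = FALSE
  )
  out$theta_pi_ratio <- ifelse(out$pi_target > 0,
                               out$pi_control / out$pi_target, Inf)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Joint top-quantile outlier windows
#'
#' For each of Fst and the theta-pi ratio, the outlier set is the
#' `ceiling((1 - q) * N)` highest-valued windows over the N windows with
#' finite values of both statistics (ties at the boundary value are all
#' included). The returned candidates are the intersection of the two sets.
#'
#' @param stats data.frame from [windowed_stats()].
#' @param q quantile (default 0.95 = top 5 percent).
#' @return list: `outliers` (data.frame subset of `stats`),
#'   `fst_threshold`, `ratio_threshold` (the realized minimum value in each
#'   outlier set), `n_used`, `n_infinite_ratio`.
#' @export
select_outliers <- function(stats, q = 0.95) {
  stopifnot(q > 0, q <= 1)
  finite <- is.finite(stats$fst) & is.finite(stats$theta_pi_ratio)
  n_inf <- sum(is.infinite(stats$theta_pi_ratio))
  usable <- stats[finite, , drop = FALSE]
  N <- nrow(usable)
  if (N < 20) stop("fewer than 20 windows with finite statistics (", N, ")")
  # small epsilon keeps e.g. (1 - 0.95) * 20 from ceiling to 2
  k <- ceiling((1 - q) * N - 1e-9)
  if (k == 0) {
    return(list(outliers = usable[0, , drop = FALSE],
                fst_threshold = NA_real_, ratio_threshold = NA_real_,
                n_used = N, n_infinite_ratio = n_inf))
  }
  fst_thr <- sort(usable$fst, decreasing = TRUE)[k]
  ratio_thr <- sort(usable$theta_pi_ratio, decreasing = TRUE)[k]
  sel <- usable$fst >= fst_thr & usable$theta_pi_ratio >= ratio_thr
  out <- usable[sel, , drop = FALSE]
  rownames(out) <- NULL
  list(outliers = out, fst_threshold = fst_thr, ratio_threshold = ratio_thr,
       n_used = N, n_infinite_ratio = n_inf)
}

#' Merge outlier windows into candidate regions
#'
#' bedtools-merge semantics: overlapping or book-ended (end + 1 == next
#' start) windows on the same chromosome collapse into one region. Carries
#' the number of merged windows and the max Fst / max ratio when present.
#'
#' @param windows data.frame with `chrom`, `start`, `end` and optionally
#'   `fst`, `theta_pi_ratio`.
#' @return data.frame: `chrom`, `start`, `end`, `n_windows`, `max_fst`,
#'   `max_theta_pi_ratio`; disjoint and sorted within chromosome.
#' @export
merge_regions <- function(windows) {
  if (!nrow(windows)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      max_fst = numeric(), max_theta_pi_ratio = numeric()))
  }
  w <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  has_fst <- "fst" %in% names(w)
  has_ratio <- "theta_pi_ratio" %in% names(w)
  res <- list()
  cur <- NULL
  flush <- function(cur) {
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               n_windows = cur$n,
               max_fst = cur$max_fst, max_theta_pi_ratio = cur$max_ratio,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(w))) {
    row <- w[i, ]
    f <- if (has_fst) row$fst else NA_real_
    r <- if (has_ratio) row$theta_pi_ratio else NA_real_
    if (is.null(cur) || row$chrom != cur$chrom || row$start > cur$end + 1) {
      if (!is.null(cur)) res[[length(res) + 1]] <- flush(cur)
      cur <- list(chrom = row$chrom, start = row$start, end = row$end,
                  n = 1L, max_fst = f, max_ratio = r)
    } else {
      cur$end <- max(cur$end, row$end)
      cur$n <- cur$n + 1L
      nmax <- function(x, y) {
        if (all(is.na(c(x, y)))) NA_real_ else max(x, y, na.rm = TRUE)
      }
      cur$max_fst <- nmax(cur$max_fst, f)
      cur$max_ratio <- nmax(cur$max_ratio, r)
    }
  }
  res[[length(res) + 1]] <- flush(cur)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write regions as BED (0-based half-open)
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, regions$start - 1L, regions$end),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
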