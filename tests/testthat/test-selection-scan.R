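test_that("make_windows enumerates sliding windows with truncation at chromosome end", {
  w <- make_windows(c(chrA = 150000), size = 100000, step = 10000)
  expect_equal(nrow(w), floor((150000 - 1) / 10000) + 1)
  expect_equal(w$start[1], 1)
  expect_equal(w$end[1], 100000)
  expect_equal(c(w$start[6], w$end[6]), c(50001, 150000))
  expect_equal(c(w$start[15], w$end[15]), c(140001, 150000))

  one <- make_windows(c(chrA = 100000))
  expect_equal(c(one$start[1], one$end[1]), c(1, 100000))

  short <- make_windows(c(chrA = 5000))
  expect_equal(nrow(short), 1)
  expect_equal(c(short$start, short$end), c(1, 5000))

  expect_error(make_windows(c(chrA = 0)), "non-positive")
})

test_that("WC84 components match hand-derived values at fixed difference and shared polymorphism", {
  fixed <- site_fst_components(25, 1.0, 0, 25, 0.0, 0)
  expect_equal(fixed$a, 0.5)
  expect_equal(fixed$b, 0)
  expect_equal(fixed$c, 0)
  expect_equal(fixed$a / (fixed$a + fixed$b + fixed$c), 1.0)

  shared <- site_fst_components(10, 0.5, 0.5, 10, 0.5, 0.5)
  expect_equal(shared$a, -0.0138889, tolerance = 1e-5)
  expect_equal(shared$b, 0.0138889, tolerance = 1e-5)
  expect_equal(shared$c, 0.25)
  expect_equal(shared$a / (shared$a + shared$b + shared$c), -0.0556,
               tolerance = 1e-3)

  mono <- site_fst_components(10, 0, 0, 10, 0, 0)
  expect_equal(unlist(mono), c(a = 0, b = 0, c = 0))
})

test_that("WC84 components agree with the independent loop-form oracle", {
  set.seed(21)
  for (i in 1:200) {
    n <- sample(2:30, 2, replace = TRUE)
    p <- runif(2)
    # heterozygote fraction must be consistent with p: h <= 2*min(p, 1-p)
    h <- runif(2) * 2 * pmin(p, 1 - p)
    got <- site_fst_components(n[1], p[1], h[1], n[2], p[2], h[2])
    want <- wc84_oracle(n, p, h)
    expect_equal(unlist(got), want, tolerance = 1e-12)
  }
})

test_that("site_pi equals exhaustive pairwise-difference counting for n <= 12", {
  for (n in 2:12) {
    for (k in 0:n) {
      expect_equal(site_pi(k, n), pi_pair_oracle(k, n),
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
  expect_equal(site_pi(2, 4), 2 / 3)
  expect_equal(site_pi(0, 10), 0)
  expect_equal(site_pi(1, 2), 1)
  expect_true(is.na(site_pi(0, 1)))
})

test_that("windowed scan discards sparse windows and hits Fst = 1 on fixed differences", {
  # 10 fixed-difference SNPs in window one, 9 in window two
  pos <- c(seq(1000, 10000, by = 1000), seq(101000, 109000, by = 1000))
  d <- rbind(matrix(2L, 10, 10), matrix(2L, 9, 10))
  d <- cbind(d, 2L - d)  # control = opposite homozygote
  gm <- make_gm(d, pos = pos)
  pm <- make_popmap(gm, 10)
  w <- make_windows(c("1" = 200000), size = 100000, step = 100000)
  ws <- windowed_stats(gm, pm, "XP", "TT", w, min_snps = 10)
  expect_equal(nrow(ws), 1)  # the 9-SNP window is absent
  expect_equal(ws$start, 1)
  expect_equal(ws$fst, 1.0)
  expect_equal(ws$pi_target, 0)
  expect_true(is.infinite(ws$theta_pi_ratio))
})

test_that("windowed Fst is small (and possibly negative) for identical populations", {
  set.seed(9)
  base <- matrix(sample(0:2, 12 * 25, replace = TRUE, prob = c(.25, .5, .25)),
                 12, 25)
  gm <- make_gm(cbind(base, base), pos = seq(1000, 12000, by = 1000))
  pm <- make_popmap(gm, 25)
  w <- make_windows(c("1" = 12000), size = 12000, step = 12000)
  ws <- windowed_stats(gm, pm, "XP", "TT", w, min_snps = 10)
  expect_true(ws$fst <= 0)  # identical columns: estimator's negative bias
  expect_equal(ws$theta_pi_ratio, 1.0)
})

test_that("windowed Fst matches the independent oracle on random genotypes", {
  set.seed(31)
  for (rep in 1:5) {
    n1 <- sample(5:20, 1); n2 <- sample(5:20, 1)
    m <- 40
    d1 <- matrix(rbinom(m * n1, 2, runif(m, .05, .95)), m, n1)
    d2 <- matrix(rbinom(m * n2, 2, runif(m, .05, .95)), m, n2)
    d <- cbind(d1, d2)
    d[sample(length(d), round(0.05 * length(d)))] <- NA_integer_
    gm <- make_gm(d, pos = seq_len(m) * 100L)
    pm <- make_popmap(gm, n1)
    w <- make_windows(c("1" = m * 100L), size = m * 100L, step = m * 100L)
    ws <- windowed_stats(gm, pm, "XP", "TT", w, min_snps = 1)
    expect_equal(ws$fst, windowed_fst_oracle(d[, 1:n1], d[, n1 + (1:n2)]),
                 tolerance = 1e-10)
  }
})

test_that("windowed pi is invariant to sample order and monomorphic ref sites", {
  set.seed(13)
  d <- matrix(sample(0:2, 20 * 16, replace = TRUE), 20, 16)
  gm <- make_gm(d, pos = seq(500, 10000, by = 500))
  pm <- make_popmap(gm, 8)
  w <- make_windows(c("1" = 10000), size = 10000, step = 10000)
  base <- windowed_stats(gm, pm, "XP", "TT", w, min_snps = 1)

  perm <- sample(ncol(d))
  gm_p <- make_gm(d[, perm], pos = gm$sites$pos,
                  samples = gm$samples[perm])
  shuffled <- windowed_stats(gm_p, pm, "XP", "TT", w, min_snps = 1)
  expect_equal(shuffled$pi_target, base$pi_target)
  expect_equal(shuffled$fst, base$fst)

  gm_m <- make_gm(rbind(d, matrix(0L, 3, 16)),
                  pos = c(gm$sites$pos, c(150L, 250L, 350L)))
  mono <- windowed_stats(gm_m, pm, "XP", "TT", w, min_snps = 1)
  expect_equal(mono$pi_target, base$pi_target)
  expect_equal(mono$pi_control, base$pi_control)
})

test_that("theta-pi ratio inverts when target and control swap", {
  set.seed(17)
  cfg <- sweep_sim_config(populations = c(XP = 15, TT = 15),
                          chrom_lengths = c("1" = 1000000), seed = 17)
  sim <- simulate_cohort(cfg)
  w <- make_windows(cfg$chrom_lengths)
  fwd <- windowed_stats(sim$genotypes, sim$popmap, "XP", "TT", w)
  rev <- windowed_stats(sim$genotypes, sim$popmap, "TT", "XP", w)
  both <- is.finite(fwd$theta_pi_ratio) & fwd$theta_pi_ratio > 0
  expect_equal(rev$theta_pi_ratio[both], 1 / fwd$theta_pi_ratio[both])
  expect_equal(rev$fst, fwd$fst)
})

test_that("outlier selection is the brute-force top-k intersection with tie inclusion", {
  ws <- data.frame(chrom = "1", start = 1:20, end = 1:20, snp_count = 10,
                   fst = 1:20, pi_target = 1, pi_control = 1,
                   theta_pi_ratio = 1:20)
  sel <- select_outliers(ws, q = 0.95)
  expect_equal(nrow(sel$outliers), 1)
  expect_equal(sel$outliers$fst, 20)
  expect_equal(sel$fst_threshold, 20)
  expect_equal(sel$ratio_threshold, 20)

  rev <- ws
  rev$theta_pi_ratio <- 20:1
  expect_equal(nrow(select_outliers(rev, q = 0.95)$outliers), 0)

  tied <- data.frame(chrom = "1", start = 1:40, end = 1:40, snp_count = 10,
                     fst = c(1:37, 38, 38, 40), pi_target = 1,
                     pi_control = 1, theta_pi_ratio = 1:40)
  sel_t <- select_outliers(tied, q = 0.95)
  # k = 2; the realized fst threshold is the boundary value 38, shared by
  # two windows, so three windows enter the fst outlier set; intersection
  # with the top-2 ratio set keeps windows 39 and 40
  expect_equal(sel_t$fst_threshold, 38)
  expect_equal(sum(tied$fst >= sel_t$fst_threshold), 3)
  expect_equal(sort(sel_t$outliers$start), c(39, 40))

  expect_error(select_outliers(ws[1:10, ]), "fewer than 20")
})

test_that("infinite ratios are excluded from quantiles but counted", {
  ws <- data.frame(chrom = "1", start = 1:25, end = 1:25, snp_count = 10,
                   fst = 1:25, pi_target = c(0, rep(1, 24)),
                   pi_control = 1, theta_pi_ratio = c(Inf, 1:24))
  sel <- select_outliers(ws, q = 0.95)
  expect_equal(sel$n_used, 24)
  expect_equal(sel$n_infinite_ratio, 1)
  expect_false(any(is.infinite(sel$outliers$theta_pi_ratio)))
})

test_that("region merging follows bedtools semantics including book-ended windows", {
  w <- data.frame(chrom = "1",
                  start = c(1, 10001), end = c(100000, 110000),
                  fst = c(.5, .7), theta_pi_ratio = c(2, 3))
  m <- merge_regions(w)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$start, m$end), c(1, 110000))
  expect_equal(m$n_windows, 2)
  expect_equal(m$max_fst, .7)
  expect_equal(m$max_theta_pi_ratio, 3)

  disjoint <- data.frame(chrom = "1", start = c(1, 200001),
                         end = c(100000, 300000))
  expect_equal(nrow(merge_regions(disjoint)), 2)

  booked <- data.frame(chrom = "1", start = c(1, 100001),
                       end = c(100000, 200000))
  mb <- merge_regions(booked)
  expect_equal(nrow(mb), 1)
  expect_equal(c(mb$start, mb$end), c(1, 200000))

  two_chrom <- data.frame(chrom = c("1", "2"), start = c(1, 1),
                          end = c(100000, 100000))
  expect_equal(nrow(merge_regions(two_chrom)), 2)
})

test_that("identical inputs give byte-identical window-stats TSV output", {
  cfg <- sweep_sim_config(populations = c(XP = 10, TT = 10),
                          chrom_lengths = c("1" = 500000), seed = 19)
  run <- function() {
    sim <- simulate_cohort(cfg)
    ws <- windowed_stats(sim$genotypes, sim$popmap, "XP", "TT",
                         make_windows(cfg$chrom_lengths))
    p <- tempfile(fileext = ".tsv")
    utils::write.table(ws, p, sep = "\t", quote = FALSE, row.names = FALSE)
    readBin(p, "raw", file.info(p)$size)
  }
  expect_identical(run(), run())
})
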