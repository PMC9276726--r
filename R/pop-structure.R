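#' Genotype PCA with Patterson scaling
#'
#' Missing dosages are mean-imputed per site, monomorphic sites dropped,
#' and each site centered by `2*p` and scaled by `sqrt(2*p*(1-p))` (`p` the
#' pooled alternate-allele frequency). Sample coordinates are the top-k
#' eigenvectors of the sample covariance, each scaled by the square root of
#' its eigenvalue.
#'
#' @param gm a `genotype_matrix`.
#' @param k number of components (default 10, capped at `n_samples - 1`).
#' @return list: `coords` (samples x k matrix), `eigenvalues`,
#'   `explained` (fraction of total variance per component).
#' @export
genotype_pca <- function(gm, k = 10) {
  stopifnot(inherits(gm, "genotype_matrix"), length(gm$samples) >= 2)
  d <- gm$dosage
  storage.mode(d) <- "double"
  # per-site mean imputation
  if (anyNA(d)) {
    mu <- rowMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 1]]
  }
  p <- rowMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites for PCA")
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  x <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  n <- ncol(x)
  m <- nrow(x)
  k <- min(k, n - 1)
  cov <- crossprod(x) / m        # n x n sample covariance
  eig <- eigen(cov, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  rownames(coords) <- gm$samples
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords,
       eigenvalues = vals[seq_len(k)],
       explained = vals[seq_len(k)] / sum(vals))
}

#' Allele-sharing (IBS) distance matrix
#'
#' `d(i, j)` = mean over co-called sites of `|dosage_i - dosage_j| / 2`;
#' a genotype-level genetic distance in `[0, 1]`.
#'
#' @param gm a `genotype_matrix`.
#' @return symmetric numeric matrix with zero diagonal, sample names on both
#'   dimensions.
#' @export
ibs_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"), length(gm$samples) >= 2)
  d <- gm$dosage
  storage.mode(d) <- "double"
  n <- ncol(d)
  out <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  called <- !is.na(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      co <- called[, i] & called[, j]
      if (!any(co)) {
        stop("samples ", gm$samples[i], " and ", gm$samples[j],
             " share no called sites")
      }
      out[i, j] <- out[j, i] <- mean(abs(d[co, i] - d[co, j])) / 2
    }
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via `ape::nj`); on an additive matrix the
#' tree's path distances reproduce the input exactly. Negative branch
#' lengths, an artifact of noisy distances, are clamped to zero with the
#' deficit transferred to the sister branch so path lengths through the
#' parent node are preserved on average.
#'
#' @param dist symmetric distance matrix (>= 3 taxa) with zero diagonal.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3) stop("need at least 3 taxa")
  if (!isSymmetric(unname(dist), tol = 1e-8)) {
    stop("distance matrix is not symmetric")
  }
  tree <- ape::nj(stats::as.dist(dist))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sibs <- which(tree$edge[, 1] == parent & seq_len(nrow(tree$edge)) != e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
  }
  tree
}

#' LD decay curve from genotype dosages
#'
#' Composite (genotype) linkage disequilibrium: `r^2` is the squared Pearson
#' correlation of dosage vectors within one population, computed for all
#' intra-chromosomal site pairs separated by at most `max_dist` bp, then
#' averaged within distance bins. Pairs where either site is monomorphic
#' within the population are skipped.
#'
#' @param gm a `genotype_matrix`.
#' @param popmap named character vector (sample -> population).
#' @param population population label (needs >= 5 samples).
#' @param max_dist maximum pair separation in bp (default 300 kb).
#' @param bin_bp distance bin width in bp (default 1000).
#' @return data.frame: `dist_mid` (bin midpoint, bp), `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(gm, popmap, population, max_dist = 300000,
                     bin_bp = 1000) {
  labels <- check_popmap(gm, popmap)
  cols <- which(labels == population)
  if (length(cols) < 5) {
    stop("population ", population, " has fewer than 5 samples")
  }
  d <- gm$dosage[, cols, drop = FALSE]
  storage.mode(d) <- "double"
  nbins <- ceiling(max_dist / bin_bp)
  sums <- numeric(nbins)
  counts <- integer(nbins)
  for (ch in unique(gm$sites$chrom)) {
    rows <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[rows]
    ord <- order(pos)
    rows <- rows[ord]
    pos <- pos[ord]
    v <- apply(d[rows, , drop = FALSE], 1, stats::var, na.rm = TRUE)
    for (ii in seq_along(rows)) {
      if (is.na(v[ii]) || v[ii] == 0) next
      jj <- ii + 1
      while (jj <= length(rows) && pos[jj] - pos[ii] <= max_dist) {
        if (!is.na(v[jj]) && v[jj] > 0) {
          r <- suppressWarnings(
            stats::cor(d[rows[ii], ], d[rows[jj], ],
                       use = "complete.obs")
          )
          if (!is.na(r)) {
            b <- ceiling((pos[jj] - pos[ii]) / bin_bp)
            sums[b] <- sums[b] + r^2
            counts[b] <- counts[b] + 1L
          }
        }
        jj <- jj + 1
      }
    }
  }
  keep <- counts > 0
  if (!any(keep)) {
    warning("no eligible site pairs for LD decay")
  }
  data.frame(
    dist_mid = (which(keep) - 0.5) * bin_bp,
    mean_r2 = sums[keep] / counts[keep],
    n_pairs = counts[keep]
  )
}
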