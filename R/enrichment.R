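#' Read a GMT gene-set file
#'
#' One set per line: `set_id<TAB>description<TAB>member<TAB>member...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors, with a `description` attribute
#'   (named character vector) on the list.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2), names(sets)
  )
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to the set id).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(names(sets), names(sets))
  }
  writeLines(vapply(names(sets), function(id) {
    paste(c(id, descriptions[[id]], sets[[id]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Hypergeometric over-representation test
#'
#' For each gene set, tests whether the selected genes overlap the set more
#' than expected by chance: `p = P(X >= k)` for `X` hypergeometric with
#' universe size `N`, set size `K` (after intersecting the set with the
#' universe), and selection size `n`. Benjamini-Hochberg q-values are
#' reported alongside; the significance flag uses the raw p < `alpha`.
#'
#' @param selected character vector of selected gene ids (must be a subset
#'   of `universe`).
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe character vector of background gene ids.
#' @param alpha raw-p significance cutoff (default 0.05).
#' @return data.frame sorted by p: `set_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`, `significant`.
#' @export
hypergeom_enrich <- function(selected, collection, universe, alpha = 0.05) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (!length(universe)) stop("empty universe")
  if (!length(selected)) stop("empty selected gene list")
  extra <- setdiff(selected, universe)
  if (length(extra)) {
    stop("selected genes outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  N <- length(universe)
  n <- length(selected)
  res <- lapply(names(collection), function(id) {
    set <- intersect(collection[[id]], universe)
    K <- length(set)
    k <- length(intersect(selected, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
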