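#' Subsample cells uniformly without replacement
#'
#' Large datasets are capped to `max_cells` cells before factorization; if
#' the matrix already has no more than `max_cells` columns it is returned
#' unchanged.
#'
#' @param counts genes x cells matrix.
#' @param max_cells maximum number of cells to retain (default 50000).
#' @param seed integer seed.
#' @return the (possibly column-subset) matrix, column order preserved.
#' @export
subsample_cells <- function(counts, max_cells = 50000, seed = 1L) {
  stopifnot(max_cells >= 2)
  validate_counts(counts)
  n <- ncol(counts)
  if (n <= max_cells) return(counts)
  keep <- with_seed(seed, sort(sample.int(n, max_cells)))
  counts[, keep, drop = FALSE]
}

#' Select highly variable genes
#'
#' Genes are ranked by a Fano-factor dispersion (variance over mean)
#' computed on counts depth-normalized to the median library size and
#' standardized within mean-expression bins — the consensus-NMF convention,
#' which keeps strongly variable low-expression genes in the set instead of
#' letting raw dispersion track the mean. Deterministic; ties broken by
#' gene order.
#'
#' @param counts genes x cells matrix.
#' @param n_hvg number of genes to return (default 2000).
#' @param n_bins number of mean-expression bins for dispersion
#'   standardization.
#' @return character vector of gene identifiers in decreasing
#'   normalized-dispersion order.
#' @export
select_hvg <- function(counts, n_hvg = 2000, n_bins = 20) {
  validate_counts(counts)
  stopifnot(n_hvg >= 1, n_hvg <= nrow(counts))
  depth <- Matrix::colSums(counts)
  if (all(depth == 0)) stop("all-zero count matrix")
  depth[depth == 0] <- 1
  sf <- stats::median(depth) / depth
  X <- as_dense(counts)
  Xn <- sweep(X, 2, sf, "*")
  mu <- rowMeans(Xn)
  v <- rowMeans(Xn^2) - mu^2
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- max(1L, min(n_bins, nrow(X) %/% 5L))
  bin <- if (nb < 2) rep(1L, nrow(X))
  else cut(rank(mu, ties.method = "first"), nb, labels = FALSE)
  z <- disp
  for (b in seq_len(nb)) {
    i <- which(bin == b)
    s <- sd(disp[i])
    if (!is.finite(s) || s == 0) s <- 1
    z[i] <- (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, seq_along(z))
  rownames(counts)[ord[seq_len(n_hvg)]]
}

#' Scale a count matrix for NMF
#'
#' Restricts to the supplied gene list and divides each gene row by its
#' standard deviation (unit variance, not centered, so non-negativity is
#' preserved). Zero-variance genes are dropped with a warning.
#'
#' @param counts genes x cells matrix.
#' @param genes character vector of gene identifiers (subset of rownames).
#' @return dense numeric matrix, `length(genes)` (minus dropped rows) x
#'   cells.
#' @export
scale_for_nmf <- function(counts, genes) {
  validate_counts(counts)
  if (length(genes) == 0) stop("empty gene list")
  if (!all(genes %in% rownames(counts))) stop("genes not present in counts")
  X <- as_dense(counts[genes, , drop = FALSE])
  mu <- rowMeans(X)
  sdv <- sqrt(pmax(rowMeans(X^2) - mu^2, 0))
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s) dropped before scaling")
    X <- X[!zero, , drop = FALSE]
    sdv <- sdv[!zero]
  }
  out <- X / sdv
  attr(out, "gene_sd") <- setNames(sdv, rownames(X))
  out
}

#' Split cells into two random halves
#'
#' The backbone of the reproducibility criterion: programs must be
#' re-discovered independently in both halves. Splitting is uniform over
#' cells (not stratified).
#'
#' @param n_cells number of cells, or a counts matrix.
#' @param seed integer seed.
#' @return an object of class `"split_pair"`: list with sorted integer
#'   index vectors `indices_a`, `indices_b` (disjoint, sizes differing by at
#'   most 1) and the `seed`.
#' @export
split_half <- function(n_cells, seed = 1L) {
  if (!is.null(dim(n_cells))) n_cells <- ncol(n_cells)
  stopifnot(n_cells >= 4)
  perm <- with_seed(seed, sample.int(n_cells))
  na <- ceiling(n_cells / 2)
  structure(list(indices_a = sort(perm[seq_len(na)]),
                 indices_b = sort(perm[(na + 1L):n_cells]),
                 seed = as.integer(seed)),
            class = "split_pair")
}

#' @export
print.split_pair <- function(x, ...) {
  cat("50/50 cell split: |A| =", length(x$indices_a),
      " |B| =", length(x$indices_b), " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
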