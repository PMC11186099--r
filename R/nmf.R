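#' Single NMF factorization
#'
#' Factorizes a non-negative matrix `X` (genes x cells) as `W H` by
#' multiplicative updates minimizing the Frobenius reconstruction error,
#' from a seeded random non-negative initialization. The objective sequence
#' is non-increasing; iteration stops when the relative change of the error
#' falls below `tol` or after `max_iter` updates.
#'
#' @param X non-negative numeric matrix, genes x cells.
#' @param k factorization rank, `1 <= k < min(dim(X))`.
#' @param seed integer seed for the initialization.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative-change stopping tolerance on the squared error.
#' @param trace_error if `TRUE`, keep the per-iteration objective values.
#' @return an object of class `"nmf_replicate"`: list with `W` (genes x k),
#'   `H` (k x cells), `frobenius_error`, `iterations`, `seed`, and
#'   optionally `error_trace` (squared errors).
#' @export
nmf_once <- function(X, k, seed = 1L, max_iter = 500L, tol = 1e-5,
                     trace_error = FALSE) {
  X <- as_dense(X)
  if (anyNA(X)) stop("NaN/NA in X")
  if (min(X) < 0) stop("X must be non-negative")
  if (k < 1 || k >= min(dim(X))) stop("k out of range")
  init <- with_seed(seed, {
    sc <- sqrt(mean(X) / k)
    list(W = matrix(runif(nrow(X) * k), nrow(X)) * sc,
         H = matrix(runif(k * ncol(X)), k) * sc)
  })
  res <- .nmf_mu_cpp(X, init$W, init$H, as.integer(max_iter), tol,
                     trace_error)
  rownames(res$W) <- rownames(X)
  colnames(res$H) <- colnames(X)
  res$seed <- as.integer(seed)
  if (!trace_error) res$error_trace <- NULL
  class(res) <- "nmf_replicate"
  res
}

#' @export
print.nmf_replicate <- function(x, ...) {
  cat("NMF replicate: ", nrow(x$W), " genes x ", ncol(x$H), " cells, k = ",
      ncol(x$W), ", Frobenius error ", signif(x$frobenius_error, 6),
      " (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}

#' Run many seeded NMF restarts
#'
#' @inheritParams nmf_once
#' @param n_restarts number of independent restarts (default 200, the
#'   full-scale convention; the scan path uses fewer).
#' @param seed master seed from which per-restart seeds are derived.
#' @return list of [nmf_once()] replicates, in deterministic order.
#' @export
nmf_restarts <- function(X, k, n_restarts = 200L, seed = 1L,
                         max_iter = 500L, tol = 1e-5) {
  stopifnot(n_restarts >= 2)
  seeds <- derive_seeds(seed, n_restarts, salt = "nmf_restarts")
  lapply(seeds, function(s) nmf_once(X, k, seed = s, max_iter = max_iter,
                                     tol = tol))
}

#' Filter outlier components across NMF restarts
#'
#' Pools the L2-normalized basis columns of all restarts, scores each by its
#' mean Euclidean distance to its `n_neighbors` nearest other components,
#' and removes the top `rate` fraction; isolated, non-reproducible
#' components are discarded before consensus clustering.
#'
#' @param components genes x n_components matrix of pooled, L2-normalized
#'   basis columns.
#' @param rate fraction removed (default 0.10).
#' @param n_neighbors neighborhood size for the isolation score.
#' @return list with `kept` (filtered component matrix), `kept_index`,
#'   `score` (per input component).
#' @export
filter_outlier_components <- function(components, rate = 0.10,
                                      n_neighbors = NULL) {
  nc <- ncol(components)
  if (nc < 2) stop("fewer than 2 components")
  stopifnot(rate >= 0, rate < 1)
  if (is.null(n_neighbors)) n_neighbors <- max(1L, floor(0.3 * nc))
  n_neighbors <- min(n_neighbors, nc - 1L)
  # squared distances via the Gram matrix of unit-norm columns
  Gm <- crossprod(components)
  nr2 <- diag(Gm)
  score <- vapply(seq_len(nc), function(i) {
    d2 <- pmax(nr2[i] + nr2 - 2 * Gm[i, ], 0)
    mean(sqrt(sort(d2[-i], partial = n_neighbors)[seq_len(n_neighbors)]))
  }, numeric(1))
  n_drop <- floor(rate * nc)
  keep <- rep(TRUE, nc)
  if (n_drop > 0) {
    ord <- order(-score, seq_len(nc))   # deterministic ties by index
    keep[ord[seq_len(n_drop)]] <- FALSE
  }
  list(kept = components[, keep, drop = FALSE],
       kept_index = which(keep), score = score)
}

# kmeans++ style greedy seeding of cluster centers (deterministic given the
# caller's RNG state).
kmeanspp_centers <- function(M, k) {
  n <- nrow(M)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((M - matrix(M[centers[1], ], n, ncol(M), byrow = TRUE))^2)
  for (i in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    if (all(!is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    centers[i + 1L] <- sample.int(n, 1L, prob = p)
    nd <- rowSums((M - matrix(M[centers[i + 1L], ], n, ncol(M),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  M[centers, , drop = FALSE]
}

#' Consensus basis from filtered components
#'
#' Clusters the kept L2-normalized components into `k` groups by seeded
#' k-means (greedy kmeans++ initialization) and takes the element-wise
#' median of each cluster, rescaled to unit L2 norm. Columns are ordered by
#' cluster size (decreasing), ties by cluster index.
#'
#' @param components genes x n_kept matrix of L2-normalized components.
#' @param k number of consensus programs.
#' @param seed integer seed for the clustering.
#' @return genes x k consensus basis matrix.
#' @export
consensus_components <- function(components, k, seed = 1L) {
  if (ncol(components) < k) stop("fewer than k components remain")
  M <- t(components)
  km <- try(with_seed(seed, {
    ctr <- kmeanspp_centers(M, k)
    kmeans(M, centers = ctr, iter.max = 50L)
  }), silent = TRUE)
  if (inherits(km, "try-error")) {
    km <- try(with_seed(seed + 1L, {
      ctr <- kmeanspp_centers(M, k)
      kmeans(M, centers = ctr, iter.max = 50L)
    }), silent = TRUE)
    if (inherits(km, "try-error"))
      stop("consensus clustering failed twice: ", attr(km, "condition")$message)
  }
  sizes <- tabulate(km$cluster, nbins = k)
  ordc <- order(-sizes, seq_len(k))
  W <- vapply(ordc, function(cl) {
    members <- components[, km$cluster == cl, drop = FALSE]
    apply(members, 1, median)
  }, numeric(nrow(components)))
  W <- l2_normalize_cols(W)
  rownames(W) <- rownames(components)
  colnames(W) <- sprintf("p%02d", seq_len(k))
  W
}

#' Refit program activities by non-negative least squares
#'
#' Per-cell NNLS of the expression profile against the consensus basis;
#' exact Lawson–Hanson solution, Gram matrix shared across cells.
#'
#' @param X genes x cells non-negative matrix.
#' @param W genes x k consensus basis.
#' @return k x cells non-negative activity matrix with an attribute
#'   `"residual"` (per-cell residual L2 norm).
#' @export
refit_activities <- function(X, W) {
  X <- as_dense(X)
  stopifnot(nrow(X) == nrow(W))
  if (qr(W)$rank < ncol(W))
    warning("rank-deficient consensus basis; NNLS solution may be non-unique")
  H <- .nnls_cols_cpp(W, X)
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(X)
  res <- sqrt(pmax(colSums(X^2) - 2 * colSums(H * crossprod(W, X)) +
                     colSums(H * (crossprod(W) %*% H)), 0))
  attr(H, "residual") <- res
  H
}

#' Z-score gene weights per program
#'
#' Each consensus basis column is centred and scaled by its population
#' standard deviation over genes; ranking within a column is preserved.
#'
#' @param W genes x k basis matrix (>= 2 genes).
#' @return matrix of the same shape with columns of mean 0, SD 1.
#' @export
zscore_weights <- function(W) {
  if (nrow(W) < 2) stop("need at least 2 genes")
  mu <- colMeans(W)
  sdv <- sqrt(colMeans(W^2) - mu^2)
  if (any(sdv == 0)) stop("zero-SD column in consensus basis")
  sweep(sweep(W, 2, mu, "-"), 2, sdv, "/")
}

#' Consensus NMF of one data split at one rank
#'
#' The cNMF-style consensus unit: many seeded restarts, outlier-component
#' filtering, k-means consensus, optional activity refit, Z-scored weights.
#'
#' @inheritParams nmf_once
#' @param n_restarts number of restarts.
#' @param filter_rate outlier filtering rate (default 0.10).
#' @param n_neighbors isolation-score neighborhood
#'   (default `0.3 * n_restarts`).
#' @param filter_level `"component"` (default) filters pooled components;
#'   `"replicate"` removes whole restarts whose components are jointly most
#'   isolated.
#' @param refit if `TRUE`, compute the consensus activity matrix by NNLS.
#' @return an object of class `"consensus_nmf"`: list with `k`,
#'   `W_consensus`, `Wz`, `H_consensus` (or `NULL`), `n_replicates_used`,
#'   `kept_component_fraction`.
#' @export
consensus_nmf <- function(X, k, n_restarts = 30L, seed = 1L,
                          max_iter = 200L, tol = 1e-5,
                          filter_rate = 0.10, n_neighbors = NULL,
                          filter_level = c("component", "replicate"),
                          refit = FALSE) {
  filter_level <- match.arg(filter_level)
  X <- as_dense(X)
  reps <- nmf_restarts(X, k, n_restarts = n_restarts, seed = seed,
                       max_iter = max_iter, tol = tol)
  if (is.null(n_neighbors)) n_neighbors <- max(1L, floor(0.3 * n_restarts))
  comps <- do.call(cbind, lapply(reps, function(r) r$W))
  comps <- l2_normalize_cols(comps)
  rownames(comps) <- rownames(X)
  if (filter_level == "component") {
    fl <- filter_outlier_components(comps, rate = filter_rate,
                                    n_neighbors = n_neighbors)
    kept <- fl$kept
  } else {
    fl <- filter_outlier_components(comps, rate = 0,
                                    n_neighbors = n_neighbors)
    rep_id <- rep(seq_along(reps), each = k)
    rep_score <- tapply(fl$score, rep_id, mean)
    n_drop <- floor(filter_rate * n_restarts)
    drop_reps <- if (n_drop > 0)
      order(-rep_score, seq_along(rep_score))[seq_len(n_drop)] else integer(0)
    kept <- comps[, !(rep_id %in% drop_reps), drop = FALSE]
  }
  W <- consensus_components(kept, k,
                            seed = derive_seeds(seed, 1L, "consensus"))
  H <- if (refit) refit_activities(X, W) else NULL
  structure(list(k = as.integer(k), W_consensus = W, Wz = zscore_weights(W),
                 H_consensus = H,
                 n_replicates_used = length(reps),
                 kept_component_fraction = ncol(kept) / ncol(comps)),
            class = "consensus_nmf")
}

#' @export
print.consensus_nmf <- function(x, ...) {
  cat("Consensus NMF: k = ", x$k, ", ", nrow(x$W_consensus), " genes, ",
      x$n_replicates_used, " restarts, ",
      round(100 * x$kept_component_fraction, 1),
      "% components kept\n", sep = "")
  invisible(x)
}
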