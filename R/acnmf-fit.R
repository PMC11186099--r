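#' Finalize reproducible programs at a chosen rank and Jaccard length
#'
#' Runs one fresh seeded 50/50 split, consensus-factorizes both halves at
#' rank `k`, matches programs across splits at Jaccard length `J`, detects
#' edge-betweenness communities, and averages the member consensus loadings
#' (raw scale) of each community into a final program, re-Z-scored.
#' Activities for all cells are refit by NNLS against the averaged weights.
#'
#' @inheritParams acnmf_scan
#' @param k chosen rank.
#' @param J chosen Jaccard length.
#' @param n_restarts NMF restarts per split.
#' @param max_iter,tol NMF solver settings (finalization default is tighter
#'   than the scan path).
#' @param average `"raw"` (default) averages raw unit-norm loadings then
#'   re-Z-scores; `"zscore"` averages the Z-scored weights directly.
#' @return list with `programs` (list: `gene_weights`, `Wz`, `activities`,
#'   `member_nodes`), `graph` (igraph), `membership`, `edges`, `split`,
#'   `k`, `J`, `n_communities`.
#' @export
finalize_programs <- function(X, k, J, seed = 1L, n_restarts = 30L,
                              alpha = 0.05, max_iter = 200L, tol = 1e-5,
                              filter_rate = 0.10,
                              average = c("raw", "zscore")) {
  average <- match.arg(average)
  X <- as_dense(X)
  stopifnot(k >= 1, J >= 1, J <= nrow(X))
  sp <- split_half(ncol(X), seed = derive_seeds(seed, 1L, "final_split"))
  sd2 <- derive_seeds(seed, 2L, "final_nmf")
  ca <- consensus_nmf(X[, sp$indices_a, drop = FALSE], k,
                      n_restarts = n_restarts, seed = sd2[1],
                      max_iter = max_iter, tol = tol,
                      filter_rate = filter_rate)
  cb <- consensus_nmf(X[, sp$indices_b, drop = FALSE], k,
                      n_restarts = n_restarts, seed = sd2[2],
                      max_iter = max_iter, tol = tol,
                      filter_rate = filter_rate)
  edges <- match_split_programs(ca$Wz, cb$Wz, J, alpha = alpha)
  cc <- count_communities(edges)
  if (cc$n_communities == 0)
    stop("no replicated program communities at k = ", k, ", J = ", J,
         "; the two splits share no significant program pair")

  node_w <- cbind(ca$W_consensus, cb$W_consensus)
  colnames(node_w) <- c(paste0("A/", colnames(ca$W_consensus)),
                        paste0("B/", colnames(cb$W_consensus)))
  node_z <- cbind(ca$Wz, cb$Wz)
  colnames(node_z) <- colnames(node_w)

  comm_ids <- sort(unique(cc$membership))
  members <- lapply(comm_ids, function(cm)
    names(cc$membership)[cc$membership == cm])
  gw_raw <- vapply(members, function(m)
    rowMeans(node_w[, m, drop = FALSE]), numeric(nrow(X)))
  rownames(gw_raw) <- rownames(X)
  colnames(gw_raw) <- sprintf("program_%02d", seq_along(members))
  gw <- if (average == "raw") gw_raw else {
    za <- vapply(members, function(m)
      rowMeans(node_z[, m, drop = FALSE]), numeric(nrow(X)))
    dimnames(za) <- dimnames(gw_raw)
    za
  }
  Wz <- zscore_weights(gw)
  # activities are always refit against the non-negative raw-average basis
  H <- refit_activities(X, gw_raw)
  rownames(H) <- colnames(gw)

  ed <- data.frame(from = paste0("A/", edges$prog_a),
                   to = paste0("B/", edges$prog_b),
                   jaccard_index = edges$jaccard_index,
                   p_adjusted = edges$p_adjusted,
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  igraph::V(g)$split <- substr(igraph::V(g)$name, 1, 1)
  igraph::V(g)$community <- as.integer(
    cc$membership[igraph::V(g)$name])

  list(programs = list(gene_weights = gw, Wz = Wz, activities = H,
                       member_nodes = setNames(members, colnames(gw))),
       graph = g, membership = cc$membership, edges = edges,
       split = sp, k = as.integer(k), J = as.integer(J),
       n_communities = cc$n_communities)
}

#' Automatic consensus NMF of a single-cell count matrix
#'
#' The package's central fitting function. Cells are (optionally
#' subsampled and) split in half at random; each half is consensus-NMF
#' factorized over a grid of ranks; programs recovered in both halves are
#' matched by an exact top-gene overlap test and reaggregated into
#' replicated communities. The rank is chosen at the inflection of the
#' replicated-community curve and the Jaccard length by the
#' post-inflection slope rule; final programs are community averages with
#' activities refit on all cells. Either parameter can also be fixed.
#'
#' @param counts genes x cells non-negative count matrix with identifiers
#'   as dimnames (dense or `Matrix`-sparse).
#' @param k factorization rank; `NULL` (default) selects it automatically
#'   from the scan.
#' @param jaccard_length top-gene set size for program matching; `NULL`
#'   selects it by the slope rule.
#' @param k_grid,j_grid scan grids (defaults follow the full-scale
#'   convention; pass smaller grids for desk-scale data).
#' @param n_hvg number of highly variable genes used for factorization.
#' @param max_cells cell cap before analysis (uniform subsample).
#' @param n_restarts NMF restarts per consensus factorization.
#' @param n_reps scan replicates (independent splits).
#' @param alpha Bonferroni-adjusted significance threshold for split
#'   matching.
#' @param seed master integer seed; every stochastic step derives from it.
#' @param scale_genes if `TRUE` (default), divide each HVG row by its
#'   standard deviation before NMF; `FALSE` factorizes raw HVG counts.
#' @param scan_max_iter,scan_tol,final_max_iter,final_tol NMF solver
#'   settings for the scan and finalization paths.
#' @param verbose print scan progress.
#' @return an object of class `"acnmf"`. Components include `chosen_k`,
#'   `chosen_J`, `scan` (an [acnmf_scan()] object, when a scan was run),
#'   `programs` (final gene weights `gene_weights`, Z-scores `Wz`,
#'   activities, member nodes), `graph`, `hvg`, `gene_sd`. Methods:
#'   [print.acnmf()], [summary.acnmf()], [coef.acnmf()], [predict.acnmf()],
#'   [fitted.acnmf()], [plot.acnmf()].
#' @export
acnmf <- function(counts, k = NULL, jaccard_length = NULL,
                  k_grid = seq(2L, 60L, by = 2L),
                  j_grid = c(10L, 20L, 30L, 50L, 100L, 150L, 200L),
                  n_hvg = 2000L, max_cells = 50000L,
                  n_restarts = 30L, n_reps = 3L, alpha = 0.05,
                  seed = 1L, scale_genes = TRUE,
                  scan_max_iter = 100L, scan_tol = 1e-4,
                  final_max_iter = 200L, final_tol = 1e-5,
                  verbose = FALSE) {
  cl <- match.call()
  validate_counts(counts)
  counts <- subsample_cells(counts, max_cells = max_cells,
                            seed = derive_seeds(seed, 1L, "subsample"))
  n_hvg <- min(n_hvg, nrow(counts))
  hvg <- select_hvg(counts, n_hvg = n_hvg)
  if (scale_genes) {
    X <- scale_for_nmf(counts, hvg)
    gene_sd <- attr(X, "gene_sd")
  } else {
    X <- as_dense(counts[hvg, , drop = FALSE])
    gene_sd <- setNames(rep(1, nrow(X)), rownames(X))
  }

  scan <- NULL
  if (is.null(k) || is.null(jaccard_length)) {
    scan <- acnmf_scan(X, k_grid = k_grid, j_grid = pmin(j_grid, nrow(X)),
                       n_reps = n_reps, n_restarts = n_restarts,
                       seed = derive_seeds(seed, 1L, "scan"),
                       alpha = alpha, max_iter = scan_max_iter,
                       tol = scan_tol, verbose = verbose)
    if (is.null(jaccard_length)) jaccard_length <- scan$chosen_J
    if (is.null(k)) k <- scan$curves[[as.character(jaccard_length)]]$k_star
  }

  fin <- finalize_programs(X, k = k, J = jaccard_length,
                           seed = derive_seeds(seed, 1L, "finalize"),
                           n_restarts = n_restarts, alpha = alpha,
                           max_iter = final_max_iter, tol = final_tol)

  structure(list(call = cl, chosen_k = as.integer(k),
                 chosen_J = as.integer(jaccard_length),
                 scan = scan, programs = fin$programs, graph = fin$graph,
                 membership = fin$membership, edges = fin$edges,
                 split = fin$split, n_programs = fin$n_communities,
                 hvg = rownames(X), gene_sd = gene_sd,
                 n_cells = ncol(counts), n_genes = nrow(counts),
                 alpha = alpha, seed = as.integer(seed)),
            class = "acnmf")
}

#' @export
print.acnmf <- function(x, ...) {
  cat("acNMF fit\n")
  cat("  data: ", x$n_genes, " genes x ", x$n_cells, " cells (",
      length(x$hvg), " HVGs used)\n", sep = "")
  cat("  rank k = ", x$chosen_k, ", Jaccard length J = ", x$chosen_J,
      if (!is.null(x$scan)) " (selected automatically)" else " (fixed)",
      "\n", sep = "")
  cat("  ", x$n_programs,
      " reproducible gene expression program(s) recovered\n", sep = "")
  invisible(x)
}

#' Summary of an acNMF fit
#'
#' @param object an `"acnmf"` object.
#' @param n_top number of top genes to display per program.
#' @param ... unused.
#' @export
summary.acnmf <- function(object, n_top = 5, ...) {
  print(object)
  cat("\nTop genes per program (by Z-scored weight):\n")
  for (p in colnames(object$programs$Wz)) {
    tg <- top_genes(object$programs$Wz[, p], n_top)
    cat("  ", p, ": ", paste(tg, collapse = ", "),
        "  [", length(object$programs$member_nodes[[p]]),
        " member nodes]\n", sep = "")
  }
  h <- object$programs$activities
  cat("\nActivity summary (h):\n")
  print(signif(t(apply(h, 1, quantile, c(0.5, 0.9, 1))), 3))
  invisible(object)
}

#' Extract program gene weights
#'
#' @param object an `"acnmf"` object.
#' @param type `"weights"` for the community-averaged raw loadings,
#'   `"zscore"` for their per-program Z-scores.
#' @param ... unused.
#' @return genes x programs matrix.
#' @export
coef.acnmf <- function(object, type = c("weights", "zscore"), ...) {
  type <- match.arg(type)
  if (type == "weights") object$programs$gene_weights else object$programs$Wz
}

#' Program activities for new cells
#'
#' Scales the new counts with the gene standard deviations learned at fit
#' time and refits activities by NNLS against the final program weights.
#'
#' @param object an `"acnmf"` object.
#' @param newdata genes x cells count matrix covering the fit's HVGs; if
#'   omitted, the activities of the training cells are returned.
#' @param ... unused.
#' @return programs x cells activity matrix.
#' @export
predict.acnmf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$programs$activities)
  if (!all(object$hvg %in% rownames(newdata)))
    stop("newdata must contain all genes used at fit time")
  X <- as_dense(newdata[object$hvg, , drop = FALSE])
  X <- X / object$gene_sd[object$hvg]
  refit_activities(X, object$programs$gene_weights)
}

#' @export
fitted.acnmf <- function(object, ...) {
  object$programs$gene_weights %*% object$programs$activities
}

#' Plot the community curves of an acNMF fit
#'
#' @param x an `"acnmf"` object with a scan component.
#' @param ... passed to [plot.acnmf_scan()].
#' @export
plot.acnmf <- function(x, ...) {
  if (is.null(x$scan)) {
    graphics::barplot(sort(igraph::degree(x$graph), decreasing = TRUE),
                      las = 2, ylab = "node degree",
                      main = "split-program graph")
    return(invisible(x))
  }
  plot(x$scan, ...)
  invisible(x)
}

#' Count ground-truth programs recovered by a fit
#'
#' Bipartite significance matching between final programs and ground-truth
#' gene sets: every program/truth pair is tested for top-`J` overlap with
#' the exact hypergeometric test, Bonferroni-corrected over all pairs; a
#' truth program counts as recovered when at least one final program
#' matches it.
#'
#' @param programs an `"acnmf"` object, or a genes x programs matrix of
#'   Z-scored weights.
#' @param truth_sets list of character vectors (e.g.
#'   [truth_gene_sets()]); genes outside the program universe are dropped.
#' @param J Jaccard length for the program top-gene sets.
#' @param alpha adjusted-significance threshold.
#' @return integer count of recovered truth sets, with attributes
#'   `"recovered"` (named logical) and `"p_adjusted"` (programs x truth
#'   matrix).
#' @export
match_to_truth <- function(programs, truth_sets, J, alpha = 0.05) {
  Wz <- if (inherits(programs, "acnmf")) programs$programs$Wz else programs
  universe <- rownames(Wz)
  G <- length(universe)
  J <- min(J, G)
  orders <- top_gene_orders(Wz)
  psets <- lapply(orders, function(o) o[seq_len(J)])
  tsets <- lapply(truth_sets, function(s) intersect(s, universe))
  n_comp <- length(psets) * length(tsets)
  padj <- matrix(1, length(psets), length(tsets),
                 dimnames = list(colnames(Wz), names(truth_sets)))
  for (i in seq_along(psets)) {
    for (j in seq_along(tsets)) {
      if (length(tsets[[j]]) == 0) next
      jt <- jaccard_test(psets[[i]], tsets[[j]], G, n_comparisons = n_comp)
      padj[i, j] <- jt$p_adjusted
    }
  }
  rec <- apply(padj, 2, function(p) any(p < alpha))
  structure(sum(rec), recovered = rec, p_adjusted = padj)
}
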