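#' Top-weighted genes of a program
#'
#' The "Jaccard length" `J` top genes of a Z-scored weight vector; ties at
#' the boundary are broken by gene identifier (lexicographically smaller
#' kept), so the set is deterministic across runs.
#'
#' @param w named numeric vector of (Z-scored) gene weights.
#' @param J set size, `1 <= J <= length(w)`.
#' @return character vector of `J` gene identifiers.
#' @export
top_genes <- function(w, J) {
  if (J <= 0) stop("J must be positive")
  if (J > length(w)) stop("J exceeds the number of genes")
  if (is.null(names(w))) stop("weights must be named by gene")
  names(w)[order(-w, names(w))][seq_len(J)]
}

# Per-column top-gene orderings of a Z-scored weight matrix; any J is then
# a prefix, so one ordering serves the whole Jaccard-length grid.
top_gene_orders <- function(Wz) {
  ids <- rownames(Wz)
  lapply(seq_len(ncol(Wz)), function(j) ids[order(-Wz[, j], ids)])
}

#' Exact Jaccard overlap significance test
#'
#' Tests whether two fixed-size gene sets drawn from a common universe of
#' `universe_size` genes overlap more than chance: the upper-tail
#' probability `P(X >= |A intersect B|)` for
#' `X ~ Hypergeometric(universe_size, |A|, |B|)`. The exact tail replaces
#' asymptotic approximations of the Jaccard-test literature; under the null
#' of independent fixed-size draws the two order instances identically.
#'
#' @param A,B character vectors (gene sets) from the same universe.
#' @param universe_size number of genes in the universe
#'   (`>= |A union B|`).
#' @param n_comparisons Bonferroni family size used to fill `p_adjusted`.
#' @return object of class `"jaccard_test"`: list with `set_size_a`,
#'   `set_size_b`, `universe_size`, `intersection`, `jaccard_index`,
#'   `p_raw`, `p_adjusted`.
#' @export
jaccard_test <- function(A, B, universe_size, n_comparisons = 1L) {
  A <- unique(A); B <- unique(B)
  if (length(A) < 1 || length(B) < 1) stop("empty gene set")
  u <- length(union(A, B))
  if (universe_size < u) stop("universe smaller than |A union B|")
  i <- length(intersect(A, B))
  p <- phyper(i - 1L, length(A), universe_size - length(A), length(B),
              lower.tail = FALSE)
  structure(list(set_size_a = length(A), set_size_b = length(B),
                 universe_size = as.integer(universe_size),
                 intersection = i,
                 jaccard_index = i / u,
                 p_raw = p,
                 p_adjusted = min(1, p * n_comparisons)),
            class = "jaccard_test")
}

#' @export
print.jaccard_test <- function(x, ...) {
  cat("Jaccard overlap test: |A| = ", x$set_size_a, ", |B| = ",
      x$set_size_b, ", universe ", x$universe_size,
      "\n  intersection ", x$intersection,
      ", index ", signif(x$jaccard_index, 4),
      ", p = ", signif(x$p_raw, 4),
      " (adjusted ", signif(x$p_adjusted, 4), ")\n", sep = "")
  invisible(x)
}

#' Match programs between the two data splits
#'
#' All `k_a x k_b` cross-split program pairs are tested for top-`J` gene-set
#' overlap with [jaccard_test()]; p-values are Bonferroni-corrected over the
#' `k_a x k_b` family and pairs with adjusted p below `alpha` become edges.
#'
#' @param Wz_a,Wz_b Z-scored weight matrices (same gene universe as
#'   rownames).
#' @param J Jaccard length (top-gene set size).
#' @param alpha significance threshold on the adjusted p-value.
#' @return data.frame of edges: `prog_a`, `prog_b`, `intersection`,
#'   `jaccard_index`, `p_raw`, `p_adjusted` (possibly zero rows).
#' @export
match_split_programs <- function(Wz_a, Wz_b, J, alpha = 0.05) {
  if (!identical(rownames(Wz_a), rownames(Wz_b)))
    stop("mismatched gene universes between splits")
  G <- nrow(Wz_a)
  if (J > G) stop("J exceeds the number of genes in the universe")
  orders_a <- top_gene_orders(Wz_a)
  orders_b <- top_gene_orders(Wz_b)
  ka <- ncol(Wz_a); kb <- ncol(Wz_b)
  n_comp <- ka * kb
  sets_a <- lapply(orders_a, function(o) o[seq_len(J)])
  sets_b <- lapply(orders_b, function(o) o[seq_len(J)])
  rows <- vector("list", n_comp)
  r <- 0L
  for (i in seq_len(ka)) {
    for (j in seq_len(kb)) {
      jt <- jaccard_test(sets_a[[i]], sets_b[[j]], G,
                         n_comparisons = n_comp)
      if (jt$p_adjusted < alpha) {
        r <- r + 1L
        rows[[r]] <- data.frame(
          prog_a = colnames(Wz_a)[i] %||% paste0("p", i),
          prog_b = colnames(Wz_b)[j] %||% paste0("p", j),
          intersection = jt$intersection,
          jaccard_index = jt$jaccard_index,
          p_raw = jt$p_raw, p_adjusted = jt$p_adjusted,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (r == 0L)
    return(data.frame(prog_a = character(), prog_b = character(),
                      intersection = integer(), jaccard_index = numeric(),
                      p_raw = numeric(), p_adjusted = numeric()))
  do.call(rbind, rows[seq_len(r)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count replicated-program communities
#'
#' Builds an undirected graph whose nodes are split programs incident to at
#' least one significant cross-split edge, detects communities by
#' Girvan–Newman edge betweenness with the dendrogram cut at maximum
#' modularity, and returns the community count. Programs with no edge never
#' enter the graph.
#'
#' @param edges edge data.frame as from [match_split_programs()]; `prog_a`
#'   and `prog_b` are prefixed internally so the two splits cannot collide.
#' @return list with `n_communities` and `membership` (named integer
#'   vector; empty when there are no edges).
#' @export
count_communities <- function(edges) {
  if (nrow(edges) == 0)
    return(list(n_communities = 0L, membership = integer(0)))
  ed <- data.frame(from = paste0("A/", edges$prog_a),
                   to = paste0("B/", edges$prog_b),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL)
  memb <- igraph::membership(cl)
  list(n_communities = length(unique(memb)),
       membership = setNames(as.integer(memb), names(memb)))
}
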