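#' Bundle a dataset's programs for cross-dataset comparison
#'
#' @param dataset_id short unique label for the dataset.
#' @param weights genes x programs matrix of (Z-scored) gene weights with
#'   gene identifiers as rownames.
#' @param tuned_J the Jaccard length tuned for this dataset (see
#'   [acnmf()]); used as its top-gene set size in the asymmetric test.
#' @return object of class `"program_catalog"`.
#' @export
program_catalog <- function(dataset_id, weights, tuned_J) {
  stopifnot(is.character(dataset_id), length(dataset_id) == 1L,
            !is.null(rownames(weights)), tuned_J >= 1,
            tuned_J <= nrow(weights))
  if (is.null(colnames(weights)))
    colnames(weights) <- sprintf("p%02d", seq_len(ncol(weights)))
  if (anyDuplicated(colnames(weights))) stop("duplicate program ids")
  structure(list(dataset_id = dataset_id, weights = weights,
                 tuned_J = as.integer(tuned_J),
                 universe = rownames(weights)),
            class = "program_catalog")
}

#' Significant cross-dataset program edges
#'
#' For every pair of programs from two different catalogs, takes each
#' program's top `tuned_J` genes (the per-dataset set sizes may differ —
#' the test is asymmetric), restricts both to the pair's shared gene
#' universe, and applies the exact hypergeometric overlap test. Bonferroni
#' correction runs over all cross-dataset pairs; edges are kept at
#' family-wise error below `alpha_fwer`.
#'
#' @param catalogs list of [program_catalog()] objects (>= 2).
#' @param alpha_fwer family-wise error threshold (default 0.05; 0.01 for a
#'   stricter graph).
#' @return data.frame of edges: `dataset_a`, `prog_a`, `dataset_b`,
#'   `prog_b`, `intersection`, `jaccard_index`, `p_raw`, `p_adjusted`.
#' @export
cross_edges <- function(catalogs, alpha_fwer = 0.05) {
  stopifnot(length(catalogs) >= 2)
  ids <- vapply(catalogs, function(ct) ct$dataset_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate dataset ids")
  orders <- lapply(catalogs, function(ct) top_gene_orders(ct$weights))
  pairs <- combn(length(catalogs), 2)
  n_comp <- 0L
  for (p in seq_len(ncol(pairs)))
    n_comp <- n_comp + ncol(catalogs[[pairs[1, p]]]$weights) *
      ncol(catalogs[[pairs[2, p]]]$weights)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    shared <- intersect(catalogs[[a]]$universe, catalogs[[b]]$universe)
    if (length(shared) == 0) stop("empty shared gene universe for pair ",
                                  ids[a], " / ", ids[b])
    G <- length(shared)
    sets_a <- lapply(orders[[a]], function(o)
      head(intersect(o, shared), catalogs[[a]]$tuned_J))
    sets_b <- lapply(orders[[b]], function(o)
      head(intersect(o, shared), catalogs[[b]]$tuned_J))
    for (i in seq_along(sets_a)) {
      for (j in seq_along(sets_b)) {
        jt <- jaccard_test(sets_a[[i]], sets_b[[j]], G,
                           n_comparisons = n_comp)
        if (jt$p_adjusted < alpha_fwer)
          rows[[length(rows) + 1L]] <- data.frame(
            dataset_a = ids[a],
            prog_a = colnames(catalogs[[a]]$weights)[i],
            dataset_b = ids[b],
            prog_b = colnames(catalogs[[b]]$weights)[j],
            intersection = jt$intersection,
            jaccard_index = jt$jaccard_index,
            p_raw = jt$p_raw, p_adjusted = jt$p_adjusted,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(dataset_a = character(), prog_a = character(),
                      dataset_b = character(), prog_b = character(),
                      intersection = integer(), jaccard_index = numeric(),
                      p_raw = numeric(), p_adjusted = numeric()))
  do.call(rbind, rows)
}

#' Assemble the cross-dataset program graph
#'
#' Nodes are all programs of all catalogs (`dataset::program`); edges are
#' the significant cross-dataset matches. Node attributes record dataset,
#' program id and degree.
#'
#' @param catalogs list of [program_catalog()] objects.
#' @param edges edge data.frame from [cross_edges()] (computed here when
#'   omitted).
#' @param alpha_fwer passed to [cross_edges()] when `edges` is missing.
#' @return an `igraph` object.
#' @export
build_program_graph <- function(catalogs, edges = NULL, alpha_fwer = 0.05) {
  if (is.null(edges)) edges <- cross_edges(catalogs, alpha_fwer)
  nodes <- do.call(rbind, lapply(catalogs, function(ct)
    data.frame(name = paste0(ct$dataset_id, "::", colnames(ct$weights)),
               dataset = ct$dataset_id,
               program = colnames(ct$weights),
               stringsAsFactors = FALSE)))
  ed <- if (nrow(edges)) data.frame(
    from = paste0(edges$dataset_a, "::", edges$prog_a),
    to = paste0(edges$dataset_b, "::", edges$prog_b),
    jaccard_index = edges$jaccard_index,
    p_adjusted = edges$p_adjusted,
    stringsAsFactors = FALSE)
  else data.frame(from = character(), to = character(),
                  jaccard_index = numeric(), p_adjusted = numeric())
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
  igraph::V(g)$degree <- igraph::degree(g)
  g
}

#' Random-walk communities of the program graph
#'
#' Walktrap agglomeration cut at maximum modularity, applied to the
#' subgraph of connected nodes; isolated programs receive singleton labels.
#'
#' @param graph an `igraph` program graph.
#' @param walk_steps random-walk length (default 4).
#' @param seed integer seed.
#' @return named integer vector of community labels for all nodes.
#' @export
detect_graph_communities <- function(graph, walk_steps = 4, seed = 1L) {
  deg <- igraph::degree(graph)
  labels <- setNames(rep(NA_integer_, igraph::vcount(graph)),
                     igraph::V(graph)$name)
  connected <- names(deg)[deg > 0]
  n_comm <- 0L
  if (length(connected)) {
    sub <- igraph::induced_subgraph(graph, connected)
    cl <- with_seed(seed,
                    igraph::cluster_walktrap(sub, steps = walk_steps))
    memb <- igraph::membership(cl)
    labels[names(memb)] <- as.integer(memb)
    n_comm <- max(memb)
  }
  iso <- which(is.na(labels))
  if (length(iso)) labels[iso] <- n_comm + seq_along(iso)
  labels
}

#' Force-directed layout of the program graph
#'
#' Seeded Fruchterman–Reingold layout; deterministic given the seed. A
#' single node is placed at the origin.
#'
#' @param graph an `igraph` object (>= 1 node).
#' @param seed integer seed.
#' @param iterations FR iterations.
#' @return matrix of node coordinates (n x 2, rownames = node names).
#' @export
layout_graph <- function(graph, seed = 1L, iterations = 500) {
  stopifnot(igraph::vcount(graph) >= 1)
  if (igraph::vcount(graph) == 1L)
    return(matrix(0, 1, 2, dimnames = list(igraph::V(graph)$name,
                                           c("x", "y"))))
  xy <- with_seed(seed, igraph::layout_with_fr(graph, niter = iterations))
  dimnames(xy) <- list(igraph::V(graph)$name, c("x", "y"))
  xy
}

#' Export / import a program graph
#'
#' GraphML preserves all node and edge attributes losslessly; the JSON
#' schema (`nodes`, `edges`, attribute fields) targets web front ends.
#'
#' @param graph an `igraph` object; node attributes may include community
#'   labels and layout coordinates.
#' @param path output file.
#' @param format `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    va <- igraph::vertex_attr(graph)
    nodes <- as.data.frame(va, stringsAsFactors = FALSE)
    ed <- igraph::as_data_frame(graph, what = "edges")
    jsonlite::write_json(list(nodes = nodes, edges = ed), path,
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  ed <- as.data.frame(obj$edges, stringsAsFactors = FALSE)
  if (nrow(ed) == 0)
    ed <- data.frame(from = character(), to = character())
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
}
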