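#' Read marker gene sets from a two-column TSV
#'
#' Expected columns: set name, gene symbol (header optional via
#' `header`). Single-set files with one symbol per line are also accepted.
#'
#' @param path TSV file.
#' @param header whether the file has a header row.
#' @return named list of unique gene symbol vectors.
#' @export
read_marker_sets <- function(path, header = TRUE) {
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) == 1L)
    return(setNames(list(unique(tab[[1L]])),
                    sub("\\.[^.]+$", "", basename(path))))
  lapply(split(tab[[2L]], tab[[1L]]), unique)
}

#' Marker-set enrichment on program gene weights
#'
#' One-sided Wilcoxon rank-sum test of the marker genes' weights against
#' all other genes' weights in the same program: high marker ranks mean the
#' program expresses the signature. Exact when the smaller group has at
#' most 20 genes and there are no ties; normal approximation with tie
#' correction otherwise. Rank-based, hence invariant to monotone
#' transformations of the weights.
#'
#' @param w named numeric vector of (Z-scored) gene weights for one
#'   program.
#' @param markers character vector of marker gene symbols; symbols absent
#'   from the weight universe are dropped (count reported).
#' @param alternative `"greater"` (default: markers ranked higher) or
#'   `"less"`.
#' @return list with `p_one_sided`, `n_markers_in_universe`,
#'   `n_markers_dropped`, `direction`, `statistic` (Mann–Whitney U).
#' @export
ranksum_enrichment <- function(w, markers, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.null(names(w))) stop("weights must be named by gene")
  present <- intersect(unique(markers), names(w))
  if (length(present) == 0) stop("no marker genes in the weight universe")
  if (length(present) == length(w)) stop("all genes are markers")
  is_m <- names(w) %in% present
  exact <- min(sum(is_m), sum(!is_m)) <= 20 && !any(duplicated(w))
  ht <- suppressWarnings(
    wilcox.test(w[is_m], w[!is_m], alternative = alternative,
                exact = exact, correct = !exact))
  list(p_one_sided = ht$p.value,
       n_markers_in_universe = length(present),
       n_markers_dropped = length(unique(markers)) - length(present),
       direction = alternative,
       statistic = unname(ht$statistic))
}

#' Enrichment of many marker sets across all programs
#'
#' Applies [ranksum_enrichment()] to every program/set pair; raw one-sided
#' p-values are reported alongside Benjamini–Hochberg adjustment within
#' each program.
#'
#' @param Wz genes x programs matrix of Z-scored weights.
#' @param marker_sets named list of marker gene vectors.
#' @param alternative passed to [ranksum_enrichment()].
#' @return data.frame: `program`, `set`, `p`, `p_bh`,
#'   `n_markers_in_universe`, `n_markers_dropped`.
#' @export
enrich_programs <- function(Wz, marker_sets, alternative = "greater") {
  out <- list()
  for (p in colnames(Wz)) {
    w <- setNames(Wz[, p], rownames(Wz))
    res <- lapply(names(marker_sets), function(s) {
      r <- ranksum_enrichment(w, marker_sets[[s]], alternative)
      data.frame(program = p, set = s, p = r$p_one_sided,
                 n_markers_in_universe = r$n_markers_in_universe,
                 n_markers_dropped = r$n_markers_dropped,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_bh <- stats::p.adjust(res$p, method = "BH")
    out[[p]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Cells highly expressing a program
#'
#' Strict threshold: a cell qualifies when its activity exceeds `h_min`
#' (cells exactly at the threshold are excluded). The conventions are
#' `h_min = 50` for annotation displays and `h_min = 100` for classifier
#' labeling.
#'
#' @param H programs x cells activity matrix.
#' @param program program row name or index.
#' @param h_min activity threshold.
#' @return character vector of cell identifiers.
#' @export
high_activity_cells <- function(H, program, h_min) {
  h <- H[program, ]
  colnames(H)[h > h_min]
}

#' Mean signature expression in selected cells
#'
#' Per-cell mean of normalized expression over the signature genes present
#' in the data, with the background mean over all other genes; the basis of
#' signature-vs-background comparisons in highly expressing cells.
#'
#' @param expr genes x cells count matrix.
#' @param cells cell identifiers to evaluate (non-empty).
#' @param signature character vector of signature genes (must intersect
#'   the universe).
#' @param normalize `"lognorm"` (default; `log1p` of depth-normalized
#'   counts scaled to 1e4) or `"raw"`.
#' @return data.frame: `cell`, `signature_mean`, `background_mean`.
#' @export
signature_mean_expression <- function(expr, cells, signature,
                                      normalize = c("lognorm", "raw")) {
  normalize <- match.arg(normalize)
  if (length(cells) == 0) stop("empty cell set")
  sig <- intersect(signature, rownames(expr))
  if (length(sig) == 0) stop("signature does not intersect the universe")
  X <- as_dense(expr[, cells, drop = FALSE])
  if (normalize == "lognorm") {
    depth <- colSums(X); depth[depth == 0] <- 1
    X <- log1p(sweep(X, 2, 1e4 / depth, "*"))
  }
  in_sig <- rownames(X) %in% sig
  data.frame(cell = cells,
             signature_mean = colMeans(X[in_sig, , drop = FALSE]),
             background_mean = if (all(in_sig))
               colMeans(X) else colMeans(X[!in_sig, , drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Program co-expression across cells
#'
#' Spearman correlation of program activities; constant rows yield missing
#' values with a warning.
#'
#' @param H programs x cells activity matrix (>= 2 programs).
#' @return programs x programs correlation matrix with unit diagonal.
#' @export
program_coexpression <- function(H) {
  if (nrow(H) < 2) stop("need at least 2 programs")
  const <- apply(H, 1, function(r) max(r) == min(r))
  if (any(const))
    warning("constant activity for program(s): ",
            paste(rownames(H)[const], collapse = ", "),
            "; correlations reported as NA")
  cc <- suppressWarnings(cor(t(H), method = "spearman"))
  diag(cc) <- 1
  cc
}
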