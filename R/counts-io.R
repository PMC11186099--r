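#' Validate a genes x cells count matrix
#'
#' The package represents counts as an ordinary (or `Matrix`-sparse) numeric
#' matrix oriented genes x cells, with unique gene identifiers as rownames
#' and unique cell identifiers as colnames.
#'
#' @param counts matrix-like object to validate.
#' @return the input, invisibly, if valid; otherwise an error.
#' @export
validate_counts <- function(counts) {
  if (is.null(dim(counts)) || length(dim(counts)) != 2L)
    stop("counts must be a two-dimensional matrix")
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("counts must have at least 2 genes and 2 cells")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene identifiers (rownames) and cell identifiers (colnames)")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell identifiers")
  mn <- if (inherits(counts, "sparseMatrix")) min(counts@x, 0) else min(counts)
  if (is.na(mn)) stop("counts contain missing values")
  if (mn < 0) stop("counts contain negative entries")
  invisible(counts)
}

#' Read a count matrix from disk
#'
#' Supports the 10x convention (a directory with `matrix.mtx`, `genes.tsv`
#' and `barcodes.tsv`, matrix stored genes x barcodes) and a dense TSV with
#' gene identifiers in the first column and cell identifiers as the header.
#'
#' @param path directory (for `mtx_dir`) or file (for `dense_tsv`).
#' @param format one of `"mtx_dir"`, `"dense_tsv"`.
#' @return a genes x cells matrix with identifiers as dimnames (sparse
#'   `dgCMatrix` for `mtx_dir`, dense for `dense_tsv`).
#' @export
read_counts <- function(path, format = c("mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mtx)
    genes <- read.delim(gf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    cells <- read.delim(bf, header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (length(genes) != nrow(m))
      stop("genes.tsv has ", length(genes), " entries but matrix has ",
           nrow(m), " rows")
    if (length(cells) != ncol(m))
      stop("barcodes.tsv has ", length(cells), " entries but matrix has ",
           ncol(m), " columns")
    m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
    dimnames(m) <- list(genes, cells)
  } else {
    tab <- read.delim(path, header = TRUE, row.names = 1L, check.names = FALSE)
    m <- as.matrix(tab)
  }
  validate_counts(m)
  m
}

#' Write a count matrix to disk
#'
#' @param counts genes x cells matrix with dimnames.
#' @param path output directory (`mtx_dir`) or file (`dense_tsv`).
#' @param format see [read_counts()].
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  validate_counts(counts)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                 "CsparseMatrix"), "generalMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(rownames(counts), file.path(path, "genes.tsv"))
    writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  } else {
    write.table(as_dense(counts), path, sep = "\t", quote = FALSE,
                col.names = NA)
  }
  invisible(path)
}
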