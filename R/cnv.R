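#' Genomic bins of consecutive genes
#'
#' Sorts genes by (chromosome, start) and groups each chromosome's genes
#' into consecutive non-overlapping bins of `bin_size`. A trailing partial
#' bin is kept as its own bin when it holds at least `bin_size / 2` genes
#' and merged into the previous bin otherwise. Bins never span
#' chromosomes.
#'
#' @param gene_coords data.frame with columns `gene_id`, `chrom`, `start`.
#' @param bin_size genes per bin (default 50).
#' @return object of class `"genomic_bins"`: list with `bins` (named list
#'   of gene id vectors) and `map` (data.frame `gene_id`, `bin`).
#' @export
build_bins <- function(gene_coords, bin_size = 50) {
  stopifnot(all(c("gene_id", "chrom", "start") %in% names(gene_coords)))
  if (anyDuplicated(gene_coords$gene_id))
    stop("duplicate gene coordinates for the same gene id")
  if (nrow(gene_coords) < bin_size)
    stop("need coordinates for at least bin_size genes")
  gc <- gene_coords[order(gene_coords$chrom, gene_coords$start,
                          gene_coords$gene_id), ]
  bins <- list()
  for (ch in unique(gc$chrom)) {
    genes <- gc$gene_id[gc$chrom == ch]
    n <- length(genes)
    n_full <- n %/% bin_size
    rem <- n %% bin_size
    if (n_full == 0) {                 # chromosome shorter than one bin
      bins[[paste0(ch, "_bin01")]] <- genes
      next
    }
    idx <- split(genes[seq_len(n_full * bin_size)],
                 rep(seq_len(n_full), each = bin_size))
    if (rem > 0) {
      tail_genes <- genes[(n_full * bin_size + 1L):n]
      if (rem >= bin_size / 2) idx[[length(idx) + 1L]] <- tail_genes
      else idx[[length(idx)]] <- c(idx[[length(idx)]], tail_genes)
    }
    names(idx) <- sprintf("%s_bin%02d", ch, seq_along(idx))
    bins <- c(bins, idx)
  }
  map <- data.frame(gene_id = unlist(bins, use.names = FALSE),
                    bin = rep(names(bins), lengths(bins)),
                    stringsAsFactors = FALSE)
  structure(list(bins = bins, map = map, bin_size = as.integer(bin_size)),
            class = "genomic_bins")
}

#' Copy-number-like expression features
#'
#' The "manual features" of the cancer/normal classifier: per gene,
#' `log(TPM-like + 1)` expression is standardized against the
#' reference-cell mean and standard deviation, clipped to `[-3, 3]`, and
#' averaged within each genomic bin. Cells resembling the reference score
#' near zero everywhere; copy-number gains and losses shift whole bins.
#'
#' @param expr genes x cells count matrix.
#' @param bins a [build_bins()] object.
#' @param reference_cells identifiers of reference (normal) cells.
#' @param scale_factor depth-normalization target (default 1e6, TPM-like).
#' @return cells x bins numeric matrix; genes with zero reference SD are
#'   dropped (count in attribute `"n_dropped_genes"`).
#' @export
cnv_features <- function(expr, bins, reference_cells, scale_factor = 1e6) {
  stopifnot(inherits(bins, "genomic_bins"))
  if (length(reference_cells) == 0) stop("reference_cells is empty")
  if (!all(reference_cells %in% colnames(expr)))
    stop("reference cells absent from the expression matrix")
  X <- as_dense(expr)
  depth <- colSums(X); depth[depth == 0] <- 1
  L <- log1p(sweep(X, 2, scale_factor / depth, "*"))
  mu <- rowMeans(L[, reference_cells, drop = FALSE])
  sdv <- apply(L[, reference_cells, drop = FALSE], 1, sd)
  ok <- sdv > 0
  n_drop <- sum(!ok)
  Z <- (L[ok, , drop = FALSE] - mu[ok]) / sdv[ok]
  Z <- pmin(pmax(Z, -3), 3)
  feat <- vapply(bins$bins, function(g) {
    g <- intersect(g, rownames(Z))
    if (length(g) == 0) return(rep(NA_real_, ncol(Z)))
    colMeans(Z[g, , drop = FALSE])
  }, numeric(ncol(Z)))
  rownames(feat) <- colnames(Z)
  feat <- feat[, colSums(is.na(feat)) == 0, drop = FALSE]
  attr(feat, "n_dropped_genes") <- n_drop
  feat
}

#' Label cells from program activities
#'
#' A cell is labeled with the class of the annotated program it expresses
#' above `h_min` (strict); cells passing the threshold for programs of more
#' than one class become `unlabeled` with a warning, as do cells passing
#' none.
#'
#' @param H programs x cells activity matrix.
#' @param program_annotations named character vector mapping program ids to
#'   classes in `{"cancer", "immune", "endothelial", "ambiguous_mes"}`.
#' @param h_min activity threshold (default 100).
#' @return object of class `"cell_labels"`: named factor over cells with
#'   levels cancer/immune/endothelial/ambiguous_mes/unlabeled and attribute
#'   `"h_min"`.
#' @export
assign_labels <- function(H, program_annotations, h_min = 100) {
  classes <- c("cancer", "immune", "endothelial", "ambiguous_mes")
  if (!all(program_annotations %in% classes))
    stop("annotations must map to ", paste(classes, collapse = "/"))
  unknown <- setdiff(names(program_annotations), rownames(H))
  if (length(unknown))
    stop("annotation references unknown program(s): ",
         paste(unknown, collapse = ", "))
  lab <- rep("unlabeled", ncol(H))
  n_conflict <- 0L
  for (ci in seq_len(ncol(H))) {
    hit <- unique(program_annotations[
      H[names(program_annotations), ci] > h_min])
    if (length(hit) == 1L) lab[ci] <- hit
    else if (length(hit) > 1L) n_conflict <- n_conflict + 1L
  }
  if (n_conflict > 0)
    warning(n_conflict,
            " cell(s) exceeded the threshold for multiple classes; left unlabeled")
  structure(factor(setNames(lab, colnames(H)),
                   levels = c(classes, "unlabeled")),
            h_min = h_min, class = c("cell_labels", "factor"))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test (two-sided by the minimum-likelihood convention:
#' summing hypergeometric probabilities no larger than the observed
#' table's) with the conditional maximum-likelihood odds ratio.
#'
#' @param a,b,c,d non-negative integer cell counts, table
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `odds_ratio`, `p_two_sided`, `table`.
#' @export
fisher_2x2 <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  tab <- matrix(as.integer(v), 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the 2x2 table")
  ht <- fisher.test(tab)
  list(odds_ratio = unname(ht$estimate), p_two_sided = ht$p.value,
       table = tab)
}

#' Train a cancer/normal classifier and predict ambiguous cells
#'
#' Mirrors the inferential design for resolving ambiguous mesenchymal-like
#' cells: cancer and immune (normal) cells are split 75/25; a classifier
#' (regularized logistic GLM, random forest, or linear-kernel SVM) is
#' trained on the 75% and its balanced accuracy — (sensitivity +
#' specificity)/2 — measured on the held-out 25%. The trained model then
#' predicts the cancer probability of the held-out endothelial cells
#' (never used in training: they estimate the misclassification rate) and
#' of the ambiguous cells; a 2x2 contingency of cancer calls
#' (endothelial vs ambiguous) is tested with Fisher's exact test.
#'
#' @param features cells x bins matrix from [cnv_features()] (or any
#'   external cells x regions matrix).
#' @param labels a [assign_labels()] factor (or named factor with the same
#'   levels) over the feature rows.
#' @param model `"glm"`, `"rf"` or `"svm"`.
#' @param train_frac training fraction of cancer and immune cells
#'   (default 0.75).
#' @param seed integer seed (split and model fitting).
#' @return object of class `"classifier_report"`: list with `model`,
#'   `balanced_accuracy`, `sensitivity`, `specificity`, `prob_endothelial`,
#'   `prob_ambiguous`, `contingency` (2x2), `fisher_p`, `odds_ratio`,
#'   `n_train`, `n_test`.
#' @export
fit_and_predict <- function(features, labels,
                            model = c("glm", "rf", "svm"),
                            train_frac = 0.75, seed = 1L) {
  model <- match.arg(model)
  labels <- labels[rownames(features)]
  cancer <- which(labels == "cancer")
  immune <- which(labels == "immune")
  endo <- which(labels == "endothelial")
  amb <- which(labels == "ambiguous_mes")
  if (length(cancer) < 20 || length(immune) < 20)
    stop("need at least 20 cancer and 20 immune cells")

  seeds <- derive_seeds(seed, 2L, "classifier")
  split_one <- function(idx, s) {
    n_tr <- round(train_frac * length(idx))
    tr <- with_seed(s, sample(idx, n_tr))
    list(train = tr, test = setdiff(idx, tr))
  }
  spc <- split_one(cancer, seeds[1])
  spi <- split_one(immune, seeds[2])
  tr_idx <- c(spc$train, spi$train)
  te_idx <- c(spc$test, spi$test)
  y_tr <- as.numeric(labels[tr_idx] == "cancer")
  if (length(unique(y_tr)) < 2) stop("single-class training set")

  x_tr <- features[tr_idx, , drop = FALSE]
  prob_fun <- switch(model,
    glm = {
      fit <- with_seed(seeds[1], glmnet::cv.glmnet(
        x_tr, y_tr, family = "binomial", alpha = 0, nfolds = 5))
      function(x) as.numeric(predict(fit, newx = x, s = "lambda.min",
                                     type = "response"))
    },
    rf = {
      fit <- with_seed(seeds[1], randomForest::randomForest(
        x = x_tr, y = factor(y_tr, levels = c(0, 1)), ntree = 500))
      function(x) predict(fit, newdata = x, type = "prob")[, "1"]
    },
    svm = {
      fit <- with_seed(seeds[1], e1071::svm(
        x = x_tr, y = factor(y_tr, levels = c(0, 1)),
        kernel = "linear", probability = TRUE))
      function(x) attr(predict(fit, newdata = x, probability = TRUE),
                       "probabilities")[, "1"]
    })

  p_te <- prob_fun(features[te_idx, , drop = FALSE])
  y_te <- as.numeric(labels[te_idx] == "cancer")
  sens <- if (any(y_te == 1)) mean(p_te[y_te == 1] > 0.5) else NA_real_
  spec <- if (any(y_te == 0)) mean(p_te[y_te == 0] <= 0.5) else NA_real_
  bacc <- mean(c(sens, spec))

  p_endo <- if (length(endo))
    prob_fun(features[endo, , drop = FALSE]) else numeric(0)
  p_amb <- if (length(amb))
    prob_fun(features[amb, , drop = FALSE]) else numeric(0)

  contingency <- NULL; fp <- NA_real_; or <- NA_real_
  if (length(p_endo) && length(p_amb)) {
    a <- sum(p_amb > 0.5); b <- length(p_amb) - a
    cc <- sum(p_endo > 0.5); dd <- length(p_endo) - cc
    contingency <- matrix(c(a, cc, b, dd), 2,
                          dimnames = list(c("ambiguous", "endothelial"),
                                          c("called_cancer", "called_normal")))
    ft <- tryCatch(fisher_2x2(a, b, cc, dd),
                   error = function(e) NULL)
    if (!is.null(ft)) { fp <- ft$p_two_sided; or <- ft$odds_ratio }
    else {            # zero margin: fall back to stats::fisher.test direct
      ht <- fisher.test(contingency)
      fp <- ht$p.value; or <- unname(ht$estimate)
    }
  }

  structure(list(model = model, balanced_accuracy = bacc,
                 sensitivity = sens, specificity = spec,
                 prob_endothelial = setNames(p_endo,
                                             rownames(features)[endo]),
                 prob_ambiguous = setNames(p_amb, rownames(features)[amb]),
                 contingency = contingency, fisher_p = fp,
                 odds_ratio = or,
                 n_train = length(tr_idx), n_test = length(te_idx),
                 seed = as.integer(seed)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Cancer/normal classifier (", x$model, ")\n", sep = "")
  cat("  balanced accuracy on held-out knowns: ",
      round(x$balanced_accuracy, 4),
      " (sens ", round(x$sensitivity, 4),
      ", spec ", round(x$specificity, 4), ")\n", sep = "")
  if (!is.null(x$contingency)) {
    cat("  cancer calls: ambiguous ", x$contingency[1, 1], "/",
        sum(x$contingency[1, ]), ", endothelial ", x$contingency[2, 1],
        "/", sum(x$contingency[2, ]), "\n", sep = "")
    cat("  Fisher exact p = ", signif(x$fisher_p, 4),
        ", odds ratio = ", signif(x$odds_ratio, 4), "\n", sep = "")
  }
  invisible(x)
}
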