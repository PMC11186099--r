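#' Configuration for the synthetic single-cell benchmark
#'
#' Parameters of a splatter-style Gamma–Poisson count simulator with
#' discrete cell-type groups and one shared "activity" program overlaid
#' across groups. Defaults reproduce the package's benchmark condition:
#' 13 cell types plus 1 activity program (14 ground-truth programs), scaled
#' to 3000 cells and 5000 genes so the whole pipeline runs at desk scale;
#' the full-scale condition (15000 cells) is available through
#' [run_config()]'s `scale = "full"` preset.
#'
#' Per-gene base means are Gamma(`mean_shape`, rate = `mean_rate`); library
#' sizes are lognormal(`lib_loc`, `lib_scale`); each group marks a fraction
#' `de_prob` of genes as differentially expressed with lognormal
#' (`de_loc`, `de_scale`) factors, a fraction `de_down_prob` of which are
#' inverted; the activity program multiplies `act_n_genes` random genes by
#' lognormal(`act_loc`, `act_scale`) factors in a fraction `act_cell_frac`
#' of cells drawn uniformly across groups. Biological overdispersion follows
#' splatter's default path: per-gene BCV inflation from a scaled
#' chi-square(`bcv_df`) around the common value `bcv_common`.
#'
#' @param n_cells,n_genes dataset dimensions.
#' @param n_groups number of discrete cell types (>= 2).
#' @param group_probs group mixing proportions (default equal); must sum
#'   to 1.
#' @param mean_shape,mean_rate Gamma parameters of per-gene base means.
#' @param lib_loc,lib_scale lognormal library-size parameters.
#' @param de_prob,de_loc,de_scale,de_down_prob differential-expression
#'   parameters per group.
#' @param act_cell_frac,act_n_genes,act_loc,act_scale activity-program
#'   parameters.
#' @param bcv_common,bcv_df overdispersion parameters.
#' @param seed integer seed; fixing it makes the dataset bit-reproducible.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 3000, n_genes = 5000, n_groups = 13,
                       group_probs = NULL,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_loc = log(20000), lib_scale = 0.2,
                       de_prob = 0.1, de_loc = 0.5, de_scale = 0.4,
                       de_down_prob = 0.5,
                       act_cell_frac = 0.3, act_n_genes = 300,
                       act_loc = 0.7, act_scale = 0.3,
                       bcv_common = 0.1, bcv_df = 60,
                       seed = 1L) {
  if (is.null(group_probs)) group_probs <- rep(1 / n_groups, n_groups)
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_groups = as.integer(n_groups), group_probs = group_probs,
              mean_shape = mean_shape, mean_rate = mean_rate,
              lib_loc = lib_loc, lib_scale = lib_scale,
              de_prob = de_prob, de_loc = de_loc, de_scale = de_scale,
              de_down_prob = de_down_prob,
              act_cell_frac = act_cell_frac,
              act_n_genes = as.integer(act_n_genes),
              act_loc = act_loc, act_scale = act_scale,
              bcv_common = bcv_common, bcv_df = bcv_df,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_cells <= 0 || cfg$n_genes <= 0) stop("non-positive dimensions")
  if (cfg$n_groups < 2) stop("n_groups must be >= 2")
  if (length(cfg$group_probs) != cfg$n_groups)
    stop("group_probs must have length n_groups")
  if (abs(sum(cfg$group_probs) - 1) > 1e-12)
    stop("group_probs must sum to 1")
  for (f in c("de_prob", "de_down_prob", "act_cell_frac")) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$act_n_genes > cfg$n_genes) stop("act_n_genes exceeds n_genes")
  invisible(cfg)
}

#' Simulate single-cell counts with planted programs
#'
#' Draws a genes x cells integer count matrix from the Gamma–Poisson model
#' described in [sim_config()]. Cell `i` in group `g` has expected count for
#' gene `j` proportional to
#' `base_mean[j] * de_factor[g, j] * act_factor[j]^activity[i]`, rescaled to
#' the cell's library size; counts carry splatter-style biological
#' coefficient of variation.
#'
#' @param cfg a [sim_config()] object.
#' @param chunk_cells internal block size for memory-bounded generation;
#'   does not affect the result.
#' @return an object of class `"acnmf_sim"`: list with `counts` (integer
#'   matrix with gene/cell identifiers), `group` (factor), `activity_flag`
#'   (logical), `truth_factors` (genes x (n_groups + 1) multiplicative
#'   factors, last column the activity program) and internal generative
#'   state used by [cnv_overlay()].
#' @export
simulate_counts <- function(cfg, chunk_cells = 500L) {
  validate_sim_config(cfg)
  G <- cfg$n_genes; n <- cfg$n_cells; ng <- cfg$n_groups
  gene_ids <- sprintf("G%06d", seq_len(G))
  cell_ids <- sprintf("cell%05d", seq_len(n))

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  base_mean <- rgamma(G, shape = cfg$mean_shape, rate = cfg$mean_rate)
  base_mean <- pmax(base_mean, 1e-8)

  de_fac <- matrix(1, G, ng)
  for (g in seq_len(ng)) {
    sel <- which(runif(G) < cfg$de_prob)
    if (length(sel)) {
      f <- rlnorm(length(sel), cfg$de_loc, cfg$de_scale)
      dn <- runif(length(sel)) < cfg$de_down_prob
      f[dn] <- 1 / f[dn]
      de_fac[sel, g] <- f
    }
  }

  act_fac <- rep(1, G)
  act_genes <- sample.int(G, cfg$act_n_genes)
  act_fac[act_genes] <- rlnorm(cfg$act_n_genes, cfg$act_loc, cfg$act_scale)

  group <- sample.int(ng, n, replace = TRUE, prob = cfg$group_probs)
  lib <- rlnorm(n, cfg$lib_loc, cfg$lib_scale)
  n_act <- round(cfg$act_cell_frac * n)
  activity <- rep(FALSE, n)
  if (n_act > 0) activity[sample.int(n, n_act)] <- TRUE

  # splatter-style per-gene BCV inflation around the common value
  bcv_infl <- sqrt(cfg$bcv_df / rchisq(G, df = cfg$bcv_df))

  counts <- matrix(0L, G, n, dimnames = list(gene_ids, cell_ids))
  denom <- numeric(n)
  starts <- seq(1L, n, by = chunk_cells)
  for (s in starts) {
    idx <- s:min(s + chunk_cells - 1L, n)
    mu_raw <- base_mean * de_fac[, group[idx], drop = FALSE]
    if (any(activity[idx]))
      mu_raw[, activity[idx]] <- mu_raw[, activity[idx]] * act_fac
    dsum <- colSums(mu_raw)
    denom[idx] <- dsum
    mu <- sweep(mu_raw, 2, lib[idx] / dsum, "*")
    counts[, idx] <- draw_gamma_poisson(mu, cfg$bcv_common, bcv_infl)
  }

  truth <- cbind(de_fac, act_fac)
  colnames(truth) <- c(sprintf("program_%02d", seq_len(ng)), "activity")
  rownames(truth) <- gene_ids

  structure(list(counts = counts,
                 group = factor(group,
                                labels = sprintf("group_%02d", seq_len(ng))),
                 activity_flag = activity,
                 truth_factors = truth,
                 base_mean = setNames(base_mean, gene_ids),
                 lib_size = setNames(lib, cell_ids),
                 cell_denominator = setNames(denom, cell_ids),
                 bcv_inflation = setNames(bcv_infl, gene_ids),
                 config = cfg),
            class = "acnmf_sim")
}

# Gamma-Poisson draw with BCV = (bcv_common + 1/sqrt(mu)) * inflation[gene].
draw_gamma_poisson <- function(mu, bcv_common, bcv_infl) {
  bcv <- (bcv_common + 1 / sqrt(pmax(mu, 1e-12))) * bcv_infl
  shp <- 1 / bcv^2
  lam <- matrix(rgamma(length(mu), shape = shp, rate = shp / mu),
                nrow(mu), ncol(mu))
  matrix(as.integer(rpois(length(lam), lam)), nrow(mu), ncol(mu))
}

#' @export
print.acnmf_sim <- function(x, ...) {
  cat("Simulated single-cell dataset: ", nrow(x$counts), " genes x ",
      ncol(x$counts), " cells\n", sep = "")
  cat("  ", nlevels(x$group), " cell types + 1 activity program (",
      sum(x$activity_flag), " activity cells)\n", sep = "")
  if (!is.null(x$cnv))
    cat("  CNV overlay: ", nrow(x$cnv$segments), " segments, ",
        sum(x$cnv$roles == "cancer"), " cancer cells\n", sep = "")
  invisible(x)
}

#' Ground-truth gene sets of the planted programs
#'
#' For each of the `n_groups + 1` planted programs, returns the `J` genes
#' with the largest absolute log multiplicative factor (ties broken by gene
#' index). If fewer than `J` genes carry a non-unit factor the set is padded
#' in tie order with a warning. With `J = NULL` (default) each program's
#' full signature — every gene with a non-unit factor, in decreasing
#' `|log factor|` order — is returned; the full signature is the robust
#' matching surface for recovery scoring, since fixed-size top slices are
#' dominated by down-regulated and lowly expressed genes that no
#' non-negative factorization can surface.
#'
#' @param ds an [simulate_counts()] result.
#' @param J set size, or `NULL` for the full per-program signature.
#' @return named list of character vectors, one per planted program.
#' @export
truth_gene_sets <- function(ds, J = NULL) {
  stopifnot(inherits(ds, "acnmf_sim"))
  tf <- ds$truth_factors
  if (is.null(J)) {
    out <- lapply(seq_len(ncol(tf)), function(p) {
      s <- abs(log(tf[, p]))
      ord <- order(-s, seq_along(s))
      rownames(tf)[ord[seq_len(sum(s > 0))]]
    })
    names(out) <- colnames(tf)
    return(out)
  }
  if (J <= 0) stop("J must be positive")
  if (J > nrow(tf)) stop("J exceeds the number of genes")
  out <- lapply(seq_len(ncol(tf)), function(p) {
    s <- abs(log(tf[, p]))
    if (sum(s > 0) < J)
      warning("program ", colnames(tf)[p], " has only ", sum(s > 0),
              " non-unit factors; set padded in tie order")
    ord <- order(-s, seq_along(s))
    rownames(tf)[ord[seq_len(J)]]
  })
  names(out) <- colnames(tf)
  out
}

#' Synthesize gene genomic coordinates
#'
#' Places genes in contiguous, near-equal blocks on `n_chrom`
#' pseudo-chromosomes with increasing start positions; used by the CNV
#' overlay and the genomic-bin classifier features.
#'
#' @param gene_ids character vector of gene identifiers (or an
#'   `"acnmf_sim"` object).
#' @param n_chrom number of pseudo-chromosomes.
#' @param gene_span genomic distance between consecutive gene starts.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
simulate_gene_coords <- function(gene_ids, n_chrom = 20, gene_span = 10000) {
  if (inherits(gene_ids, "acnmf_sim")) gene_ids <- rownames(gene_ids$counts)
  G <- length(gene_ids)
  chrom_of <- sort(rep_len(seq_len(n_chrom), G))
  pos <- unlist(lapply(split(seq_len(G), chrom_of),
                       function(i) seq_along(i)), use.names = FALSE)
  data.frame(gene_id = gene_ids,
             chrom = sprintf("chr%02d", chrom_of),
             start = (pos - 1L) * gene_span,
             end = (pos - 1L) * gene_span + gene_span %/% 2,
             stringsAsFactors = FALSE)
}

#' Configuration for the copy-number overlay
#'
#' @param n_segments number of CNV segments.
#' @param segment_gene_span genes per segment.
#' @param gain_factor,loss_factor multiplicative factors for gained / lost
#'   segments (`gain_factor > 1 > loss_factor > 0`).
#' @param cancer_cell_frac fraction of cells designated cancer when roles
#'   are not supplied.
#' @param ambiguous_cell_frac fraction designated ambiguous when roles are
#'   not supplied.
#' @param ambiguous_mode `"as_normal"` (ambiguous cells carry no CNVs) or
#'   `"as_cancer"` (they carry the cancer CNV profile).
#' @param seed integer seed.
#' @return an object of class `"cnv_config"`.
#' @export
cnv_config <- function(n_segments = 6, segment_gene_span = 100,
                       gain_factor = 2, loss_factor = 0.5,
                       cancer_cell_frac = 0.25, ambiguous_cell_frac = 0.1,
                       ambiguous_mode = c("as_normal", "as_cancer"),
                       seed = 1L) {
  ambiguous_mode <- match.arg(ambiguous_mode)
  if (!(gain_factor > 1 && 1 > loss_factor && loss_factor > 0))
    stop("need gain_factor > 1 > loss_factor > 0")
  structure(list(n_segments = as.integer(n_segments),
                 segment_gene_span = as.integer(segment_gene_span),
                 gain_factor = gain_factor, loss_factor = loss_factor,
                 cancer_cell_frac = cancer_cell_frac,
                 ambiguous_cell_frac = ambiguous_cell_frac,
                 ambiguous_mode = ambiguous_mode,
                 seed = as.integer(seed)),
            class = "cnv_config")
}

#' Overlay copy-number segments on a simulated dataset
#'
#' Re-draws (rather than post-multiplies) counts for designated cancer cells
#' over randomly placed contiguous genomic segments, scaling the generative
#' mean by the gain/loss factor. Ambiguous cells are scaled according to
#' `ccfg$ambiguous_mode`; normal cells are untouched.
#'
#' @param ds an [simulate_counts()] result.
#' @param ccfg a [cnv_config()] object.
#' @param gene_coords data.frame as from [simulate_gene_coords()], covering
#'   all genes of `ds`.
#' @param roles optional per-cell character vector in
#'   `{"cancer", "ambiguous", "normal"}`; by default roles are sampled using
#'   the configured fractions.
#' @return `ds` with modified counts plus a `cnv` element recording the
#'   segment map (`segments`), per-cell `roles` and the config.
#' @export
cnv_overlay <- function(ds, ccfg, gene_coords, roles = NULL) {
  stopifnot(inherits(ds, "acnmf_sim"), inherits(ccfg, "cnv_config"))
  gids <- rownames(ds$counts)
  if (!all(gids %in% gene_coords$gene_id))
    stop("gene_coords must cover all genes")
  gc <- gene_coords[match(gids, gene_coords$gene_id), ]
  ord <- order(gc$chrom, gc$start)      # genome order of matrix rows

  n <- ncol(ds$counts)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(ccfg$seed)

  if (is.null(roles)) {
    roles <- rep("normal", n)
    n_cancer <- round(ccfg$cancer_cell_frac * n)
    n_amb <- round(ccfg$ambiguous_cell_frac * n)
    pick <- sample.int(n, n_cancer + n_amb)
    roles[pick[seq_len(n_cancer)]] <- "cancer"
    if (n_amb > 0) roles[pick[n_cancer + seq_len(n_amb)]] <- "ambiguous"
  }
  stopifnot(length(roles) == n, all(roles %in% c("cancer", "ambiguous", "normal")))

  # non-overlapping segments of consecutive genes within chromosomes
  span <- ccfg$segment_gene_span
  chrom_rows <- split(ord, gc$chrom[ord])
  eligible <- names(chrom_rows)[vapply(chrom_rows, length, 1L) >= span]
  if (!length(eligible)) stop("segments exceed genome extent")
  seg_rows <- list(); seg_meta <- list()
  used <- rep(FALSE, length(gids))
  tries <- 0L
  while (length(seg_rows) < ccfg$n_segments) {
    tries <- tries + 1L
    if (tries > 200L) stop("could not place non-overlapping segments; reduce n_segments or segment_gene_span")
    ch <- sample(eligible, 1L)
    rows <- chrom_rows[[ch]]
    st <- sample.int(length(rows) - span + 1L, 1L)
    sel <- rows[st:(st + span - 1L)]
    if (any(used[sel])) next
    used[sel] <- TRUE
    i <- length(seg_rows) + 1L
    fac <- if (i %% 2L == 1L) ccfg$gain_factor else ccfg$loss_factor
    seg_rows[[i]] <- sel
    seg_meta[[i]] <- data.frame(segment = i, chrom = ch,
                                factor = fac,
                                n_genes = span, stringsAsFactors = FALSE)
  }
  segments <- do.call(rbind, seg_meta)

  cnv_gene_fac <- rep(1, length(gids))
  for (i in seq_along(seg_rows))
    cnv_gene_fac[seg_rows[[i]]] <- segments$factor[i]

  scaled_cells <- which(roles == "cancer")
  if (ccfg$ambiguous_mode == "as_cancer")
    scaled_cells <- sort(c(scaled_cells, which(roles == "ambiguous")))

  affected_genes <- which(cnv_gene_fac != 1)
  if (length(scaled_cells) && length(affected_genes)) {
    cfg <- ds$config
    g <- as.integer(ds$group)[scaled_cells]
    mu_raw <- ds$base_mean[affected_genes] *
      ds$truth_factors[affected_genes, g, drop = FALSE]
    act <- ds$activity_flag[scaled_cells]
    if (any(act))
      mu_raw[, act] <- mu_raw[, act] * ds$truth_factors[affected_genes, "activity"]
    mu_raw <- mu_raw * cnv_gene_fac[affected_genes]
    # keep the pre-CNV library denominator: gains genuinely raise totals
    mu <- sweep(mu_raw, 2,
                ds$lib_size[scaled_cells] / ds$cell_denominator[scaled_cells],
                "*")
    ds$counts[affected_genes, scaled_cells] <-
      draw_gamma_poisson(mu, cfg$bcv_common,
                         ds$bcv_inflation[affected_genes])
  }

  ds$cnv <- list(segments = segments,
                 segment_genes = lapply(seg_rows, function(r) gids[r]),
                 roles = setNames(roles, colnames(ds$counts)),
                 config = ccfg)
  ds
}

#' Write a simulated dataset to disk
#'
#' Emits 10x-convention MatrixMarket counts with sidecars, truth labels as
#' TSV, and the configuration as YAML.
#'
#' @param ds an [simulate_counts()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_sim <- function(ds, dir) {
  stopifnot(inherits(ds, "acnmf_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(ds$counts, dir, format = "mtx_dir")
  lab <- data.frame(cell_id = colnames(ds$counts),
                    group = as.character(ds$group),
                    activity = ds$activity_flag)
  if (!is.null(ds$cnv)) lab$role <- as.character(ds$cnv$roles)
  write.table(lab, file.path(dir, "truth_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = rownames(ds$truth_factors),
                         ds$truth_factors, check.names = FALSE),
              file.path(dir, "truth_factors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(ds$config), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
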