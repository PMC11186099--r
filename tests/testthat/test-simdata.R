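test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_cells = 200, n_genes = 400, n_groups = 3, seed = 11)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$group, b$group)
  expect_identical(a$activity_flag, b$activity_flag)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_groups = 1), "n_groups")
  expect_error(sim_config(group_probs = c(0.5, 0.4), n_groups = 2), "sum to 1")
  expect_error(sim_config(de_prob = 1.5), "de_prob")
  expect_error(sim_config(act_n_genes = 10, n_genes = 5), "act_n_genes")
  expect_error(sim_config(n_cells = 0), "dimensions")
})

test_that("without DE or activity, groups are exchangeable", {
  cfg <- sim_config(n_cells = 900, n_genes = 300, n_groups = 3,
                    de_prob = 0, act_cell_frac = 0, seed = 5)
  ds <- simulate_counts(cfg)
  g1 <- ds$counts[, ds$group == "group_01"]
  g2 <- ds$counts[, ds$group == "group_02"]
  d <- rowMeans(g1) - rowMeans(g2)
  se <- sqrt(apply(g1, 1, var) / ncol(g1) + apply(g2, 1, var) / ncol(g2))
  expect_gte(mean(abs(d) <= 3 * se), 0.95)
})

test_that("mean library size matches the lognormal closed form", {
  cfg <- sim_config(n_cells = 3000, n_genes = 1000, n_groups = 5, seed = 3)
  ds <- simulate_counts(cfg)
  target <- exp(cfg$lib_loc + cfg$lib_scale^2 / 2)
  expect_lt(abs(mean(colSums(ds$counts)) - target) / target, 0.05)
})

test_that("counts are non-negative integers and truth factors positive", {
  ds <- small_sim()
  expect_true(all(ds$counts >= 0))
  expect_identical(storage.mode(ds$counts), "integer")
  expect_true(all(ds$truth_factors > 0))
  expect_identical(ncol(ds$truth_factors), nlevels(ds$group) + 1L)
})

test_that("activity genes are elevated in activity cells of every group", {
  ds <- small_sim()
  up <- ds$truth_factors[, "activity"] > 1.2
  for (g in levels(ds$group)) {
    on_cells <- ds$group == g & ds$activity_flag
    off_cells <- ds$group == g & !ds$activity_flag
    ratio <- mean(ds$counts[up, on_cells]) / mean(ds$counts[up, off_cells])
    expect_gt(ratio, 1)
  }
})

test_that("per-gene group tests reject far above nominal for DE genes only", {
  ds <- small_sim()
  lf <- abs(log(ds$truth_factors[, seq_len(nlevels(ds$group))]))
  strong <- rowSums(lf > 0.5) > 0
  none <- rowSums(lf) == 0
  pick_de <- which(strong)[1:60]
  pick_null <- which(none)[1:60]
  pvals <- function(rows) vapply(rows, function(r)
    kruskal.test(ds$counts[r, ], ds$group)$p.value, numeric(1))
  expect_gt(mean(pvals(pick_de) < 0.05), 0.6)
  expect_lt(mean(pvals(pick_null) < 0.05), 0.15)
})

test_that("truth gene sets have the requested cardinality and tie padding", {
  ds <- small_sim()
  sets <- truth_gene_sets(ds, 20)
  expect_length(sets, 6)
  expect_true(all(lengths(sets) == 20))
  expect_error(truth_gene_sets(ds, 0), "positive")

  # full signatures: exactly the non-unit-factor genes of each program
  full <- truth_gene_sets(ds)
  for (p in seq_along(full))
    expect_setequal(full[[p]],
                    rownames(ds$truth_factors)[
                      ds$truth_factors[, p] != 1])

  # forged dataset: program with only 2 non-unit factors must pad + warn
  tf <- matrix(1, 30, 2,
               dimnames = list(sprintf("g%02d", 1:30), c("a", "b")))
  tf[1:2, 1] <- 3
  tf[5:30, 2] <- 2
  forged <- structure(list(truth_factors = tf), class = "acnmf_sim")
  expect_warning(sets <- truth_gene_sets(forged, 10), "padded")
  expect_length(sets$a, 10)
  expect_identical(sets$a[1:2], c("g01", "g02"))
  expect_identical(sets$a[3:10], sprintf("g%02d", 3:10))  # tie order
})

test_that("truth set intersections respect the DE bookkeeping", {
  ds <- small_sim()
  J <- 15
  sets <- truth_gene_sets(ds, J)
  for (p in seq_len(ncol(ds$truth_factors))) {
    nonunit <- rownames(ds$truth_factors)[ds$truth_factors[, p] != 1]
    if (length(nonunit) >= J)
      expect_true(all(sets[[p]] %in% nonunit))
  }
})

test_that("CNV overlay scales segment means by the design factor", {
  ds <- simulate_counts(sim_config(n_cells = 800, n_genes = 1000,
                                   n_groups = 4, act_cell_frac = 0,
                                   seed = 21))
  coords <- simulate_gene_coords(ds, n_chrom = 5)
  ccfg <- cnv_config(n_segments = 4, segment_gene_span = 60,
                     gain_factor = 2, loss_factor = 0.5,
                     cancer_cell_frac = 0.4, ambiguous_cell_frac = 0.1,
                     ambiguous_mode = "as_normal", seed = 9)
  ov <- cnv_overlay(ds, ccfg, coords)
  seg <- ov$cnv$segments
  cancer <- names(ov$cnv$roles)[ov$cnv$roles == "cancer"]
  normal <- names(ov$cnv$roles)[ov$cnv$roles == "normal"]
  amb <- names(ov$cnv$roles)[ov$cnv$roles == "ambiguous"]
  for (i in seq_len(nrow(seg))) {
    genes <- ov$cnv$segment_genes[[i]]
    mc <- colSums(ov$counts[genes, cancer])
    mn <- colSums(ov$counts[genes, normal])
    ratio <- mean(mc) / mean(mn)
    se <- ratio * sqrt(var(mc) / length(mc) / mean(mc)^2 +
                         var(mn) / length(mn) / mean(mn)^2)
    expect_lt(abs(ratio - seg$factor[i]), 3 * se)
    # as_normal ambiguous cells look like normals over the segment
    ma <- colSums(ov$counts[genes, amb])
    ra <- mean(ma) / mean(mn)
    sea <- ra * sqrt(var(ma) / length(ma) / mean(ma)^2 +
                       var(mn) / length(mn) / mean(mn)^2)
    expect_lt(abs(ra - 1), 3 * sea)
  }
})

test_that("CNV overlay with zero cancer fraction leaves counts untouched", {
  ds <- simulate_counts(sim_config(n_cells = 100, n_genes = 300,
                                   n_groups = 2, seed = 2))
  coords <- simulate_gene_coords(ds)
  ccfg <- cnv_config(n_segments = 2, segment_gene_span = 10,
                     cancer_cell_frac = 0, ambiguous_cell_frac = 0,
                     seed = 4)
  ov <- cnv_overlay(ds, ccfg, coords)
  expect_identical(ov$counts, ds$counts)
  expect_identical(nrow(ov$cnv$segments), 2L)
})

test_that("simulated datasets round-trip through the on-disk format", {
  ds <- simulate_counts(sim_config(n_cells = 30, n_genes = 50,
                                   n_groups = 2, act_n_genes = 10,
                                   seed = 13))
  dir <- withr::local_tempdir()
  export_sim(ds, dir)
  back <- read_counts(dir, format = "mtx_dir")
  expect_equal(as.matrix(back), ds$counts, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(ds$counts))
  lab <- read.delim(file.path(dir, "truth_labels.tsv"))
  expect_identical(lab$group, as.character(ds$group))
})
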