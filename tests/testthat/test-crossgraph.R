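test_that("twin catalogs connect in a perfect matching", {
  Wz <- toy_weights(G = 300, k = 5, seed = 3)
  ca <- program_catalog("dsA", Wz, tuned_J = 20)
  cb <- program_catalog("dsB", Wz, tuned_J = 20)
  ed <- cross_edges(list(ca, cb))
  expect_identical(nrow(ed), 5L)
  expect_identical(ed$prog_a, ed$prog_b)
  expect_true(all(ed$jaccard_index == 1))
})

test_that("asymmetric set sizes and nested sets behave as designed", {
  Wz <- toy_weights(G = 300, k = 3, seed = 5)
  ca <- program_catalog("a", Wz, tuned_J = 20)
  cb <- program_catalog("b", Wz, tuned_J = 50)
  ed <- cross_edges(list(ca, cb))
  self <- ed[ed$prog_a == ed$prog_b, ]
  expect_identical(nrow(self), 3L)
  # top-20 nested in top-50: intersection 20, minimal attainable p
  expect_true(all(self$intersection == 20))
  expect_equal(self$p_raw[1], hyper_tail_enum(300, 20, 50, 20),
               tolerance = 1e-12)
})

test_that("shuffled catalogs stay within the FWER bound and edge sets are
           order-invariant", {
  Wz <- toy_weights(G = 400, k = 6, seed = 6)
  set.seed(7)
  Wz_shuf <- apply(Wz, 2, sample)
  rownames(Wz_shuf) <- rownames(Wz)
  ca <- program_catalog("a", Wz, tuned_J = 30)
  cb <- program_catalog("b", Wz_shuf, tuned_J = 30)
  ed <- cross_edges(list(ca, cb))
  expect_lte(nrow(ed), qbinom(0.99, 36, 0.05 / 36) + 1)

  cc <- program_catalog("c", toy_weights(G = 400, k = 4, seed = 8),
                        tuned_J = 25)
  e1 <- cross_edges(list(ca, cb, cc))
  e2 <- cross_edges(list(cc, cb, ca))
  key <- function(e) sort(paste(pmin(paste(e$dataset_a, e$prog_a),
                                     paste(e$dataset_b, e$prog_b)),
                                pmax(paste(e$dataset_a, e$prog_a),
                                     paste(e$dataset_b, e$prog_b))))
  expect_identical(key(e1), key(e2))
})

test_that("catalogs sharing planted truth connect almost all truth pairs", {
  ds <- small_sim()
  Wa <- truth_catalog_weights(ds, noise_sd = 0.05, seed = 1)
  Wb <- truth_catalog_weights(ds, noise_sd = 0.05, seed = 2)
  ca <- program_catalog("simA", Wa, tuned_J = 30)
  cb <- program_catalog("simB", Wb, tuned_J = 30)
  ed <- cross_edges(list(ca, cb))
  hits <- sum(ed$prog_a == ed$prog_b)
  expect_gte(hits / ncol(Wa), 0.9)
})

test_that("random-walk communities respect connected components", {
  Wz <- toy_weights(G = 300, k = 3, seed = 9)
  ca <- program_catalog("a", Wz, tuned_J = 20)
  cb <- program_catalog("b", Wz, tuned_J = 20)
  g <- build_program_graph(list(ca, cb))
  lab <- detect_graph_communities(g, seed = 1)
  expect_identical(length(lab), 6L)
  # twins must share a community; different twins never merge
  for (p in colnames(Wz))
    expect_identical(lab[paste0("a::", p)], lab[paste0("b::", p)],
                     ignore_attr = TRUE)
  expect_identical(length(unique(lab)), 3L)

  # single edge -> one community over its two nodes
  ed1 <- data.frame(dataset_a = "a", prog_a = "p01",
                    dataset_b = "b", prog_b = "p01",
                    intersection = 20L, jaccard_index = 1,
                    p_raw = 0, p_adjusted = 0)
  g1 <- build_program_graph(list(
    program_catalog("a", Wz[, 1, drop = FALSE], 20),
    program_catalog("b", Wz[, 1, drop = FALSE], 20)), edges = ed1)
  lab1 <- detect_graph_communities(g1, seed = 1)
  expect_identical(unname(lab1[1]), unname(lab1[2]))
})

test_that("layouts are seeded, finite, and geometry-aware", {
  Wz <- toy_weights(G = 300, k = 4, seed = 10)
  ca <- program_catalog("a", Wz, tuned_J = 20)
  cb <- program_catalog("b", Wz, tuned_J = 20)
  g <- build_program_graph(list(ca, cb))
  xy1 <- layout_graph(g, seed = 3)
  xy2 <- layout_graph(g, seed = 3)
  expect_identical(xy1, xy2)
  expect_true(all(is.finite(xy1)))

  single <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(single)$name <- "solo"
  expect_equal(unname(layout_graph(single)), matrix(0, 1, 2))

  # two bridged cliques: intra-clique layout distances < inter-clique
  gg <- igraph::graph_from_literal(a - b, a - c, b - c, d - e, d - f,
                                   e - f, c - d)
  xy <- layout_graph(gg, seed = 5)
  d <- as.matrix(dist(xy))
  intra <- mean(c(d["a", "b"], d["a", "c"], d["b", "c"],
                  d["d", "e"], d["d", "f"], d["e", "f"]))
  inter <- mean(d[c("a", "b", "c"), c("d", "e", "f")])
  expect_lt(intra, inter)
})

test_that("graph export round-trips through GraphML and JSON", {
  Wz <- toy_weights(G = 300, k = 3, seed = 11)
  ca <- program_catalog("datos_ñ", Wz, tuned_J = 20)
  cb <- program_catalog("b", Wz, tuned_J = 20)
  g <- build_program_graph(list(ca, cb))
  lab <- detect_graph_communities(g, seed = 1)
  igraph::V(g)$community <- as.integer(lab[igraph::V(g)$name])

  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "g.graphml")
  export_graph(g, f1, format = "graphml")
  g1 <- import_graph(f1, format = "graphml")
  expect_identical(sort(igraph::V(g1)$name), sort(igraph::V(g)$name))
  expect_identical(igraph::ecount(g1), igraph::ecount(g))
  expect_true(any(grepl("datos_ñ", igraph::V(g1)$dataset)))

  f2 <- file.path(dir, "g.json")
  export_graph(g, f2, format = "json")
  g2 <- import_graph(f2, format = "json")
  expect_identical(sort(igraph::V(g2)$name), sort(igraph::V(g)$name))
  expect_identical(igraph::ecount(g2), igraph::ecount(g))
  m1 <- igraph::as_data_frame(g, "edges"); m2 <- igraph::as_data_frame(g2, "edges")
  expect_equal(sort(m1$jaccard_index), sort(m2$jaccard_index))

  # empty graph exports to valid documents
  e <- build_program_graph(list(ca, cb),
                           edges = cross_edges(list(ca, cb))[0, ])
  f3 <- file.path(dir, "empty.json")
  export_graph(e, f3, format = "json")
  ge <- import_graph(f3, format = "json")
  expect_equal(igraph::ecount(ge), 0)
  expect_equal(igraph::vcount(ge), 6)
})
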