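de_rec <- function(ids, classes, dirs) {
  data.frame(feature_id = ids, rna_class = classes, fc_ratio = 2, fc_abs = 2,
             regulation = dirs, p_value = 0.01, fdr = 0.01, significant = TRUE,
             rescued = FALSE, stringsAsFactors = FALSE)
}

tp <- function(mirna, target, class, symbol = target) {
  data.frame(mirna_id = mirna, target_id = target, target_symbol = symbol,
             target_class = class, source = "db", stringsAsFactors = FALSE)
}

test_that("interaction edges obey the strict 0.4 confidence cutoff", {
  de <- de_rec(c("m1", "t1", "t2"), c("miRNA", "mRNA", "mRNA"),
               c("down", "up", "up"))
  pairs <- rbind(tp("m1", "t1", "mRNA", "A"), tp("m1", "t2", "mRNA", "B"))
  edges <- data.frame(node_a = c("A", "A"), node_b = c("B", "B"),
                      score = c(0.41, 0.39))
  g <- suppressMessages(build_network(pairs, tp("m1", "x", "lncRNA")[0, ],
                                      de, gene_edges = edges))
  e <- igraph::as_data_frame(g, what = "edges")
  expect_equal(sum(e$type == "mrna_mrna"), 1)
  g2 <- suppressMessages(build_network(
    pairs, tp("m1", "x", "lncRNA")[0, ], de,
    gene_edges = data.frame(node_a = "A", node_b = "B", score = 0.39)))
  expect_equal(sum(igraph::E(g2)$type == "mrna_mrna"), 0)
  # bipartite edges survive without any gene edges
  g3 <- suppressMessages(build_network(pairs, tp("m1", "x", "lncRNA")[0, ], de))
  expect_equal(igraph::ecount(g3), 2)
})

test_that("edges to non-differential features are dropped and duplicates collapse", {
  de <- de_rec(c("m1", "t1"), c("miRNA", "mRNA"), c("down", "up"))
  pairs <- rbind(tp("m1", "t1", "mRNA"), tp("m1", "t1", "mRNA"),
                 tp("m1", "absent", "mRNA"))
  expect_message(g <- build_network(pairs, tp("m1", "x", "lncRNA")[0, ], de),
                 "dropped 1")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 2)
})

test_that("hub ranking reports all maximum-degree nodes with lexicographic ties", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", "a", "b", "d", "e", "f")
  h <- hub_by_degree(star)
  expect_equal(h$node[h$is_hub], "c")
  # two tied centers over distinct leaves
  g <- igraph::graph_from_edgelist(
    rbind(c("z", "x"), c("z", "y"), c("a", "u"), c("a", "v")), directed = FALSE)
  h2 <- hub_by_degree(g)
  expect_equal(h2$node[h2$is_hub], c("a", "z"))
  expect_error(hub_by_degree(igraph::make_empty_graph(0)), "empty")
})

test_that("dense-module mining matches hand-traced MCODE behavior on toys", {
  clique5 <- igraph::make_full_graph(5)
  igraph::V(clique5)$name <- letters[1:5]
  with_pendant <- igraph::add_edges(igraph::add_vertices(clique5, 1, name = "p"),
                                    c("a", "p"))
  mods <- mine_dense_modules(with_pendant)
  expect_length(mods, 1)
  expect_setequal(mods[[1]]$members, letters[1:5])

  two4 <- igraph::disjoint_union(igraph::make_full_graph(4),
                                 igraph::make_full_graph(4))
  igraph::V(two4)$name <- letters[1:8]
  mods2 <- mine_dense_modules(two4)
  expect_length(mods2, 2)
  expect_setequal(unlist(lapply(mods2, `[[`, "members")), letters[1:8])

  edgeless <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(edgeless)$name <- letters[1:5]
  expect_length(mine_dense_modules(edgeless), 0)
  expect_length(mine_dense_modules(igraph::make_full_graph(2)), 0)
})

test_that("mined modules are denser than the whole graph on toys", {
  set.seed(21)
  # sparse background plus an embedded 5-clique
  g <- igraph::sample_gnp(30, 0.06)
  igraph::V(g)$name <- sprintf("v%02d", 1:30)
  g <- igraph::add_edges(g, as.vector(t(t(combn(paste0("v0", 1:5), 2)))))
  g <- igraph::simplify(g)
  mods <- mine_dense_modules(g)
  expect_gt(length(mods), 0)
  for (m in mods) expect_gt(m$density, igraph::edge_density(g))
})

test_that("triad extraction equals exhaustive enumeration on random networks", {
  set.seed(31)
  sizes <- list(c(3, 10, 6), c(5, 40, 20), c(8, 120, 70))
  for (sz in sizes) {
    g <- random_tripartite(sz[1], sz[2], sz[3], p_edge = 0.25)
    expect_lte(igraph::vcount(g), 200)
    got <- extract_cerna_triads(g)
    want <- triads_oracle(g)
    expect_equal(got[, c("lncrna_id", "mirna_id", "mrna_id")], want)
    # sponge consistency holds exhaustively
    expect_true(all(got$mirna_direction != got$mrna_direction))
    expect_true(all(got$mirna_direction != got$lncrna_direction))
  }
})

test_that("same-direction partners never form triads", {
  de <- de_rec(c("m1", "g1", "g2", "l1"),
               c("miRNA", "mRNA", "mRNA", "lncRNA"),
               c("down", "up", "down", "up"))
  g <- suppressMessages(build_network(
    rbind(tp("m1", "g1", "mRNA"), tp("m1", "g2", "mRNA")),
    tp("m1", "l1", "lncRNA"), de))
  tri <- extract_cerna_triads(g)
  expect_equal(tri$mrna_id, "g1")  # g2 shares the miRNA's direction
  expect_equal(tri$lncrna_id, "l1")
})

test_that("functional restriction keeps only triads whose mRNA symbol is in the set", {
  tri <- data.frame(
    lncrna_id = c("l1", "l1", "l2"), mirna_id = "m1",
    mrna_id = c("g1", "g2", "g1"), mrna_symbol = c("Adcy1", "Xyz", "Adcy1"),
    mirna_direction = "down", lncrna_direction = "up", mrna_direction = "up",
    stringsAsFactors = FALSE)
  expect_equal(nrow(restrict_by_function(tri, "Adcy1")), 2)
  expect_equal(nrow(restrict_by_function(tri, c("Adcy1", "Xyz"))), 3)
  expect_equal(nrow(restrict_by_function(tri, character(0))), 0)
})
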