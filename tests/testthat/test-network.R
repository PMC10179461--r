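pairs_df <- function(lnc, tgt) data.frame(lncRNA_id = lnc, target_id = tgt,
                                          stringsAsFactors = FALSE)

test_that("network construction de-duplicates and stays bipartite", {
  g <- build_network(pairs_df("hub", c("a", "b", "c")))
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  expect_equal(igraph::degree(g)[["hub"]], 3)

  dup <- rbind(pairs_df("l1", "m1"), pairs_df("l1", "m1"))
  expect_equal(igraph::ecount(build_network(dup)), 1L)

  empty <- build_network(pairs_df(character(0), character(0)))
  expect_equal(igraph::vcount(empty), 0L)

  expect_error(build_network(pairs_df("x", "x")), class = "validation_error")
  expect_error(build_network(rbind(pairs_df("a", "b"), pairs_df("b", "c"))),
               class = "validation_error")
})

test_that("maximal cliques and MCC follow the factorial formula", {
  tri <- igraph::make_graph(~ a - b, b - c, a - c)
  expect_equal(maximal_cliques(tri), list(c("a", "b", "c")))
  expect_equal(unname(mcc(tri)), rep(2, 3))

  path <- igraph::make_graph(~ a - b, b - c)
  expect_equal(maximal_cliques(path), list(c("a", "b"), c("b", "c")))

  star <- build_network(pairs_df("hub", paste0("m", 1:30)))
  expect_equal(mcc(star)[["hub"]], 30)

  iso <- igraph::add_vertices(tri, 1, name = "z")
  expect_equal(mcc(iso)[["z"]], 0)
})

test_that("the suite reproduces hand-computed values on a 3-path", {
  g <- igraph::make_graph(~ a - b, b - c)
  tab <- centrality_suite(g, centrality_config(seed = 3))
  b_row <- tab[tab$node == "b", ]
  expect_equal(b_row$Betweenness, 1)
  expect_equal(b_row$Stress, 1)
  expect_equal(b_row$Radiality, 2)
  expect_equal(b_row$Closeness, 2)
  expect_equal(b_row$Eccentricity, 1)
  expect_equal(b_row$Degree, 2)
  a_row <- tab[tab$node == "a", ]
  expect_equal(a_row$Radiality, 1.5)
  expect_equal(a_row$Closeness, 1.5)
  expect_equal(a_row$Eccentricity, 0.5)
})

test_that("every lncRNA node of a bipartite network has DMNC 0 and MNC 1", {
  ds <- simulate_dataset(sim_config(seed = 23))
  g <- build_network(ds$truth_targets)
  tab <- centrality_suite(g, centrality_config(epc_iterations = 50, seed = 1))
  lnc <- tab[tab$node_type == "lncRNA", ]
  expect_true(all(lnc$DMNC == 0))
  expect_true(all(lnc$MNC == 1))
  expect_equal(tab$MCC, tab$Degree)
})

test_that("EPC matches its closed form on tiny graphs", {
  edge <- igraph::make_graph(~ a - b)
  cfg <- centrality_config(epc_iterations = 2000, seed = 11)
  tab <- centrality_suite(edge, cfg)
  se <- sqrt(0.25 / 2000)
  expect_lt(max(abs(tab$EPC - 1.5)), 3 * se)

  p3 <- igraph::make_graph(~ a - b, b - c)
  tab3 <- centrality_suite(p3, cfg)
  # center: 1 + Bern(p) + Bern(p) -> 2; leaf: 1 + p + p^2 -> 1.75
  expect_lt(abs(tab3$EPC[tab3$node == "b"] - 2), 3 * sqrt(0.5 / 2000))
  expect_lt(abs(tab3$EPC[tab3$node == "a"] - 1.75), 3 * sqrt(0.5 / 2000))
})

test_that("the centrality table is deterministic given graph and seed", {
  ds <- simulate_dataset(sim_config(genes_per_chromosome = c(X = 120),
                                    n_cis_planted = 6, n_trans_planted = 6,
                                    seed = 31))
  g <- build_network(ds$truth_targets)
  cfg <- centrality_config(epc_iterations = 100, seed = 99)
  expect_identical(centrality_suite(g, cfg), centrality_suite(g, cfg))
})

test_that("hub selection is inclusive at the threshold", {
  tab <- data.frame(node = c("A", "B", "C"), MCC = c(31, 30, 29))
  expect_equal(select_hubs(tab)$hubs, c("A", "B"))
  expect_equal(select_hubs(data.frame(node = "A", MCC = 10))$hubs, character(0))

  star <- build_network(pairs_df("hub", paste0("m", 1:31)))
  tab2 <- centrality_suite(star, centrality_config(epc_iterations = 10, seed = 1))
  sel <- select_hubs(tab2, star)
  expect_equal(sel$hubs, "hub")
  expect_equal(igraph::vcount(sel$subnetwork), 32L)
  expect_equal(igraph::ecount(sel$subnetwork), 31L)
})

test_that("SIF and GraphML exports round-trip the topology", {
  g <- build_network(pairs_df(c("l1", "l1", "l2"), c("m1", "m2", "m2")))
  g <- igraph::add_vertices(g, 1, name = "lonely")
  f <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, f)
  back <- read_sif(f)
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(g))

  fg <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, fg)
  gml <- igraph::read_graph(fg, format = "graphml")
  expect_equal(igraph::vcount(gml), igraph::vcount(g))

  ft <- withr::local_tempfile(fileext = ".tsv")
  tab <- centrality_suite(g, centrality_config(epc_iterations = 10, seed = 1))
  write_centrality_table(tab, ft)
  hdr <- strsplit(readLines(ft, n = 1), "\t")[[1]]
  expect_equal(hdr[1], "Node_Name")
  expect_true(all(c("MCC", "DMNC", "MNC", "Degree", "EPC", "Bottleneck",
                    "Eccentricity", "Closeness", "Radiality", "Betweenness",
                    "Stress") %in% hdr))
})
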