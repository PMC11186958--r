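test_that("graph constructor enforces its invariants", {
  expect_error(network_graph(matrix(0, 2, 3)), "square")
  expect_error(network_graph(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
  expect_error(network_graph(matrix(c(1, 0, 0, 0), 2, 2)), "diagonal")
  expect_error(network_graph(matrix(c(0, 2, 2, 0), 2, 2)), "0 or 1")
  expect_error(network_graph(diag(4) * 0, hemisphere = c("L", "R")),
               "one label per node")
  expect_error(network_graph(diag(4) * 0, homotopy_partner = c(1, 2, 3, 4)),
               "fixed-point")
  expect_error(network_graph(diag(4) * 0, homotopy_partner = c(2, 3, 4, 1)),
               "involution")
  g <- network_graph(diag(4) * 0, hemi4, partner4)
  expect_s3_class(g, "ergmpop_graph")
  expect_identical(g$n_nodes, 4L)
})

test_that("edge, nodematch and homotopy counts match their definitions", {
  expect_identical(count_edges(complete_graph(4)), 6L)
  expect_identical(count_edges(network_graph(matrix(0L, 30, 30))), 0L)
  expect_identical(count_edges(path_graph(4)), 3L)

  expect_identical(count_nodematch(complete_graph(4, hemisphere = rep("L", 4))), 6L)
  cross <- edge_graph(4, list(c(1, 3)), hemisphere = hemi4)
  expect_identical(count_nodematch(cross), 0L)
  two_tri <- edge_graph(6, list(c(1, 2), c(2, 3), c(1, 3),
                                c(4, 5), c(5, 6), c(4, 6)),
                        hemisphere = rep(c("L", "R"), each = 3))
  expect_identical(count_nodematch(two_tri), 6L)
  expect_error(count_nodematch(complete_graph(4)), "no node attribute")

  half <- 15
  matched <- edge_graph(30, lapply(seq_len(half), function(j) c(j, j + half)),
                        homotopy_partner = c(seq_len(half) + half, seq_len(half)))
  expect_identical(count_homotopy(matched), 15L)
  expect_identical(count_homotopy(network_graph(matrix(0L, 4, 4),
                                                homotopy_partner = partner4)), 0L)
  g <- edge_graph(4, list(c(1, 3), c(1, 2)), homotopy_partner = partner4)
  expect_identical(count_homotopy(g), 1L)
  expect_error(count_homotopy(complete_graph(4)), "homotopy")
})

test_that("esp counts and gwesp match the shared-partner definitions", {
  tri <- complete_graph(3)
  expect_equal(unname(esp_counts(tri)), c(0L, 3L))
  expect_equal(unname(esp_counts(complete_graph(4))), c(0L, 0L, 6L))
  expect_equal(unname(esp_counts(path_graph(3))), c(2L, 0L))

  for (tau in c(0.2, 0.9, 2.5)) expect_equal(gwesp(tri, tau), 3)
  expect_equal(gwesp(network_graph(matrix(0L, 30, 30)), 0.9), 0)
  # K4: independently derived from EP_2 = 6 and the geometric weights
  expect_equal(gwesp(complete_graph(4), 0.9),
               r_gwesp(complete_graph(4)$adjacency, 0.9))
  expect_error(gwesp(tri, -1), "positive")

  # against the brute-force oracle on random graphs
  set.seed(401)
  for (r in 1:10) {
    g <- random_graph(9, 0.45)
    expect_equal(gwesp(g, 0.7), r_gwesp(g$adjacency, 0.7))
    ep <- esp_counts(g)
    expect_equal(unname(ep), r_esp_counts(g$adjacency))
    expect_identical(sum(ep), count_edges(g))
  }
})

test_that("summary_stats respects term order and attribute requirements", {
  expect_equal(summary_stats(complete_graph(4), ergm_spec("edges")),
               c(edges = 6))
  expect_equal(summary_stats(complete_graph(3), ergm_spec(c("edges", "gwesp"), 0.9)),
               c(edges = 3, gwesp = 3))
  empty <- network_graph(matrix(0L, 30, 30), hemisphere = rep(c("L", "R"), each = 15))
  expect_equal(unname(summary_stats(empty, ergm_spec())), c(0, 0, 0))
  # order of terms defines coordinate order
  g <- random_graph(6, hemisphere = rep(c("L", "R"), each = 3))
  s1 <- summary_stats(g, ergm_spec(c("edges", "nodematch.hemisphere")))
  s2 <- summary_stats(g, ergm_spec(c("nodematch.hemisphere", "edges")))
  expect_equal(unname(s1), unname(rev(s2)))
  expect_error(summary_stats(complete_graph(4), ergm_spec()), "hemisphere")
})

test_that("change_stats equals the summary-statistic difference", {
  spec <- ergm_spec(c("edges", "gwesp"), 0.9)
  expect_equal(unname(change_stats(complete_graph(5), c(2, 4), ergm_spec("edges"))), 1)
  near_tri <- edge_graph(3, list(c(1, 2), c(2, 3)))
  expect_equal(unname(change_stats(near_tri, c(1, 3), spec)), c(1, 3))
  expect_error(change_stats(near_tri, c(2, 2), spec), "distinct")

  full <- ergm_spec(c("edges", "nodematch.hemisphere", "nodematch.homotopy",
                      "gwesp"), 0.9)
  set.seed(402)
  for (r in 1:10) {
    g <- random_graph(10, 0.4, hemisphere = rep(c("L", "R"), each = 5),
                      homotopy_partner = c(6:10, 1:5))
    for (k in 1:20) {
      d <- sample(10, 2)
      gp <- g; gp$adjacency[d[1], d[2]] <- gp$adjacency[d[2], d[1]] <- 1L
      gm <- g; gm$adjacency[d[1], d[2]] <- gm$adjacency[d[2], d[1]] <- 0L
      expect_equal(unname(change_stats(g, d, full)),
                   unname(summary_stats(gp, full) - summary_stats(gm, full)))
    }
  }
})

test_that("gwesp is monotone under edge addition (exhaustive 5-node graphs)", {
  violations <- enumerate_graphs(5, function(adj) {
    base <- r_gwesp(adj, 0.9)
    bad <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      if (adj[i, j]) next
      adj2 <- adj; adj2[i, j] <- adj2[j, i] <- 1L
      g2 <- network_graph(adj2)
      if (gwesp(g2, 0.9) < base - 1e-12) bad <- bad + 1
    }
    bad
  })
  expect_identical(sum(violations), 0)
})

test_that("metric distributions satisfy their accounting identities", {
  two_edges <- edge_graph(4, list(c(1, 2), c(3, 4)))
  md <- metric_distributions(two_edges)
  expect_equal(md$geodesic[["1"]], 2)
  expect_equal(md$geodesic[["Inf"]], 4)

  p3 <- metric_distributions(path_graph(3))
  expect_equal(unname(p3$degree), c(0, 2, 1))
  expect_equal(p3$geodesic[["1"]], 2)
  expect_equal(p3$geodesic[["2"]], 1)

  k4 <- metric_distributions(complete_graph(4))
  expect_equal(k4$degree[["3"]], 4)
  expect_equal(k4$geodesic[["1"]], 6)
  expect_equal(k4$esp[["2"]], 6)

  set.seed(403)
  for (r in 1:5) {
    g <- random_graph(12, 0.2)
    md <- metric_distributions(g)
    expect_equal(sum(md$degree), g$n_nodes)
    expect_equal(sum(md$geodesic), choose(g$n_nodes, 2))
    expect_equal(sum(md$esp), count_edges(g))
  }
})

test_that("graph readers and writers round-trip", {
  set.seed(404)
  g <- random_graph(8, 0.4, hemisphere = rep(c("L", "R"), each = 4),
                    homotopy_partner = c(5:8, 1:4))
  tmp <- withr::local_tempdir()

  f <- file.path(tmp, "adj.csv")
  write_adjacency(g, f)
  g2 <- read_adjacency(f, hemisphere = g$hemisphere,
                       homotopy_partner = g$homotopy_partner)
  expect_identical(g2$adjacency, g$adjacency)

  # edge list (0- and 1-based)
  el <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  f1 <- file.path(tmp, "el1.csv")
  write.table(el, f1, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_identical(read_edge_list(f1, 8)$adjacency, g$adjacency)
  f0 <- file.path(tmp, "el0.csv")
  write.table(el - 1L, f0, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_identical(read_edge_list(f0, 8, one_based = FALSE)$adjacency,
                   g$adjacency)

  # GraphML via igraph
  fg <- file.path(tmp, "g.graphml")
  igraph::write_graph(
    igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected"),
    fg, format = "graphml")
  expect_identical(read_graphml(fg)$adjacency, g$adjacency)

  # node attributes
  fa <- file.path(tmp, "attrs.csv")
  write.csv(data.frame(node = 1:8, hemisphere = g$hemisphere,
                       homotopy_partner = g$homotopy_partner),
            fa, row.names = FALSE)
  at <- read_node_attributes(fa)
  expect_identical(at$hemisphere, g$hemisphere)
  expect_identical(at$homotopy_partner, g$homotopy_partner)
})
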