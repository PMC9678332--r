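path_aabb <- function() {
  g <- igraph::make_graph(c("n1", "n2", "n2", "n3", "n3", "n4"),
                          directed = FALSE)
  igraph::V(g)$group <- c("A", "A", "B", "B")
  g
}

test_that("mixing matrix splits undirected edges symmetrically", {
  m <- mixing_matrix(path_aabb(), "group")
  expect_equal(sum(m$e), 1, tolerance = 1e-12)
  expect_equal(m$e["A", "A"], 1 / 3)
  expect_equal(m$e["B", "B"], 1 / 3)
  expect_equal(m$e["A", "B"], 1 / 6)
  expect_equal(m$e["B", "A"], 1 / 6)

  # single directed edge concentrates all weight in one cell
  gd <- igraph::make_graph(c("x", "y"), directed = TRUE)
  igraph::V(gd)$group <- c("A", "B")
  md <- mixing_matrix(gd, "group")
  expect_equal(md$e["A", "B"], 1)
  expect_equal(sum(md$e), 1)

  gu <- igraph::make_graph(c("x", "y"), directed = FALSE)
  igraph::V(gu)$group <- c("A", "B")
  mu <- mixing_matrix(gu, "group")
  expect_equal(mu$e["A", "B"], 0.5)
  expect_equal(mu$e["B", "A"], 0.5)
})

test_that("missing attributes raise an error naming the nodes", {
  g <- path_aabb()
  igraph::V(g)$group <- c("A", NA, "B", "B")
  expect_error(mixing_matrix(g, "group"), "n2",
               class = "echonet_attribute_error")
})

test_that("assortativity matches hand-derived cases", {
  expect_equal(assortativity(mixing_matrix(path_aabb(), "group"))$r, 1 / 3)

  # two disconnected same-attribute cliques: perfect assortment
  g <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(3))
  igraph::V(g)$group <- rep(c("A", "B"), each = 3)
  expect_equal(assortativity(mixing_matrix(g, "group"))$r, 1)

  # complete bipartite across two attributes: perfect disassortment
  g <- igraph::make_full_bipartite_graph(3, 3)
  igraph::V(g)$group <- rep(c("A", "B"), each = 3)
  expect_equal(assortativity(mixing_matrix(g, "group"))$r, -1)

  # single-category graph is degenerate, not an exception
  g <- igraph::make_full_graph(3)
  igraph::V(g)$group <- "A"
  res <- assortativity(mixing_matrix(g, "group"))
  expect_true(res$degenerate)
  expect_true(is.na(res$r))
})

test_that("assortativity equals direct-enumeration and igraph oracles", {
  withr::with_seed(101, {
    for (i in 1:40) {
      g <- random_attr_graph(sample(3:6, 1), directed = i %% 2 == 0,
                             k_cat = sample(2:3, 1))
      for (wt in c(TRUE, FALSE)) {
        r_pkg <- assortativity(mixing_matrix(g, "group", weighted = wt))$r
        r_or <- oracle_assortativity(g, "group", weighted = wt)
        expect_equal(r_pkg, r_or, tolerance = 1e-9)
      }
      vals <- igraph::V(g)$group
      if (length(unique(vals)) > 1) {
        r_ig <- igraph_assortativity(g, "group")
        r_pkg <- assortativity(mixing_matrix(g, "group", weighted = TRUE))$r
        expect_equal(r_pkg, r_ig, tolerance = 1e-9)
      }
    }
  })
})

test_that("r is invariant to category relabeling and weight scaling", {
  withr::with_seed(202, {
    for (i in 1:10) {
      g <- random_attr_graph(5, directed = FALSE, k_cat = 3)
      r0 <- assortativity(mixing_matrix(g, "group"))$r
      g2 <- igraph::set_vertex_attr(g, "group", value = chartr(
        "ABC", "ZYX", igraph::V(g)$group))
      expect_equal(assortativity(mixing_matrix(g2, "group"))$r, r0,
                   tolerance = 1e-12)
      g3 <- igraph::set_edge_attr(g, "weight",
                                  value = igraph::E(g)$weight * 7)
      expect_equal(assortativity(mixing_matrix(g3, "group"))$r, r0,
                   tolerance = 1e-12)
    }
  })
})

test_that("topology summaries match closed-form small graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  ts <- topology_summary(tri)
  expect_equal(ts$density, 1)
  expect_equal(ts$transitivity, 1)
  expect_equal(ts$avg_clustering, 1)
  expect_true(is.na(ts$reciprocity))

  cyc <- igraph::make_graph(c("a", "b", "b", "a"), directed = TRUE)
  expect_equal(topology_summary(cyc)$reciprocity, 1)

  chain <- igraph::make_graph(c("u", "v", "v", "w"), directed = TRUE)
  expect_equal(topology_summary(chain)$reciprocity, 0)
  expect_equal(topology_summary(chain)$density, 2 / (3 * 2))
})

test_that("node degrees sum incident weights by direction", {
  star <- igraph::make_graph(c("l1", "ctr", "l2", "ctr", "l3", "ctr",
                               "l4", "ctr"), directed = TRUE)
  igraph::E(star)$weight <- 2
  nd <- node_degrees(star)
  ctr <- nd[nd$node == "ctr", ]
  expect_equal(ctr$in_degree, 8)
  expect_equal(ctr$out_degree, 0)

  # a node whose two neighbors are connected has clustering 1
  tri_plus <- igraph::make_graph(c("a", "b", "b", "c", "a", "c", "d", "a"),
                                 directed = FALSE)
  nd <- node_degrees(tri_plus)
  expect_equal(nd$clustering[nd$node == "b"], 1)

  g <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g)$name <- "solo"
  nd <- node_degrees(g)
  expect_equal(nd$in_degree, 0)
  expect_equal(nd$clustering, 0)
})
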