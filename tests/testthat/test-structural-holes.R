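test_that("star geometries match Burt's closed forms", {
  star <- named_star(4)
  tp <- tie_profile(star, "ctr")
  expect_equal(unname(tp$p), rep(1 / 4, 4))
  expect_equal(unname(tp$c), rep(1 / 16, 4))
  m <- sh_metrics(star, "ctr")
  expect_equal(m$effective_size, 4)
  expect_equal(m$efficiency, 1)
  expect_equal(m$constraint, 0.25)
  expect_equal(m$hierarchy, 0)

  leaf <- tie_profile(star, "l1")
  expect_equal(unname(leaf$p), 1)
  expect_equal(unname(leaf$c), 1)
  lm <- sh_metrics(star, "l1")
  expect_equal(lm$constraint, 1)
  expect_equal(lm$effective_size, 1)
  expect_equal(lm$efficiency, 1)
})

test_that("triangle nodes match the hand-evaluated Burt values", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  tp <- tie_profile(tri, "a")
  expect_equal(unname(tp$c), rep((0.5 + 0.25)^2, 2))
  m <- sh_metrics(tri, "a")
  expect_equal(m$effective_size, 1)
  expect_equal(m$efficiency, 0.5)
  expect_equal(m$constraint, 1.125)
  expect_equal(m$hierarchy, 0)
  # igraph's independent constraint implementation agrees
  expect_equal(m$constraint, unname(igraph::constraint(tri)[1]),
               tolerance = 1e-12)

  rows <- sh_table(tri)$metrics
  expect_equal(nrow(rows), 3)
  expect_equal(length(unique(round(rows$constraint, 12))), 1)
})

test_that("a dyad is one fully constrained contact", {
  g <- igraph::make_graph(c("x", "y"), directed = TRUE)
  igraph::E(g)$weight <- 3
  m <- sh_metrics(g, "x")
  expect_equal(m$effective_size, 1)
  expect_equal(m$efficiency, 1)
  expect_equal(m$constraint, 1)
  expect_equal(m$hierarchy, 0)
})

test_that("all indices equal the dense-matrix oracle on random graphs", {
  withr::with_seed(303, {
    for (i in 1:25) {
      g <- random_attr_graph(sample(4:8, 1), directed = i %% 2 == 0, p = 0.5)
      tab <- sh_table(g)
      ig_con <- igraph::constraint(g, weights = igraph::E(g)$weight)
      for (r in seq_len(nrow(tab$metrics))) {
        row <- tab$metrics[r, ]
        orc <- oracle_sh(g, row$node)
        expect_equal(row$effective_size, orc$effective_size,
                     tolerance = 1e-9)
        expect_equal(row$efficiency, orc$efficiency, tolerance = 1e-9)
        expect_equal(row$constraint, orc$constraint, tolerance = 1e-9)
        expect_equal(row$hierarchy, orc$hierarchy, tolerance = 1e-9)
        if (!igraph::is_directed(g)) {
          expect_equal(row$constraint, unname(ig_con[row$node]),
                       tolerance = 1e-9)
        }
      }
      expect_true(all(!tab$metrics$node %in% tab$isolated))
    }
  })
})

test_that("ego invariants hold on random graphs", {
  withr::with_seed(404, {
    for (i in 1:15) {
      g <- random_attr_graph(6, directed = FALSE, p = 0.5)
      adj_names <- igraph::V(g)$name
      for (nm in adj_names) {
        tp <- tie_profile(g, nm)
        if (tp$isolated) next
        expect_equal(sum(tp$p), 1, tolerance = 1e-9)
        expect_true(all(tp$p > 0))
        m <- sh_metrics(g, nm)
        expect_gte(m$hierarchy, -1e-12)
        expect_lte(m$hierarchy, 1 + 1e-12)
        expect_gt(m$efficiency, 0)
        expect_lte(m$efficiency, 1 + 1e-12)
        expect_lte(m$effective_size, m$n_contacts + 1e-12)
        expect_gt(m$constraint, 0)
        # equal dyadic constraints <=> zero hierarchy
        spread <- diff(range(tp$c))
        if (spread < 1e-12) expect_equal(m$hierarchy, 0, tolerance = 1e-9)
        if (m$hierarchy < 1e-12) expect_lt(spread, 1e-9)
      }
    }
  })
})

test_that("removing a tie between contacts cannot raise ego's constraint", {
  # all 4-node graphs containing the star around ego plus contact-contact ties
  base <- igraph::make_graph(c("e", "a", "e", "b", "e", "c"),
                             directed = FALSE)
  extras <- list(c("a", "b"), c("a", "c"), c("b", "c"))
  for (subset in 1:7) {
    on <- extras[bitwAnd(subset, c(1, 2, 4)) > 0]
    g_full <- igraph::add_edges(base, unlist(on))
    c_full <- sh_metrics(g_full, "e")$constraint
    for (drop in seq_along(on)) {
      g_less <- igraph::add_edges(base, unlist(on[-drop]))
      c_less <- sh_metrics(g_less, "e")$constraint
      expect_lte(c_less, c_full + 1e-12)
    }
  }
})

test_that("isolated nodes are excluded with an explicit marker", {
  g <- igraph::add_vertices(named_star(3), 1)
  g <- igraph::set_vertex_attr(g, "name", value = c("ctr", "l1", "l2", "l3",
                                                    "lonely"))
  tab <- sh_table(g)
  expect_equal(tab$isolated, "lonely")
  expect_setequal(tab$metrics$node, c("ctr", "l1", "l2", "l3"))
  solo <- sh_metrics(g, "lonely")
  expect_true(is.na(solo$constraint))
  expect_equal(solo$n_contacts, 0L)
})
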