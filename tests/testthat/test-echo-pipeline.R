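test_that("opinion leaders need both top cuts; spanners exclude leaders", {
  metrics <- tibble::tibble(
    node = sprintf("u%02d", 1:20),
    in_degree = c(100, 90, seq(80, 0, length.out = 18)),
    out_degree = 0,
    clustering = c(0.9, 0.01, 0.8, seq(0.5, 0, length.out = 17)))
  leaders <- detect_opinion_leaders(metrics, percentile = 10)
  expect_equal(leaders, "u01") # u02 is top in-degree but low clustering
  union <- detect_opinion_leaders(metrics, percentile = 10, rule = "union")
  expect_setequal(union, c("u01", "u02", "u03"))

  sh <- tibble::tibble(node = metrics$node, n_contacts = 3,
                       effective_size = 1, efficiency = 0.5,
                       constraint = seq(0.1, 2, length.out = 20),
                       hierarchy = 0)
  sp <- detect_spanners(sh, leaders = "u01", percentile = 10)
  expect_equal(sp, "u02") # u01 has the lowest constraint but is a leader
  expect_length(intersect(sp, leaders), 0)
  expect_error(detect_opinion_leaders(metrics[0, ]),
               class = "echonet_empty_error")
})

test_that("intersection leaders stay well below a single percentile cut", {
  corp <- generate_echo_corpus(generator_config(n_users = 2000, seed = 13))
  g <- build_user_network(corp, "global")
  nd <- node_degrees(g)
  leaders <- detect_opinion_leaders(nd, percentile = 5)
  expect_lt(length(leaders), 0.05 * nrow(nd))
})

test_that("topic roles count distinct topics across all activity", {
  corp <- tiny_corpus()
  tr <- topic_roles(corp)
  roles <- setNames(tr$topic_role, tr$user_id)
  expect_equal(roles[["u3"]], "bridger")  # conspiracy + means
  expect_equal(roles[["u1"]], "echoer")   # single original, no interactions
  expect_equal(roles[["u5"]], "echoer")
})

test_that("attitude roles compare partners to the ego's attitude", {
  corp <- tiny_corpus()
  ar <- attitude_roles(corp)
  roles <- setNames(ar$attitude_role, ar$user_id)
  expect_equal(roles[["u5"]], "echoer")   # positive ego, positive partner
  expect_equal(roles[["u3"]], "bridger")  # positive ego, one negative partner
  expect_equal(roles[["u4"]], "bridger")  # negative ego, positive partner
  expect_equal(roles[["u6"]], "echoer")   # no partners: vacuously an echoer
})

test_that("association rules tally joint roles with a pooled total", {
  roles <- tibble::tibble(
    user_id = sprintf("u%02d", 1:10),
    n_topics = 1,
    topic_role = rep(c("bridger", "echoer"), each = 5),
    attitude = "positive",
    attitude_role = c(rep("bridger", 4), "echoer",
                      rep("echoer", 4), "bridger"))
  groups <- list(g1 = sprintf("u%02d", 1:6), g2 = sprintf("u%02d", 7:10))
  tab <- association_rules(roles, groups, "bridger")
  g1 <- tab[tab$group == "g1", ]
  expect_equal(g1$n_total, 6)
  expect_equal(g1$n_antecedent, 5)
  expect_equal(g1$n_joint, 4)
  expect_equal(g1$support, 4 / 6)
  expect_equal(g1$confidence, 4 / 5)
  tot <- tab[tab$group == "Total", ]
  expect_equal(tot$n_total, sum(tab$n_total[tab$group != "Total"]))
  expect_equal(tot$n_antecedent, sum(tab$n_antecedent[tab$group != "Total"]))
  expect_equal(tot$n_joint, sum(tab$n_joint[tab$group != "Total"]))
  expect_true(all(tab$support <= tab$confidence + 1e-12, na.rm = TRUE))

  # a group of pure joint bridgers has support = confidence = 1
  pure <- association_rules(roles[1:4, ], list(all = roles$user_id[1:4]),
                            "bridger")
  expect_equal(pure$support, c(1, 1))
  expect_equal(pure$confidence, c(1, 1))

  # zero antecedent: confidence undefined, not an error
  none <- association_rules(roles[6:9, ], list(g = roles$user_id[6:9]),
                            "bridger")
  expect_true(all(is.na(none$confidence)))
  expect_equal(none$support, c(0, 0))
})

test_that("chi-square matches the direct O/E oracle and handles edge cases", {
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  res <- chi_square_test(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-9) # 4 * 25 / 15
  expect_equal(res$df, 1)

  flat <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE)
  expect_equal(chi_square_test(flat)$statistic, 0, tolerance = 1e-12)

  withr::with_seed(55, {
    for (i in 1:10) {
      r <- sample(2:4, 1); c <- sample(2:3, 1)
      t <- matrix(sample(5:50, r * c, replace = TRUE), r, c)
      res <- chi_square_test(t)
      expect_equal(res$statistic, oracle_chisq(t), tolerance = 1e-9)
      expect_equal(res$df, (r - 1) * (c - 1))
    }
  })

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)),
               class = "echonet_degenerate_error")
})

test_that("the full pipeline is deterministic and structurally complete", {
  corp <- generate_echo_corpus(generator_config(n_users = 400, seed = 77))
  rep1 <- run_pipeline(corp)
  rep2 <- run_pipeline(corp)
  expect_equal(rep1, rep2)

  aw <- rep1$assortativity[rep1$assortativity$weighted, ]
  expect_equal(nrow(aw), 6) # 2 layers x 3 modes
  expect_setequal(unique(rep1$assortativity$layer),
                  c("information", "user"))
  expect_length(intersect(rep1$key_users$opinion_leaders,
                          rep1$key_users$spanners), 0)
  expect_false(any(rep1$sh_isolated %in% rep1$key_users$spanners))
  expect_equal(nrow(rep1$roles), 400)

  dir <- withr::local_tempdir()
  write_report(rep1, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "report.json", "topology.csv", "assortativity.csv", "association.csv")))))
})

test_that("a corpus without comments degrades gracefully", {
  corp <- generate_echo_corpus(small_config())
  no_cm <- corpus(corp$users,
                  corp$tweets[corp$tweets$kind != "comment", ])
  rep <- run_pipeline(no_cm)
  expect_true(any(grepl("comment", rep$empty_modes)))
  cm <- rep$topology[rep$topology$mode == "comment", ]
  expect_true(all(cm$edges == 0))
})

test_that("tidiers and autoplot produce well-formed output", {
  corp <- generate_echo_corpus(small_config())
  rep <- run_pipeline(corp)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$n_users, 300)
  m <- mixing_matrix(build_user_network(corp, "global"))
  td <- tidy(m)
  expect_equal(sum(td$proportion), 1, tolerance = 1e-9)
  expect_equal(glance(m)$r, assortativity(m)$r)
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_structural_holes(rep$sh_metrics, rep$roles), "ggplot")
  if (length(rep$chi_square)) {
    ct <- rep$chi_square[[1]]
    expect_equal(nrow(tidy(ct)), length(ct$observed))
    expect_equal(glance(ct)$statistic, ct$statistic)
  }
})
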