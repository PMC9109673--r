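# Modularity, greedy detection, the exact enumeration oracle, refinement.

# two disjoint unit-weight triangles: one rater sorting {1,2,3} | {4,5,6}
two_triangles <- function() {
  partition <- stats::setNames(c(1, 1, 1, 2, 2, 2), 1:6)
  build_network(identical_sort_study(partition, n_raters = 1))
}

test_that("modularity matches closed forms and the direct-sum oracle", {
  net <- two_triangles()
  triangles <- stats::setNames(c(1, 1, 1, 2, 2, 2), 1:6)
  all_in_one <- stats::setNames(rep(1, 6), 1:6)
  singletons <- stats::setNames(1:6, 1:6)
  expect_equal(modularity_q(all_in_one, net), 0)
  expect_equal(modularity_q(triangles, net), 0.5)
  expect_equal(modularity_q(singletons, net), -1 / 6)

  # against an independent evaluation on random networks and partitions
  set.seed(3)
  for (i in 1:10) {
    study <- random_study(8, n_raters = 3)
    net_i <- build_network(study)
    part <- stats::setNames(sample(1:3, 8, TRUE), 1:8)
    gamma <- sample(c(0.5, 1, 2), 1)
    expect_equal(modularity_q(part, net_i, gamma),
                 direct_modularity(part, net_i$weights, gamma))
    # cross-check against igraph's weighted modularity at gamma = 1
    g <- igraph::graph_from_adjacency_matrix(net_i$weights, "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_q(part, net_i),
                 igraph::modularity(g, part, weights = igraph::E(g)$weight))
  }
})

test_that("modularity input contracts hold", {
  net <- two_triangles()
  expect_error(modularity_q(stats::setNames(1:5, 1:5), net),
               "6", class = "pte_coverage_error")
  expect_error(modularity_q(stats::setNames(1:6, 1:6), net, resolution = 0),
               class = "pte_parameter_error")
  # m = 0 convention
  empty_net <- build_network(sort_study(
    quote_corpus(1:3), list(rater_sort("A", c(`1` = "a", `2` = "b", `3` = "c")))))
  expect_equal(modularity_q(stats::setNames(rep(1, 3), 1:3), empty_net), 0)
})

test_that("detection recovers identical sorts and handles edgeless networks", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    partition <- stats::setNames(sample(1:3, n, TRUE), seq_len(n))
    R <- sample(1:8, 1)
    net <- build_network(identical_sort_study(partition, R))
    part <- detect_communities(net, seed = rep)
    expect_equal(adjusted_rand_index(part$assignment, planted_as_labels(partition)), 1)
  }
  edgeless <- build_network(sort_study(
    quote_corpus(1:4), list(rater_sort("A", c(`1` = "a", `2` = "b", `3` = "c", `4` = "d")))))
  part0 <- detect_communities(edgeless, seed = 1)
  expect_equal(part0$n_communities, 4L)
  expect_equal(part0$modularity, 0)
})

test_that("detection is deterministic in (net, gamma, seed) and validates gamma", {
  set.seed(5)
  net <- build_network(random_study(15, n_raters = 4))
  p1 <- detect_communities(net, resolution = 1.3, seed = 99)
  p2 <- detect_communities(net, resolution = 1.3, seed = 99)
  expect_identical(p1, p2)
  expect_error(detect_communities(net, resolution = -1, seed = 1),
               class = "pte_parameter_error")
})

test_that("partition invariants: contiguous ids, recomputable Q, stable labels", {
  set.seed(29)
  net <- build_network(random_study(20, n_raters = 5))
  part <- detect_communities(net, seed = 2)
  expect_setequal(unique(part$assignment), seq_len(part$n_communities))
  expect_equal(part$modularity, modularity_q(part$assignment, net))
  # ids ordered by descending community size
  sizes <- as.integer(table(part$assignment))
  expect_true(all(diff(sizes) <= 0))
})

test_that("exact oracle reproduces closed-form optima", {
  net <- two_triangles()
  ex <- exact_max_modularity(net)
  expect_equal(ex$modularity, 0.5)
  expect_equal(ex$n_communities, 2L)
  expect_equal(adjusted_rand_index(
    ex$assignment, stats::setNames(c("a", "a", "a", "b", "b", "b"), 1:6)), 1)

  # single node
  single <- build_network(sort_study(quote_corpus(1L),
                                     list(rater_sort("A", c(`1` = "g")))))
  ex1 <- exact_max_modularity(single)
  expect_equal(ex1$n_communities, 1L)
  expect_equal(ex1$modularity, 0)

  # complete equal-weight graph: one community is optimal (Q = 0)
  complete <- build_network(identical_sort_study(
    stats::setNames(rep(1, 5), 1:5), n_raters = 3))
  exc <- exact_max_modularity(complete)
  expect_equal(exc$n_communities, 1L)
  expect_equal(exc$modularity, 0)

  big <- build_network(identical_sort_study(stats::setNames(rep(1, 13), 1:13), 1))
  expect_error(exact_max_modularity(big), class = "pte_size_error")
})

test_that("greedy detection never beats the exact oracle on small networks", {
  set.seed(41)
  for (i in 1:25) {
    study <- random_study(n = sample(4:8, 1), n_raters = sample(1:4, 1),
                          max_groups = 3)
    net <- build_network(study)
    gamma <- sample(c(0.7, 1, 1.5), 1)
    q_exact <- exact_max_modularity(net, gamma)$modularity
    q_greedy <- detect_communities(net, gamma, seed = i)$modularity
    expect_lte(q_greedy, q_exact + 1e-9)
  }
})

test_that("merging two communities matches the analytic delta-Q", {
  set.seed(53)
  net <- build_network(random_study(10, n_raters = 4))
  part <- detect_communities(net, seed = 1)
  expect_gte(part$n_communities, 2)
  a <- part$assignment
  two_m <- 2 * total_weight(net)
  s <- node_strength(net)
  ia <- names(a)[a == 1]; ib <- names(a)[a == 2]
  W_ab <- sum(net$weights[ia, ib, drop = FALSE])
  dq_analytic <- 2 * W_ab / two_m -
    2 * sum(s[ia]) * sum(s[ib]) / two_m^2
  merged <- a; merged[merged == 2] <- 1
  expect_equal(modularity_q(merged, net) - modularity_q(a, net), dq_analytic)
})

test_that("refinement actions rebuild themes with full provenance", {
  partition <- stats::setNames(c(1, 1, 2, 2, 3, 3), 1:6)
  net <- build_network(identical_sort_study(partition, 3))
  part <- detect_communities(net, seed = 1)

  # identity: no actions
  themes0 <- apply_refinement(part)
  expect_equal(names(themes0$themes), paste("Group", 1:3))
  expect_length(themes0$provenance, 0)
  expect_equal(themes_assignment(themes0)[as.character(1:6)] |> unname(),
               paste("Group", part$assignment) |> unname())

  # create an additional theme and move quotes into it
  actions <- c(
    list(refinement_action("create_theme", label = "Future Courses",
                           rationale = "agreed in session")),
    lapply(c(2, 4), function(q)
      refinement_action("move_quote", quote_id = q, to = "Future Courses"))
  )
  themes <- apply_refinement(part, actions, net = net)
  expect_length(themes$themes, 4L)
  expect_equal(themes$themes[["Future Courses"]], c(2L, 4L))
  expect_length(themes$provenance, 3L)
  # moving quotes around keeps the partition property
  expect_setequal(unlist(themes$themes), 1:6)
  # recomputed modularity equals modularity() on the edited assignment
  expect_equal(attr(themes, "modularity"),
               modularity_q(themes_assignment(themes), net))

  # rename keeps membership
  renamed <- apply_refinement(themes, list(
    refinement_action("rename_theme", from = "Group 1", to_label = "Approach")))
  expect_true("Approach" %in% names(renamed$themes))
  expect_length(renamed$provenance, 4L)
})

test_that("refinement errors and the retain-empty switch behave as specified", {
  part <- structure(list(assignment = stats::setNames(c(1L, 1L, 2L), 1:3)),
                    class = "pte_partition")
  expect_error(apply_refinement(part, list(
    refinement_action("move_quote", quote_id = 9, to = "Group 1"))),
    class = "pte_reference_error")
  expect_error(apply_refinement(part, list(
    refinement_action("move_quote", quote_id = 1, to = "Nope"))),
    class = "pte_reference_error")
  # emptying "Group 2" drops it unless retained
  move3 <- list(refinement_action("move_quote", quote_id = 3, to = "Group 1"))
  expect_length(apply_refinement(part, move3)$themes, 1L)
  kept <- apply_refinement(part, move3, retain_empty = TRUE)
  expect_length(kept$themes, 2L)
  expect_length(kept$themes[["Group 2"]], 0L)
})
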