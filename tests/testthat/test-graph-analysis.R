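test_that("structure evaluation counts TP/FP against the right denominators", {
  labs <- paste0("n", 1:4)
  gt <- microcircuit_from_edges(labs, rbind(c("n1", "n2"), c("n2", "n3")))
  est <- microcircuit_from_edges(labs, rbind(c("n1", "n2"), c("n3", "n4")))
  ev <- evaluate_structure(est, gt)
  expect_identical(c(ev$tp, ev$fp), c(1L, 1L))
  expect_equal(ev$tpr, 0.5)
  expect_equal(ev$fpr, 0.25)

  g6 <- six_node_model()$graph
  perfect <- evaluate_structure(g6, g6)
  expect_identical(c(perfect$n_edges_gt, perfect$n_empty_gt), c(6L, 9L))
  expect_equal(c(perfect$tpr, perfect$fpr), c(1, 0))

  empty <- evaluate_structure(microcircuit(labs), gt)
  expect_identical(c(empty$tp, empty$fp), c(0L, 0L))
  expect_equal(c(empty$tpr, empty$fpr), c(0, 0))
})

test_that("evaluation satisfies the accounting identities on random graph pairs", {
  set.seed(12)
  labs <- paste0("v", 1:7)
  pairs <- t(combn(labs, 2))
  for (k in 1:8) {
    gt <- microcircuit_from_edges(labs, pairs[runif(nrow(pairs)) < 0.4, ,
                                              drop = FALSE])
    est <- microcircuit_from_edges(labs, pairs[runif(nrow(pairs)) < 0.4, ,
                                               drop = FALSE])
    ev <- evaluate_structure(est, gt)
    expect_identical(ev$tp + ev$fn, ev$n_edges_gt)
    expect_identical(ev$fp + ev$tn, ev$n_empty_gt)
    expect_equal(ev$n_edges_gt + ev$n_empty_gt, choose(7, 2))
  }
  expect_error(evaluate_structure(microcircuit(labs),
                                  microcircuit(c("x", "y"))), "node sets")
})

test_that("Dice similarity has the right identities and bounds", {
  labs <- c("A", "B", "C", "D", "E")
  g1 <- microcircuit_from_edges(labs, rbind(c("A", "B"), c("B", "C"),
                                            c("C", "D")))
  g2 <- microcircuit_from_edges(labs, rbind(c("A", "B"), c("B", "C"),
                                            c("C", "E")))
  expect_equal(dice_similarity(g1, g2), 2 * 2 / 6)
  expect_equal(dice_similarity(g1, g1), 1)
  g3 <- microcircuit_from_edges(labs, rbind(c("D", "E")))
  expect_equal(dice_similarity(g1, g3), 0)
  # both empty: identical objects
  expect_equal(dice_similarity(microcircuit(labs), microcircuit(labs)), 1)
  # symmetry and bounds on random pairs
  set.seed(3)
  pairs <- t(combn(labs, 2))
  for (k in 1:6) {
    a <- microcircuit_from_edges(labs, pairs[runif(10) < 0.5, , drop = FALSE])
    b <- microcircuit_from_edges(labs, pairs[runif(10) < 0.5, , drop = FALSE])
    expect_equal(dice_similarity(a, b), dice_similarity(b, a))
    expect_gte(dice_similarity(a, b), 0)
    expect_lte(dice_similarity(a, b), 1)
    if (n_edges(a) > 0 && dice_similarity(a, b) == 1)
      expect_identical(a$adjacency, b$adjacency)
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  labs <- c("A", "B", "C", "D", "E")
  g1 <- microcircuit_from_edges(labs, rbind(c("A", "B"), c("B", "C"),
                                            c("C", "D")))
  g2 <- microcircuit_from_edges(labs, rbind(c("A", "B"), c("B", "C"),
                                            c("C", "E")))
  g3 <- microcircuit_from_edges(labs, rbind(c("D", "E")))
  S <- similarity_matrix(list(g1, g2, g3))
  expect_identical(diag(S), rep(1, 3))
  expect_identical(S, t(S))
  expect_equal(S[1, 2], 2 / 3)
  expect_equal(S[1, 3], 0)
  S_same <- similarity_matrix(list(g1, g1, g1))
  expect_true(all(S_same == 1))
})

test_that("modularity clustering separates planted blocks and respects reordering", {
  n <- 12
  sim <- matrix(0.05, n, n)
  sim[1:6, 1:6] <- 0.9
  sim[7:12, 7:12] <- 0.9
  diag(sim) <- 1
  lab <- detect_subtypes(sim, seed = 1)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(length(unique(lab[1:6])), 1L)
  expect_identical(length(unique(lab[7:12])), 1L)
  expect_false(lab[1] == lab[7])

  set.seed(2)
  perm <- sample(n)
  lab2 <- detect_subtypes(sim[perm, perm], seed = 1)
  # same partition up to label names
  expect_identical(outer(lab2, lab2, "=="),
                   outer(lab[perm], lab[perm], "=="))

  expect_identical(detect_subtypes(matrix(1, 1, 1), seed = 1), 1L)
  expect_error(detect_subtypes(matrix(numeric(0), 0, 0)), "empty")
})

test_that("representative graphs maximize within-cluster similarity", {
  labs <- c("A", "B", "C", "D")
  g <- microcircuit_from_edges(labs, rbind(c("A", "B"), c("B", "C")))
  h <- microcircuit_from_edges(labs, rbind(c("C", "D")))
  reps <- representative_graph(list(g, g, h), labels = c(1, 1, 1))
  expect_identical(unname(reps["1"]), 1L) # g beats h, first g wins the tie
  reps2 <- representative_graph(list(g, g, g), labels = c(1, 1, 1))
  expect_identical(unname(reps2["1"]), 1L)
  reps3 <- representative_graph(list(g, h), labels = c(1, 2))
  expect_identical(unname(reps3), c(1L, 2L))
})

test_that("graph-level centrality matches hand-computed values", {
  k4 <- microcircuit(paste0("k", 1:4), !diag(4))
  expect_equal(graph_centrality(k4, "betweenness"), 0)
  ev <- graph_centrality(k4, "eigenvector")
  expect_equal(ev, 1 / sqrt(4)) # equal centralities at unit L2 norm

  path <- microcircuit_from_edges(c("A", "B", "C"),
                                  rbind(c("A", "B"), c("B", "C")))
  expect_equal(graph_centrality(path, "betweenness"), 1 / 3)

  expect_error(graph_centrality(microcircuit(c("a", "b")), "eigenvector"),
               "edgeless")
})

test_that("subtype score contrasts use the pooled t with a separation guard", {
  same <- compare_subtypes(c(1, 2, 3, 1, 2, 3), rep(c("u", "v"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  sep <- compare_subtypes(c(0, 0, 0, 1, 1, 1), rep(c("u", "v"), each = 3))
  expect_gt(abs(sep$statistic), 1e6)
  expect_lt(sep$p.value, 1e-12)

  hand <- compare_subtypes(c(1, 2, 3, 2, 3, 4), rep(c("u", "v"), each = 3))
  expect_equal(hand$statistic, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(hand$p.value, 2 * pt(-abs(-1 / sqrt(2 / 3)), df = 4),
               tolerance = 1e-12)
  expect_error(compare_subtypes(1:4, rep("a", 4)), "two groups")
})

test_that("cluster purity reproduces confusion-table accuracy", {
  expect_equal(label_accuracy(c(1, 1, 1, 2, 2), c("a", "a", "b", "b", "b")),
               4 / 5)
  expect_equal(label_accuracy(c(1, 2), c("x", "y")), 1)
})

test_that("subtype accuracy does not improve as structural noise grows", {
  tpl <- default_trial_templates(n_nodes = 12)
  acc <- vapply(c(0, 0.25, 0.5), function(fn) {
    tc <- generate_trial_collection(10, tpl$a, tpl$b, n_samples = 250,
                                    flip_noise = fn, seed = 41)
    graphs <- lapply(tc$trials, learn_microcircuit)
    out <- subtype_pipeline(graphs, types = tc$types, seed = 1)
    out$accuracy
  }, numeric(1))
  expect_gte(acc[1], acc[2] - 1e-9)
  expect_gte(acc[2], acc[3] - 1e-9)
  expect_equal(acc[1], 1)
})
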