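test_that("ising energy matches the pairwise form and counts each pair once", {
  m <- six_node_model()
  expect_identical(ising_energy(rep(0, 6), m$params), 0)
  # only w12 = 0.5 active
  expect_equal(ising_energy(c(1, 1, 0, 0, 0, 0), m$params), -0.5)
  # only w45 = -0.8 active
  expect_equal(ising_energy(c(0, 0, 0, 1, 1, 0), m$params), 0.8)
  expect_error(ising_energy(c(1, 0), m$params), "length")
  expect_error(ising_energy(c(2, 0, 0, 0, 0, 0), m$params), "binary")
})

test_that("ising energy is invariant under joint permutation of state and parameters", {
  set.seed(42)
  W <- six_node_model()$params$W
  for (k in 1:5) {
    perm <- sample(6)
    r <- runif(6, -1, 1)
    p1 <- ising_params(r, W, beta = 2)
    p2 <- ising_params(r[perm], W[perm, perm], beta = 2)
    x <- rbinom(6, 1, 0.5)
    expect_equal(ising_energy(x[perm], p2), ising_energy(x, p1))
  }
})

test_that("exact ising distribution normalizes, is uniform for null params, and refuses large n", {
  null6 <- ising_params(rep(0, 6), matrix(0, 6, 6), beta = 2)
  ex <- ising_exact_distribution(null6)
  expect_equal(ex$prob, rep(1 / 64, 64))

  m <- six_node_model()
  ex6 <- ising_exact_distribution(m$params)
  expect_equal(sum(ex6$prob), 1, tolerance = 1e-12)
  expect_true(all(ex6$prob > 0))

  big <- ising_params(rep(0, 21), matrix(0, 21, 21), beta = 1)
  expect_error(ising_exact_distribution(big), "enumeration")
})

test_that("exact ising distribution is invariant under node relabeling", {
  m <- six_node_model()
  set.seed(7)
  r <- runif(6, -0.5, 0.5)
  p1 <- ising_params(r, m$params$W, beta = 2)
  ex1 <- ising_exact_distribution(p1)
  enc <- function(x) 1L + sum(x * 2^(seq_along(x) - 1L))
  for (k in 1:3) {
    perm <- sample(6)
    p2 <- ising_params(r[perm], m$params$W[perm, perm], beta = 2)
    ex2 <- ising_exact_distribution(p2)
    # state s of the permuted model corresponds to original x with x[perm] = s
    for (row in sample(64, 10)) {
      s <- ex2$states[row, ]
      x <- integer(6)
      x[perm] <- s
      expect_equal(ex2$prob[row], ex1$prob[enc(x)], tolerance = 1e-12)
    }
  }
})

test_that("DAG Markov blanket is parents + children + co-parents", {
  g <- fig1_dag()
  expect_setequal(dag_markov_blanket(g, "C"), c("A", "B", "D", "E"))
  # A's child C has co-parent B
  expect_setequal(dag_markov_blanket(g, "A"), c("C", "B"))
  iso <- directed_graph(c("U", "V"), parents = list())
  expect_length(dag_markov_blanket(iso, "U"), 0)
  chain <- directed_graph(c("A", "B", "C"),
                          parents = list(B = "A", C = "B"))
  expect_setequal(dag_markov_blanket(chain, "B"), c("A", "C"))
  expect_error(dag_markov_blanket(g, "Z"), "unknown node")
})

test_that("directed_graph rejects cycles and unknown labels", {
  expect_error(directed_graph(c("A", "B"), parents = list(A = "B", B = "A")),
               "cycle")
  expect_error(directed_graph(c("A"), parents = list(A = "A")), "own parent")
  expect_error(directed_graph(c("A"), parents = list(A = "Q")), "unknown")
})

test_that("moralization marries co-parents and drops directions", {
  g <- fig1_dag()
  mg <- moralize(g)
  expect_setequal(neighborhood(mg, "C"), c("A", "B", "D", "E"))
  # A and B are co-parents of C, so they become adjacent
  expect_true(mg$adjacency["A", "B"])

  empty <- moralize(directed_graph(c("X", "Y", "Z")))
  expect_identical(n_edges(empty), 0L)

  collider <- moralize(directed_graph(c("A", "B", "C"),
                                      parents = list(C = c("A", "B"))))
  expect_identical(n_edges(collider), 3L) # triangle
})

test_that("moralized neighborhoods equal DAG Markov blankets on random DAGs", {
  set.seed(11)
  for (k in 1:10) {
    g <- random_dag(sample(4:8, 1))
    mg <- moralize(g)
    for (v in g$node_labels) {
      expect_setequal(neighborhood(mg, v), dag_markov_blanket(g, v))
    }
  }
})

test_that("microcircuit neighborhood works on chains and the benchmark graph", {
  chain <- microcircuit_from_edges(c("A", "B", "C"),
                                   rbind(c("A", "B"), c("B", "C")))
  expect_identical(neighborhood(chain, "C"), "B")
  iso <- microcircuit(c("A", "B"))
  expect_length(neighborhood(iso, "A"), 0)
  g6 <- six_node_model()$graph
  expect_setequal(neighborhood(g6, "N4"), c("N1", "N3", "N5"))
  expect_error(neighborhood(g6, "N9"), "unknown")
})

test_that("microcircuit construction enforces symmetry and simple-graph rules", {
  A <- matrix(FALSE, 2, 2); A[1, 2] <- TRUE
  expect_error(microcircuit(c("a", "b"), A), "symmetric")
  B <- diag(TRUE, 2)
  expect_error(microcircuit(c("a", "b"), B), "self-loops")
  g <- microcircuit_from_edges(c("a", "b", "c"),
                               rbind(c("a", "b"), c("b", "a"), c("a", "b")))
  expect_identical(n_edges(g), 1L) # duplicates collapse
})

test_that("gaussian MN structure comes from the precision matrix", {
  p <- chain_gmn_params(5, partial = 0.4)
  g <- gmn_structure(p)
  expect_identical(n_edges(g), 4L)
  expect_setequal(neighborhood(g, "V2"), c("V1", "V3"))
  # independent model: no edges despite numerical inversion noise
  ind <- gaussian_mn_params(rep(0, 4), diag(c(1, 2, 3, 4)))
  expect_identical(n_edges(gmn_structure(ind)), 0L)
  expect_error(gaussian_mn_params(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})
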