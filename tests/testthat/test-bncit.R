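# Independent BDeu oracle: loop over parent configurations and evaluate the
# Dirichlet-multinomial marginal with gamma functions directly.
bdeu_oracle <- function(y, Xp, ess) {
  k <- if (is.null(Xp)) 0L else ncol(Xp)
  q <- 2^k
  a <- ess / q
  ac <- ess / (2 * q)
  configs <- if (k) as.matrix(expand.grid(rep(list(0:1), k))) else
    matrix(0, 1, 0)
  total <- 0
  for (ci in seq_len(nrow(configs))) {
    sel <- rep(TRUE, length(y))
    if (k) for (j in seq_len(k)) sel <- sel & (Xp[, j] == configs[ci, j])
    n1 <- sum(y[sel])
    n0 <- sum(sel) - n1
    total <- total + lgamma(a) - lgamma(a + n0 + n1) +
      lgamma(ac + n1) - lgamma(ac) + lgamma(ac + n0) - lgamma(ac)
  }
  total
}

test_that("BDeu matches the closed-form Dirichlet-multinomial marginal", {
  # no parents: log[ G(1)/G(5) * G(1/2+3)G(1/2+1) / (G(1/2)G(1/2)) ]
  expect_equal(bdeu_family_score(c(1, 1, 0, 1), NULL, ess = 1),
               lgamma(1) - lgamma(5) +
                 lgamma(0.5 + 3) + lgamma(0.5 + 1) - 2 * lgamma(0.5),
               tolerance = 1e-12)
  set.seed(3)
  for (k in 0:3) {
    y <- rbinom(80, 1, 0.4)
    Xp <- if (k) matrix(rbinom(80 * k, 1, 0.5), ncol = k) else NULL
    for (ess in c(0.5, 1, 4)) {
      expect_equal(bdeu_family_score(y, Xp, ess), bdeu_oracle(y, Xp, ess),
                   tolerance = 1e-9)
    }
  }
  expect_error(bdeu_family_score(c(0, 2, 1), NULL), "binary")
})

test_that("BDeu satisfies likelihood equivalence and orderings of a complete DAG tie", {
  set.seed(9)
  x <- rbinom(60, 1, 0.5)
  y <- rbinom(60, 1, plogis(2 * x - 1))
  s1 <- bdeu_family_score(x, cbind(y)) + bdeu_family_score(y, NULL)
  s2 <- bdeu_family_score(y, cbind(x)) + bdeu_family_score(x, NULL)
  expect_equal(s1, s2, tolerance = 1e-9)

  # all 6 node orderings of the complete 3-node DAG give the same total score
  z <- rbinom(60, 1, plogis(x - y))
  cols <- list(x = x, y = y, z = z)
  totals <- apply(rbind(c("x", "y", "z"), c("x", "z", "y"), c("y", "x", "z"),
                        c("y", "z", "x"), c("z", "x", "y"), c("z", "y", "x")),
                  1, function(ord) {
    bdeu_family_score(cols[[ord[1]]], NULL) +
      bdeu_family_score(cols[[ord[2]]], cbind(cols[[ord[1]]])) +
      bdeu_family_score(cols[[ord[3]]], cbind(cols[[ord[1]]], cols[[ord[2]]]))
  })
  expect_equal(max(totals) - min(totals), 0, tolerance = 1e-9)
})

test_that("BIC matches its closed form and handles degenerate fits", {
  # child (0,1,2), no parents: sigma2 = 2/3, k = 2
  expect_equal(bic_family_score(c(0, 1, 2), NULL),
               -1.5 * log(2 * pi * 2 / 3) - 1.5 - log(3),
               tolerance = 1e-12)
  # perfect predictor engages the variance floor but must win
  set.seed(5)
  x <- rnorm(50)
  s_copy <- bic_family_score(x, cbind(x))
  s_null <- bic_family_score(x, NULL)
  expect_true(is.finite(s_copy))
  expect_gt(s_copy, s_null)
  # an irrelevant parent loses to the empty set at n = 1000
  y <- rnorm(1000)
  w <- rnorm(1000)
  expect_gt(bic_family_score(y, NULL), bic_family_score(y, cbind(w)))
  # collinear parents are dropped with a warning, not double-counted
  expect_warning(s_dup <- bic_family_score(x, cbind(x, x)), "collinear")
  expect_equal(s_dup, s_copy)
})

test_that("family scores are invariant to sample order", {
  set.seed(21)
  y <- rbinom(200, 1, 0.5)
  p <- matrix(rbinom(400, 1, 0.5), ncol = 2)
  perm <- sample(200)
  expect_equal(bdeu_family_score(y, p), bdeu_family_score(y[perm], p[perm, ]))
  yc <- rnorm(200)
  pc <- matrix(rnorm(400), ncol = 2)
  expect_equal(bic_family_score(yc, pc),
               bic_family_score(yc[perm], pc[perm, ]))
})

test_that("blanket search recovers the benchmark DAG blanket of C", {
  d <- sample_fig1_data(5000, seed = 1)
  mb <- find_markov_blanket(d, "C")
  expect_setequal(mb$members, c("A", "B", "D", "E"))
})

test_that("blanket search returns empty sets on independent data and perfect predictors", {
  set.seed(2)
  d <- data_matrix(matrix(rbinom(2000 * 5, 1, 0.5), ncol = 5,
                          dimnames = list(NULL, paste0("X", 1:5))))
  mb <- find_markov_blanket(d, "X3")
  expect_length(mb$members, 0)

  x <- rbinom(1000, 1, 0.5)
  d2 <- data_matrix(cbind(a = x, b = x,
                          c = rbinom(1000, 1, 0.5),
                          d = rbinom(1000, 1, 0.5)))
  expect_identical(find_markov_blanket(d2, "a")$members, "b")

  d3 <- data_matrix(cbind(k = rep(1, 50), x = rbinom(50, 1, 0.5)),
                    mode = "binary")
  expect_warning(mb3 <- find_markov_blanket(d3, "k"), "constant")
  expect_length(mb3$members, 0)
})

test_that("greedy blanket search is locally optimal and matches exhaustive search here", {
  d <- sample_fig1_data(5000, seed = 4)
  cfg <- score_config("bdeu")
  mb <- find_markov_blanket(d, "C", cfg)
  y <- d$values[, "C"]
  cand <- setdiff(d$node_labels, "C")
  sc <- function(set) bdeu_family_score(y, if (length(set))
    d$values[, set, drop = FALSE], cfg$ess)
  s_greedy <- sc(mb$members)
  # no single addition or removal improves the final score
  for (c in setdiff(cand, mb$members))
    expect_lte(sc(c(mb$members, c)), s_greedy + cfg$eps)
  for (s in mb$members)
    expect_lte(sc(setdiff(mb$members, s)), s_greedy + cfg$eps)
  # exhaustive enumeration over all 2^4 candidate subsets: regret is zero here
  subsets <- unlist(lapply(0:4, function(k)
    combn(cand, k, simplify = FALSE)), recursive = FALSE)
  best <- max(vapply(subsets, sc, numeric(1)))
  expect_gte(best, s_greedy)
  expect_equal(best, s_greedy, tolerance = 1e-9)
})

test_that("score/mode pairing and max_parents are enforced", {
  d <- sample_fig1_data(200, seed = 8)
  expect_error(find_markov_blanket(d, "C", score_config("bic")),
               "continuous")
  mb <- find_markov_blanket(d, "C", score_config("bdeu", max_parents = 1))
  expect_lte(length(mb$members), 1L)
})
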