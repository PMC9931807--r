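# Shared fixtures: a five-node benchmark DAG (collider D makes E a co-parent
# of C) and a forward sampler for it, plus a generic random-DAG generator for
# property-style tests. All data are generated in code at test time.

fig1_dag <- function() {
  directed_graph(LETTERS[1:5],
                 parents = list(C = c("A", "B"), D = c("C", "E")))
}

# Strong, asymmetric CPTs so that every blanket member is marginally
# informative and the collider coupling between C and E given D is strong.
sample_fig1_data <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- rbinom(n, 1, 0.5)
  B <- rbinom(n, 1, 0.5)
  E <- rbinom(n, 1, 0.5)
  pC <- c(0.05, 0.65, 0.35, 0.95)[1 + A + 2 * B]
  C <- rbinom(n, 1, pC)
  pD <- c(0.05, 0.70, 0.30, 0.95)[1 + C + 2 * E]
  D <- rbinom(n, 1, pD)
  data_matrix(cbind(A = A, B = B, C = C, D = D, E = E))
}

# Random DAG over n nodes: each node draws parents from its predecessors in a
# random topological order.
random_dag <- function(n_nodes, p_edge = 0.35) {
  labs <- paste0("X", seq_len(n_nodes))
  ord <- sample(labs)
  parents <- list()
  for (i in seq_along(ord)) {
    if (i == 1L) next
    pool <- ord[seq_len(i - 1L)]
    pa <- pool[runif(length(pool)) < p_edge]
    if (length(pa)) parents[[ord[i]]] <- pa
  }
  directed_graph(labs, parents)
}
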