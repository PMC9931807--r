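#' Sorensen-Dice similarity between two microcircuits
#'
#' `2 |Ea & Eb| / (|Ea| + |Eb|)` on the edge sets: 1 for a perfect match, 0
#' for no overlap. Two edgeless graphs are identical objects, so their
#' similarity is defined as 1.
#'
#' @param a,b [microcircuit()]s over the same node set.
#' @return similarity in `[0, 1]`.
#' @export
dice_similarity <- function(a, b) {
  stopifnot(inherits(a, "microcircuit"), inherits(b, "microcircuit"))
  if (!setequal(a$node_labels, b$node_labels))
    stop("node sets differ between the two graphs")
  Bb <- b$adjacency[a$node_labels, a$node_labels]
  ut <- upper.tri(a$adjacency)
  na <- sum(a$adjacency[ut])
  nb <- sum(Bb[ut])
  if (na + nb == 0L) return(1)
  2 * sum(a$adjacency[ut] & Bb[ut]) / (na + nb)
}

#' Pairwise Dice similarity matrix for a graph collection
#'
#' @param graphs list of [microcircuit()]s over a shared node set.
#' @return symmetric numeric matrix with unit diagonal.
#' @export
similarity_matrix <- function(graphs) {
  if (!length(graphs)) stop("empty graph list")
  n <- length(graphs)
  S <- diag(1, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    S[i, j] <- S[j, i] <- dice_similarity(graphs[[i]], graphs[[j]])
  }
  S
}

#' Detect microcircuit subtypes by modularity clustering
#'
#' Runs multi-level (Louvain) modularity optimization on the weighted graph
#' whose edge weights are the pairwise similarities (self-loops removed,
#' weights below 1e-12 dropped). Deterministic given `seed`.
#'
#' @param sim square symmetric similarity matrix with entries in `[0, 1]`.
#' @param seed optional integer seed (Louvain visits vertices in a
#'   random order).
#' @param resolution modularity resolution parameter.
#' @return integer vector of cluster labels, one per row of `sim`.
#' @export
detect_subtypes <- function(sim, seed = NULL, resolution = 1) {
  sim <- as.matrix(sim)
  if (nrow(sim) == 0L) stop("empty similarity matrix")
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
  if (max(abs(sim - t(sim))) > 1e-8) stop("similarity matrix must be symmetric")
  if (min(sim) < -1e-12 || max(sim) > 1 + 1e-12)
    stop("similarities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  W <- sim
  diag(W) <- 0
  W[W < 1e-12] <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0L) return(seq_len(nrow(sim)) * 0L + 1L)
  as.integer(igraph::membership(
    igraph::cluster_louvain(g, resolution = resolution)))
}

#' Representative graph of each cluster
#'
#' For every cluster, the member graph with the largest mean Dice similarity
#' to its co-members (ties broken by the lowest index; singleton clusters
#' return their only member).
#'
#' @param graphs list of [microcircuit()]s.
#' @param labels cluster label per graph (from [detect_subtypes()]).
#' @param sim optional precomputed [similarity_matrix()] of `graphs`.
#' @return named integer vector mapping cluster label to the representative
#'   graph's index.
#' @export
representative_graph <- function(graphs, labels, sim = NULL) {
  if (length(graphs) != length(labels))
    stop("labels must align with graphs")
  if (is.null(sim)) sim <- similarity_matrix(graphs)
  out <- integer(0)
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    if (!length(members)) next
    if (length(members) == 1L) {
      rep_idx <- members
    } else {
      meansim <- vapply(members, function(i)
        mean(sim[i, setdiff(members, i)]), numeric(1))
      rep_idx <- members[which.max(meansim)]
    }
    out[as.character(cl)] <- rep_idx
  }
  out
}

#' Graph-level centrality score
#'
#' Computes a node-level centrality for every node and averages across nodes.
#' Betweenness counts, for each node, the fraction of shortest paths between
#' other node pairs passing through it (unnormalized node scores by default).
#' Eigenvector centrality is the principal eigenvector of the adjacency
#' matrix, taken entrywise nonnegative and scaled to unit Euclidean norm
#' before averaging; it is undefined on an edgeless graph.
#'
#' @param g a [microcircuit()].
#' @param metric `"betweenness"` or `"eigenvector"`.
#' @param normalized for betweenness, whether to normalize node scores by
#'   `(n-1)(n-2)/2`.
#' @return scalar graph-level score.
#' @export
graph_centrality <- function(g, metric = c("betweenness", "eigenvector"),
                             normalized = FALSE) {
  stopifnot(inherits(g, "microcircuit"))
  metric <- match.arg(metric)
  if (metric == "betweenness") {
    ig <- .mc_as_igraph(g)
    return(mean(igraph::betweenness(ig, directed = FALSE,
                                    normalized = normalized)))
  }
  if (n_edges(g) == 0L)
    stop("eigenvector centrality is undefined for an edgeless graph")
  ev <- eigen(g$adjacency * 1, symmetric = TRUE)
  v <- abs(ev$vectors[, 1L])
  mean(v / sqrt(sum(v^2)))
}

#' Two-sample t-test between subtype score groups
#'
#' Pooled-variance two-sample t statistic with a two-tailed p-value. The
#' pooled variance is floored at a tiny positive value so that perfectly
#' separated constant groups yield a huge |t| with p near 0 instead of 0/0;
#' identical constant groups yield t = 0, p = 1. Set `var_equal = FALSE` for
#' the Welch variant (via [stats::t.test()]).
#'
#' @param scores numeric vector of per-graph scores.
#' @param labels group label per score; exactly two groups, each with at
#'   least two observations.
#' @param var_equal pooled (TRUE, default) or Welch (FALSE).
#' @return list with `statistic`, `p.value`, `df`, and `means` (named group
#'   means).
#' @export
compare_subtypes <- function(scores, labels, var_equal = TRUE) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  groups <- split(scores, labels)
  if (length(groups) != 2L)
    stop("need exactly two groups, got ", length(groups))
  n1 <- length(groups[[1L]]); n2 <- length(groups[[2L]])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least two observations")
  means <- vapply(groups, mean, numeric(1))
  if (!var_equal) {
    ht <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = FALSE)
    return(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                df = unname(ht$parameter), means = means))
  }
  sp2 <- ((n1 - 1) * var(groups[[1L]]) + (n2 - 1) * var(groups[[2L]])) /
    (n1 + n2 - 2)
  sp2 <- max(sp2, 1e-300)
  tval <- (means[[1L]] - means[[2L]]) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = tval, p.value = 2 * pt(-abs(tval), df), df = df,
       means = means)
}

#' Cluster-to-type prediction accuracy
#'
#' Assigns every cluster its majority type and reports the fraction of
#' graphs whose type matches their cluster's majority (cluster purity) —
#' how predictive the detected subtypes are of the true trial types.
#'
#' @param labels cluster label per graph.
#' @param types true type per graph.
#' @return accuracy in `[0, 1]`.
#' @export
label_accuracy <- function(labels, types) {
  if (length(labels) != length(types)) stop("length mismatch")
  tab <- table(labels, types)
  sum(apply(tab, 1L, max)) / length(labels)
}

#' Full microcircuit subtype pipeline
#'
#' Similarity matrix, multi-level modularity clustering, per-cluster
#' representative graphs, graph-level betweenness and eigenvector centrality,
#' and (when exactly two subtypes are found) two-sample t-tests contrasting
#' the centrality scores across subtypes. Graphs on which eigenvector
#' centrality is undefined (edgeless) get `NA` with a warning and are dropped
#' from that contrast.
#'
#' @param graphs list of [microcircuit()]s over a shared node set.
#' @param types optional true trial type per graph; when given, the
#'   cluster-to-type [label_accuracy()] is reported.
#' @param seed optional integer seed for the clustering.
#' @return An object of class `bca_subtypes`: list with `similarity`,
#'   `labels`, `representatives`, `centrality` (data frame with per-graph
#'   scores), `tests` (list of [compare_subtypes()] results or NULL), and
#'   `accuracy` (or NULL).
#' @export
subtype_pipeline <- function(graphs, types = NULL, seed = NULL) {
  sim <- similarity_matrix(graphs)
  labels <- detect_subtypes(sim, seed = seed)
  reps <- representative_graph(graphs, labels, sim)
  betw <- vapply(graphs, graph_centrality, numeric(1), metric = "betweenness")
  eig <- vapply(graphs, function(g)
    tryCatch(graph_centrality(g, "eigenvector"),
             error = function(e) { warning(conditionMessage(e)); NA_real_ }),
    numeric(1))
  centrality <- data.frame(graph = seq_along(graphs), cluster = labels,
                           betweenness = betw, eigenvector = eig)
  tests <- NULL
  if (length(unique(labels)) == 2L) {
    tests <- list(
      betweenness = compare_subtypes(betw, labels),
      eigenvector = if (sum(!is.na(eig)) >= 4L)
        compare_subtypes(eig, labels) else NULL)
  }
  accuracy <- if (!is.null(types)) label_accuracy(labels, types) else NULL
  structure(list(similarity = sim, labels = labels, representatives = reps,
                 centrality = centrality, tests = tests, accuracy = accuracy),
            class = "bca_subtypes")
}

#' @export
print.bca_subtypes <- function(x, ...) {
  cat(sprintf("<bca_subtypes> %d graphs, %d subtype(s)%s\n",
              length(x$labels), length(unique(x$labels)),
              if (!is.null(x$accuracy))
                sprintf(", type accuracy %.2f", x$accuracy) else ""))
  invisible(x)
}
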