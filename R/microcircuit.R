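#' Undirected microcircuit graph
#'
#' A microcircuit is a simple undirected graph over labelled nodes: a symmetric
#' logical adjacency matrix with an all-FALSE diagonal. It is the output type
#' of every structure-learning method in the package and the container for
#' ground-truth graphs.
#'
#' @param node_labels character vector of unique node names.
#' @param adjacency symmetric logical (or 0/1) matrix with FALSE diagonal;
#'   defaults to the edgeless graph.
#' @return An object of class `microcircuit`: list with `node_labels` and
#'   `adjacency` (logical matrix, dimnames set to the labels).
#' @seealso [microcircuit_from_edges()], [edge_list()], [neighborhood()]
#' @export
microcircuit <- function(node_labels, adjacency = NULL) {
  node_labels <- as.character(node_labels)
  n <- length(node_labels)
  if (n < 1L) stop("need at least one node")
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  if (is.null(adjacency)) adjacency <- matrix(FALSE, n, n)
  adjacency <- as.matrix(adjacency)
  if (!all(dim(adjacency) == c(n, n)))
    stop("adjacency must be ", n, " x ", n)
  storage.mode(adjacency) <- "logical"
  if (anyNA(adjacency)) stop("adjacency must not contain NA")
  if (!identical(adjacency, t(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency))) stop("self-loops are not allowed")
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(list(node_labels = node_labels, adjacency = adjacency),
            class = "microcircuit")
}

#' Build a microcircuit from an edge list
#'
#' @param node_labels character vector of unique node names.
#' @param edges two-column matrix or data frame of node labels (one edge per
#'   row), or NULL for the edgeless graph. Duplicate rows and reversed
#'   duplicates collapse to a single edge.
#' @return a [microcircuit()].
#' @export
microcircuit_from_edges <- function(node_labels, edges = NULL) {
  g <- microcircuit(node_labels)
  if (is.null(edges) || NROW(edges) == 0L) return(g)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("`edges` must have two columns")
  edges[] <- as.character(edges)
  unknown <- setdiff(c(edges), node_labels)
  if (length(unknown))
    stop("unknown node label(s) in edges: ", paste(unknown, collapse = ", "))
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  A <- g$adjacency
  A[edges] <- TRUE
  A[edges[, 2:1, drop = FALSE]] <- TRUE
  microcircuit(node_labels, A)
}

#' @export
print.microcircuit <- function(x, ...) {
  cat(sprintf("<microcircuit> %d nodes, %d edges\n",
              length(x$node_labels), n_edges(x)))
  invisible(x)
}

#' Number of edges in a microcircuit
#' @param g a [microcircuit()].
#' @return integer edge count (each unordered pair counted once).
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "microcircuit"))
  sum(g$adjacency) %/% 2L
}

#' Edge list of a microcircuit
#'
#' @param g a [microcircuit()].
#' @return character matrix with two columns; each row is one edge with the
#'   two labels in lexicographic order, rows sorted lexicographically.
#' @export
edge_list <- function(g) {
  stopifnot(inherits(g, "microcircuit"))
  idx <- which(g$adjacency & upper.tri(g$adjacency), arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(matrix(character(0), 0, 2, dimnames = list(NULL, c("from", "to"))))
  a <- g$node_labels[idx[, 1L]]
  b <- g$node_labels[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  el <- cbind(from = a, to = b)
  el[order(el[, 1L], el[, 2L]), , drop = FALSE]
}

#' Neighborhood of a node in a microcircuit
#'
#' In a Markov network the Markov blanket of a node is exactly its
#' neighborhood, so this is the undirected counterpart of
#' [dag_markov_blanket()].
#'
#' @param g a [microcircuit()].
#' @param node a node label present in `g`.
#' @return character vector of adjacent node labels (possibly empty).
#' @examples
#' g <- microcircuit_from_edges(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' neighborhood(g, "C") # "B"
#' @export
neighborhood <- function(g, node) {
  stopifnot(inherits(g, "microcircuit"))
  if (!node %in% g$node_labels) stop("unknown node: ", node)
  g$node_labels[g$adjacency[node, ]]
}

#' Restrict a microcircuit to a subset of nodes
#' @param g a [microcircuit()].
#' @param nodes labels to keep.
#' @return the induced subgraph as a [microcircuit()] over `nodes`.
#' @export
mc_subgraph <- function(g, nodes) {
  stopifnot(inherits(g, "microcircuit"))
  nodes <- as.character(nodes)
  missing <- setdiff(nodes, g$node_labels)
  if (length(missing))
    stop("unknown node label(s): ", paste(missing, collapse = ", "))
  microcircuit(nodes, g$adjacency[nodes, nodes, drop = FALSE])
}

.mc_as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Directed acyclic graph over labelled nodes
#'
#' Minimal Bayesian-network structure type: each node carries a parent set.
#' Used for exact Markov-blanket extraction and moralization; the package uses
#' DAGs as computational devices, not causal claims.
#'
#' @param node_labels character vector of unique node names.
#' @param parents named list mapping a node label to a character vector of its
#'   parents. Nodes absent from the list have no parents.
#' @return An object of class `bca_dag` with fields `node_labels` and
#'   `parents` (complete named list, one entry per node).
#' @export
directed_graph <- function(node_labels, parents = list()) {
  node_labels <- as.character(node_labels)
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  if (length(parents) && is.null(names(parents)))
    stop("`parents` must be a named list")
  unknown <- setdiff(names(parents), node_labels)
  if (length(unknown))
    stop("parent sets given for unknown node(s): ",
         paste(unknown, collapse = ", "))
  full <- setNames(vector("list", length(node_labels)), node_labels)
  for (v in node_labels) {
    p <- unique(as.character(parents[[v]]))
    bad <- setdiff(p, node_labels)
    if (length(bad))
      stop("unknown parent label(s) for ", v, ": ", paste(bad, collapse = ", "))
    if (v %in% p) stop("node ", v, " cannot be its own parent")
    full[[v]] <- p
  }
  # Kahn's algorithm: every node must be removable once its parents are gone
  indeg <- vapply(full, length, integer(1))
  children <- setNames(vector("list", length(node_labels)), node_labels)
  for (v in node_labels) for (p in full[[v]])
    children[[p]] <- c(children[[p]], v)
  queue <- node_labels[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(node_labels)) stop("graph contains a directed cycle")
  structure(list(node_labels = node_labels, parents = full),
            class = "bca_dag")
}

#' @export
print.bca_dag <- function(x, ...) {
  ne <- sum(vapply(x$parents, length, integer(1)))
  cat(sprintf("<bca_dag> %d nodes, %d directed edges\n",
              length(x$node_labels), ne))
  invisible(x)
}

.dag_children <- function(g, node) {
  has <- vapply(g$parents, function(p) node %in% p, logical(1))
  g$node_labels[has[g$node_labels]]
}

#' Markov blanket of a node in a DAG
#'
#' Parents, children, and the other parents of each child (co-parents). This
#' is the set that renders the node conditionally independent of the rest of
#' the network, and it coincides with the node's neighborhood in the
#' moralized graph.
#'
#' @param g a [directed_graph()].
#' @param node a node label present in `g`.
#' @return character vector of blanket members (never includes `node`).
#' @examples
#' g <- directed_graph(LETTERS[1:5],
#'                     parents = list(C = c("A", "B"), D = c("C", "E")))
#' sort(dag_markov_blanket(g, "C")) # A B D E
#' @export
dag_markov_blanket <- function(g, node) {
  stopifnot(inherits(g, "bca_dag"))
  if (!node %in% g$node_labels) stop("unknown node: ", node)
  ch <- .dag_children(g, node)
  coparents <- unlist(lapply(ch, function(c) g$parents[[c]]), use.names = FALSE)
  out <- unique(c(g$parents[[node]], ch, coparents))
  setdiff(out, node)
}

#' Moralize a DAG into a microcircuit
#'
#' Drops edge directions and connects every pair of co-parents ("marries"
#' them). For every node, its neighborhood in the result equals its Markov
#' blanket in the input DAG.
#'
#' @param g a [directed_graph()].
#' @return a [microcircuit()] over the same nodes.
#' @export
moralize <- function(g) {
  stopifnot(inherits(g, "bca_dag"))
  labs <- g$node_labels
  A <- matrix(FALSE, length(labs), length(labs), dimnames = list(labs, labs))
  for (v in labs) {
    pa <- g$parents[[v]]
    for (p in pa) {
      A[v, p] <- A[p, v] <- TRUE
    }
    if (length(pa) > 1L) {
      for (i in seq_len(length(pa) - 1L)) for (j in seq(i + 1L, length(pa))) {
        A[pa[i], pa[j]] <- A[pa[j], pa[i]] <- TRUE
      }
    }
  }
  microcircuit(labs, A)
}

#' Markov blanket result
#'
#' Pairs a target node with the member set detected for it.
#'
#' @param target node label.
#' @param members character vector of blanket members (must not contain
#'   `target`).
#' @return An object of class `markov_blanket`.
#' @export
markov_blanket <- function(target, members = character(0)) {
  target <- as.character(target)
  members <- unique(as.character(members))
  if (target %in% members) stop("target cannot be a member of its own blanket")
  structure(list(target = target, members = members), class = "markov_blanket")
}

#' @export
print.markov_blanket <- function(x, ...) {
  cat(sprintf("mb*(%s) = {%s}\n", x$target, paste(x$members, collapse = ", ")))
  invisible(x)
}
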