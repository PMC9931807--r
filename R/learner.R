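#' Drop inactive (constant) nodes from a data matrix
#'
#' Columns with zero variance — e.g. neurons that never fired during the
#' recording — carry no information for structure learning and break the
#' score functions, so they are removed before learning. The dropped labels
#' are reported rather than silently lost.
#'
#' @param data a [data_matrix()].
#' @return list with `data` (reduced matrix, mode preserved) and `dropped`
#'   (character vector of removed labels, possibly empty).
#' @export
filter_inactive_nodes <- function(data) {
  stopifnot(inherits(data, "bca_data"))
  v <- apply(data$values, 2L, var)
  keep <- v > 0
  if (!any(keep)) stop("all columns are constant")
  dropped <- data$node_labels[!keep]
  out <- if (all(keep)) data else
    data_matrix(data$values[, keep, drop = FALSE], mode = data$mode,
                node_labels = data$node_labels[keep])
  list(data = out, dropped = dropped)
}

#' Learn per-node Markov blankets
#'
#' Runs [find_markov_blanket()] once per node, each time with that node as
#' the leaf and all other nodes as candidate parents. The per-node searches
#' are independent, so the result does not depend on the order in which nodes
#' are processed.
#'
#' @param data a [data_matrix()] without constant columns.
#' @param cfg a [score_config()] (default chosen from the data mode).
#' @return An object of class `blanket_collection`: list with `blankets`
#'   (named list of [markov_blanket()]s, one per node) and `config`.
#' @export
learn_blankets <- function(data, cfg = NULL) {
  stopifnot(inherits(data, "bca_data"))
  if (is.null(cfg))
    cfg <- score_config(if (data$mode == "binary") "bdeu" else "bic")
  bl <- lapply(data$node_labels, function(v) find_markov_blanket(data, v, cfg))
  names(bl) <- data$node_labels
  structure(list(blankets = bl, config = cfg), class = "blanket_collection")
}

#' @export
print.blanket_collection <- function(x, ...) {
  cat(sprintf("<blanket_collection> %d nodes (%s score)\n",
              length(x$blankets), x$config$score_type))
  invisible(x)
}

#' Combine per-node blankets into one microcircuit
#'
#' Under the default OR rule, nodes i and j are connected when i is in the
#' detected blanket of j *or* j is in the detected blanket of i — the
#' sensitivity-restoring combination step. An AND variant (both memberships
#' required) is available for experimentation.
#'
#' @param bc a `blanket_collection` from [learn_blankets()].
#' @param rule `"OR"` (default) or `"AND"`.
#' @return a [microcircuit()] over the collection's nodes.
#' @export
combine_blankets <- function(bc, rule = c("OR", "AND")) {
  stopifnot(inherits(bc, "blanket_collection"))
  rule <- match.arg(rule)
  labs <- names(bc$blankets)
  n <- length(labs)
  M <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (v in labs) {
    m <- bc$blankets[[v]]$members
    if (length(m)) M[v, m] <- TRUE
  }
  A <- if (rule == "OR") M | t(M) else M & t(M)
  diag(A) <- FALSE
  microcircuit(labs, A)
}

#' Learn a microcircuit from activity data
#'
#' The full node-wise pipeline: drop constant columns, detect one Markov
#' blanket per remaining node with the target as leaf, and combine the
#' blankets into an undirected graph. Dropped nodes reappear in the output as
#' isolated nodes so that evaluation against a ground truth over the full
#' node set stays well-defined; their labels are attached as the `"dropped"`
#' attribute.
#'
#' @param data a [data_matrix()] (binary or continuous).
#' @param cfg a [score_config()]; default is BDeu with `ess = 1` for binary
#'   data and BIC for continuous data.
#' @param combine `"OR"` (default) or `"AND"` blanket combination.
#' @return a [microcircuit()] over all input nodes, with attributes
#'   `"dropped"` (labels of constant columns) and `"blankets"` (the
#'   `blanket_collection`).
#' @examples
#' m <- six_node_model()
#' d <- sample_ising_mh(m$params, 2000, seed = 1)
#' g <- learn_microcircuit(d)
#' n_edges(g)
#' @export
learn_microcircuit <- function(data, cfg = NULL, combine = c("OR", "AND")) {
  combine <- match.arg(combine)
  filt <- filter_inactive_nodes(data)
  bc <- learn_blankets(filt$data, cfg)
  g0 <- combine_blankets(bc, combine)
  labs <- data$node_labels
  A <- matrix(FALSE, length(labs), length(labs), dimnames = list(labs, labs))
  keep <- filt$data$node_labels
  A[keep, keep] <- g0$adjacency
  out <- microcircuit(labs, A)
  attr(out, "dropped") <- filt$dropped
  attr(out, "blankets") <- bc
  out
}
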