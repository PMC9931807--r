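#' Detect the Markov blanket of one node
#'
#' Leaf-node blanket discovery: the target is treated as the leaf of a
#' Bayesian network and all remaining nodes are candidate parents. Greedy
#' hill-climbing starts from the empty parent set and repeatedly applies the
#' single addition or single removal that most improves the family score of
#' the target (BDeu for binary data, BIC for continuous), stopping when no
#' move improves the score by more than `cfg$eps`. The returned parent set is
#' the detected blanket, a subset of the target's true Markov blanket under
#' the method's faithfulness assumptions.
#'
#' Among equal-gain moves the candidate with the lowest column index wins, so
#' the search is deterministic given the data.
#'
#' @param data a [data_matrix()]; its mode must match the score family
#'   (binary for BDeu, continuous for BIC).
#' @param target label of the node whose blanket is sought.
#' @param cfg a [score_config()]; default picks BDeu or BIC from the data
#'   mode.
#' @return a [markov_blanket()] object. A constant target column yields an
#'   empty blanket with a warning.
#' @examples
#' set.seed(1)
#' x <- rbinom(500, 1, 0.5)
#' d <- data_matrix(cbind(a = x, b = x, c = rbinom(500, 1, 0.5)))
#' find_markov_blanket(d, "a")$members # "b"
#' @export
find_markov_blanket <- function(data, target, cfg = NULL) {
  stopifnot(inherits(data, "bca_data"))
  if (is.null(cfg))
    cfg <- score_config(if (data$mode == "binary") "bdeu" else "bic")
  stopifnot(inherits(cfg, "score_config"))
  if (cfg$score_type == "bdeu" && data$mode != "binary")
    stop("BDeu scoring requires binary data")
  if (cfg$score_type == "bic" && data$mode != "continuous")
    stop("BIC scoring requires continuous data")
  labs <- data$node_labels
  if (!target %in% labs) stop("unknown node: ", target)

  X <- data$values
  if (cfg$score_type == "bdeu") storage.mode(X) <- "integer"
  y <- X[, target]
  if (var(as.numeric(y)) == 0) {
    warning("target '", target, "' is constant; returning an empty blanket")
    return(markov_blanket(target))
  }
  scorer <- if (cfg$score_type == "bdeu") {
    function(cols) .bdeu_score(y, if (length(cols)) X[, cols, drop = FALSE], cfg$ess)
  } else {
    function(cols) .bic_score(y, if (length(cols)) X[, cols, drop = FALSE],
                              cfg$variance_floor)$score
  }

  cand <- setdiff(labs, target)
  S <- character(0)
  cur <- scorer(S)
  repeat {
    moves <- list()
    if (length(S) < cfg$max_parents) {
      for (c in cand[!cand %in% S]) moves[[length(moves) + 1L]] <- c(S, c)
    }
    for (s in S) moves[[length(moves) + 1L]] <- setdiff(S, s)
    if (!length(moves)) break
    scores <- vapply(moves, scorer, numeric(1))
    best <- which.max(scores) # first max: lowest-index tie-break
    if (scores[best] - cur <= cfg$eps) break
    S <- moves[[best]]
    cur <- scores[best]
  }
  # report members in node order for reproducible printing
  markov_blanket(target, labs[labs %in% S])
}
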