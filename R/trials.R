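#' Default two-subtype trial templates
#'
#' Two Gaussian Markov networks over the same nodes with disjoint edge sets,
#' used as generating structures for the synthetic per-trial collection: type
#' "a" is the chain over the natural node order, type "b" the chain over the
#' odd-then-even reordering (consecutive labels are never adjacent, so no
#' edge is shared with type "a"). Both have `n_nodes - 1` edges of equal
#' partial-correlation strength.
#'
#' @param n_nodes number of nodes per template.
#' @param partial partial correlation on template edges.
#' @return list with `a` and `b`, both [gaussian_mn_params()].
#' @export
default_trial_templates <- function(n_nodes = 20, partial = 0.35) {
  labels <- paste0("L", seq_len(n_nodes))
  ord_a <- seq_len(n_nodes)
  ord_b <- c(seq(1, n_nodes, by = 2), seq(2, n_nodes, by = 2))
  edges_a <- cbind(ord_a[-n_nodes], ord_a[-1])
  edges_b <- cbind(ord_b[-n_nodes], ord_b[-1])
  list(a = gaussian_mn_params(rep(0, n_nodes),
                              solve(.precision_from_edges(n_nodes, edges_a, partial)),
                              labels),
       b = gaussian_mn_params(rep(0, n_nodes),
                              solve(.precision_from_edges(n_nodes, edges_b, partial)),
                              labels))
}

# Toggle a fraction of the precision edges: remove n_flip present edges and
# add n_flip absent ones at the median absolute off-diagonal weight.
.perturb_precision <- function(K, flip_noise) {
  n <- nrow(K)
  ut <- which(upper.tri(K), arr.ind = TRUE)
  vals <- K[ut]
  present <- which(vals != 0)
  absent <- which(vals == 0)
  n_flip <- round(flip_noise * length(present))
  if (n_flip == 0L) return(K)
  drop_idx <- present[sample.int(length(present), min(n_flip, length(present)))]
  add_idx <- absent[sample.int(length(absent), min(n_flip, length(absent)))]
  w <- stats::median(abs(vals[present]))
  out <- K
  for (idx in drop_idx) {
    i <- ut[idx, 1L]; j <- ut[idx, 2L]
    out[i, j] <- out[j, i] <- 0
  }
  for (idx in add_idx) {
    i <- ut[idx, 1L]; j <- ut[idx, 2L]
    out[i, j] <- out[j, i] <- -w
  }
  for (it in 1:60) {
    ok <- tryCatch({ chol(out); TRUE }, error = function(e) FALSE)
    if (ok) return(out)
    out[row(out) != col(out)] <- out[row(out) != col(out)] * 0.95
  }
  stop("could not make the perturbed precision positive definite")
}

#' Generate a synthetic two-subtype trial collection
#'
#' Emulates a per-trial calcium-imaging design with two trial types: every
#' trial draws `n_samples` observations from its type's Gaussian Markov
#' network template, optionally with a fraction `flip_noise` of the
#' template's precision edges toggled (removed and replaced by random absent
#' pairs) independently per trial. With `flip_noise = 0` all trials of a type
#' share the same generating structure.
#'
#' @param n_trials_per_type trials per type (total is twice this).
#' @param template_a,template_b [gaussian_mn_params()] over the same node
#'   count; defaults to [default_trial_templates()].
#' @param n_samples observations per trial.
#' @param flip_noise fraction of precision edges perturbed per trial, in
#'   `[0, 1]`.
#' @param seed optional integer seed.
#' @return list with `trials` (list of continuous [data_matrix()]s), `types`
#'   (character vector `"a"`/`"b"`, one per trial), and `structures` (the
#'   per-trial generating [microcircuit()]s).
#' @export
generate_trial_collection <- function(n_trials_per_type = 25,
                                      template_a = NULL, template_b = NULL,
                                      n_samples = 300, flip_noise = 0,
                                      seed = NULL) {
  if (is.null(template_a) || is.null(template_b)) {
    tpl <- default_trial_templates()
    if (is.null(template_a)) template_a <- tpl$a
    if (is.null(template_b)) template_b <- tpl$b
  }
  stopifnot(inherits(template_a, "gmn_params"),
            inherits(template_b, "gmn_params"))
  if (template_a$n != template_b$n)
    stop("templates must share the node count")
  if (flip_noise < 0 || flip_noise > 1) stop("flip_noise must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  templates <- list(a = template_a, b = template_b)
  trials <- list()
  types <- character(0)
  structures <- list()
  for (ty in c("a", "b")) {
    tpl <- templates[[ty]]
    K0 <- gmn_precision(tpl)
    for (k in seq_len(n_trials_per_type)) {
      K <- .perturb_precision(K0, flip_noise)
      p <- gaussian_mn_params(tpl$mu, solve(K), tpl$node_labels)
      trials[[length(trials) + 1L]] <- sample_gaussian_mn(p, n_samples)
      structures[[length(structures) + 1L]] <- gmn_structure(p)
      types <- c(types, ty)
    }
  }
  list(trials = trials, types = types, structures = structures)
}
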