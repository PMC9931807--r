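#' Evaluate a learned microcircuit against a ground truth
#'
#' Counts true positives (edges in both graphs) and false positives (edges in
#' the estimate absent from the truth) over all node pairs; the true positive
#' rate divides by the number of ground-truth edges and the false positive
#' rate by the number of ground-truth empty pairs. Sensitivity equals TPR and
#' specificity equals 1 - FPR.
#'
#' @param est estimated [microcircuit()].
#' @param gt ground-truth [microcircuit()].
#' @param nodes optional node subset on which to evaluate (both graphs are
#'   restricted to it first); without it the two node sets must coincide.
#' @return An object of class `bca_eval`: list with `n_edges_gt`,
#'   `n_empty_gt`, `tp`, `fp`, `fn`, `tn`, `tpr`, `fpr`. Rates are `NA` when
#'   their denominator is zero.
#' @export
evaluate_structure <- function(est, gt, nodes = NULL) {
  stopifnot(inherits(est, "microcircuit"), inherits(gt, "microcircuit"))
  if (!is.null(nodes)) {
    est <- mc_subgraph(est, nodes)
    gt <- mc_subgraph(gt, nodes)
  } else if (!setequal(est$node_labels, gt$node_labels)) {
    stop("node sets differ; pass `nodes` to evaluate on a subset")
  }
  Ae <- est$adjacency[gt$node_labels, gt$node_labels]
  Ag <- gt$adjacency
  ut <- upper.tri(Ag)
  tp <- sum(Ae[ut] & Ag[ut])
  fp <- sum(Ae[ut] & !Ag[ut])
  n_edges_gt <- sum(Ag[ut])
  n_empty_gt <- sum(!Ag[ut])
  structure(list(n_edges_gt = n_edges_gt, n_empty_gt = n_empty_gt,
                 tp = tp, fp = fp,
                 fn = n_edges_gt - tp, tn = n_empty_gt - fp,
                 tpr = if (n_edges_gt > 0) tp / n_edges_gt else NA_real_,
                 fpr = if (n_empty_gt > 0) fp / n_empty_gt else NA_real_),
            class = "bca_eval")
}

#' @export
print.bca_eval <- function(x, ...) {
  cat(sprintf("#edge %d  #empty %d  TP %d  FP %d  TPR %.2f  FPR %.2f\n",
              x$n_edges_gt, x$n_empty_gt, x$tp, x$fp, x$tpr, x$fpr))
  invisible(x)
}
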