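#' Activity data matrix
#'
#' Container for an `n_samples x n_nodes` neural-activity matrix, the dataset
#' fed to every structure-learning routine in the package. Rows are samples
#' (time bins or trials), columns are nodes (neurons). The `mode` flag records
#' whether values are binary spikes per bin (`"binary"`) or continuous
#' signals such as normalized fluorescence (`"continuous"`).
#'
#' @param values numeric matrix (or object coercible to one), samples in rows.
#' @param mode `"binary"`, `"continuous"`, or `"auto"` (default): auto resolves
#'   to binary exactly when every value is 0 or 1.
#' @param node_labels character vector of unique node names; defaults to the
#'   column names of `values`, or `V1..Vn` when absent.
#' @return An object of class `bca_data`: a list with elements `values`
#'   (numeric matrix with `node_labels` as column names), `mode`, and
#'   `node_labels`.
#' @examples
#' d <- data_matrix(matrix(c(0, 1, 1, 0), 2), node_labels = c("a", "b"))
#' d$mode # "binary"
#' @export
data_matrix <- function(values, mode = c("auto", "binary", "continuous"),
                        node_labels = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L) stop("need at least one sample (row)")
  if (anyNA(values)) stop("missing values are not supported")
  if (is.null(node_labels)) {
    node_labels <- colnames(values)
    if (is.null(node_labels)) node_labels <- paste0("V", seq_len(ncol(values)))
  }
  node_labels <- as.character(node_labels)
  if (length(node_labels) != ncol(values))
    stop("length(node_labels) must equal ncol(values)")
  if (anyDuplicated(node_labels)) stop("node labels must be unique")
  all01 <- all(values == 0 | values == 1)
  if (mode == "auto") mode <- if (all01) "binary" else "continuous"
  if (mode == "binary" && !all01)
    stop("binary mode requires every value to be 0 or 1")
  dimnames(values) <- list(NULL, node_labels)
  structure(list(values = values, mode = mode, node_labels = node_labels),
            class = "bca_data")
}

#' @export
print.bca_data <- function(x, ...) {
  cat(sprintf("<bca_data> %d samples x %d nodes, mode = %s\n",
              nrow(x$values), ncol(x$values), x$mode))
  invisible(x)
}

#' Number of samples / nodes in a data matrix
#' @param data a [data_matrix()] object.
#' @return integer count.
#' @export
n_samples <- function(data) {
  stopifnot(inherits(data, "bca_data"))
  nrow(data$values)
}

#' @rdname n_samples
#' @export
n_nodes_data <- function(data) {
  stopifnot(inherits(data, "bca_data"))
  ncol(data$values)
}

#' Select a subset of nodes (columns) from a data matrix
#'
#' @param data a [data_matrix()] object.
#' @param labels node labels to keep, in the requested order.
#' @return a `bca_data` object restricted to `labels`; the mode is preserved.
#' @export
select_nodes <- function(data, labels) {
  stopifnot(inherits(data, "bca_data"))
  labels <- as.character(labels)
  missing <- setdiff(labels, data$node_labels)
  if (length(missing))
    stop("unknown node label(s): ", paste(missing, collapse = ", "))
  data_matrix(data$values[, labels, drop = FALSE], mode = data$mode,
              node_labels = labels)
}
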