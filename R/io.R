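#' Read an activity matrix from CSV
#'
#' Expects a comma-separated file with a mandatory header row of node labels
#' and a numeric body (one sample per row). Mode is auto-detected (all values
#' 0/1 means binary) unless overridden. Ragged rows, non-numeric cells, and
#' duplicate labels raise errors that name the offending line.
#'
#' @param path file path.
#' @param mode `"auto"` (default), `"binary"`, or `"continuous"`.
#' @return a [data_matrix()].
#' @export
read_data_csv <- function(path, mode = c("auto", "binary", "continuous")) {
  mode <- match.arg(mode)
  nf <- count.fields(path, sep = ",")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row at line ", bad, " of ", path)
  }
  df <- read.csv(path, check.names = FALSE)
  labs <- names(df)
  if (anyDuplicated(labs))
    stop("duplicate node label(s) in header of ", path, ": ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      suppressWarnings(num <- as.numeric(as.character(df[[j]])))
      bad <- which(is.na(num) & !is.na(df[[j]]))[1L]
      stop("non-numeric value in column '", labs[j], "' at line ",
           bad + 1L, " of ", path)
    }
  }
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  data_matrix(m, mode = mode, node_labels = labs)
}

#' Write an activity matrix to CSV
#' @param data a [data_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_data_csv <- function(data, path) {
  stopifnot(inherits(data, "bca_data"))
  write.csv(as.data.frame(data$values), path, row.names = FALSE)
  invisible(path)
}

#' Write a microcircuit as a tab-separated edge list
#'
#' The first line is a node manifest (`#nodes` followed by every label,
#' tab-separated) so that isolated nodes survive a round trip; each following
#' line is one edge as two tab-separated labels in lexicographic order.
#'
#' @param g a [microcircuit()]; labels must not contain tabs or newlines.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  stopifnot(inherits(g, "microcircuit"))
  if (any(grepl("[\t\n]", g$node_labels)))
    stop("node labels must not contain tabs or newlines")
  el <- edge_list(g)
  lines <- c(paste(c("#nodes", g$node_labels), collapse = "\t"),
             if (nrow(el)) paste(el[, 1L], el[, 2L], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a microcircuit from a tab-separated edge list
#'
#' Inverse of [write_graph()]: the `#nodes` manifest line defines the node
#' set; each remaining non-empty line is one edge. Duplicate edge lines
#' collapse to a single edge; unknown labels raise an error.
#'
#' @param path file path.
#' @return a [microcircuit()].
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#nodes\t"))
    stop("missing '#nodes' manifest line in ", path)
  labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]][-1L]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) return(microcircuit(labels))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L))
    stop("malformed edge line ", which(nfield != 2L)[1L] + 1L, " in ", path)
  edges <- do.call(rbind, parts)
  microcircuit_from_edges(labels, edges)
}
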