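#' Write an ROI x time matrix as delimited text
#'
#' Tab-separated, one row per ROI: first column the ROI label, remaining
#' columns the timepoints (header `roi  t1 ... tT`). Values are written with
#' 17 significant digits so a write/read round trip is exact.
#'
#' @param ts ROI x time numeric matrix (row names used as labels).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(ts, path) {
  ts <- as.matrix(ts)
  labels <- rownames(ts)
  if (is.null(labels)) labels <- roi_labels_for(nrow(ts))
  header <- paste(c("roi", paste0("t", seq_len(ncol(ts)))), collapse = "\t")
  body <- vapply(seq_len(nrow(ts)), function(i)
    paste(c(labels[i], sprintf("%.17g", ts[i, ])), collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ROI x time matrix from delimited text
#'
#' Expects the format of [write_timeseries()]. Ragged rows, non-numeric
#' cells and duplicate ROI labels are rejected with the offending location.
#'
#' @param path Input file.
#' @return ROI x time numeric matrix with ROI labels as row names.
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("timeseries file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  labels <- character(length(lines) - 1)
  out <- matrix(NA_real_, length(lines) - 1, width - 1)
  for (i in seq_along(labels)) {
    f <- fields[[i + 1]]
    if (length(f) != width)
      stop("ragged row ", i + 1, " in ", path, ": expected ", width,
           " fields, found ", length(f))
    labels[i] <- f[1]
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(vals)) {
      col <- which(is.na(vals))[1]
      stop("non-numeric value at row ", i + 1, ", column ", col + 1,
           " ('", f[col + 1], "') in ", path)
    }
    out[i, ] <- vals
  }
  if (anyDuplicated(labels))
    stop("duplicate ROI label '", labels[anyDuplicated(labels)], "' in ", path)
  rownames(out) <- labels
  out
}

#' Convert an FC topology or line graph to an igraph object
#'
#' Topology edges carry `delta_mean` (mean task-minus-baseline change
#' across participants) and `baseline_mean` attributes; graph-level
#' attributes record alpha, the participation threshold and the counts.
#' Line graphs carry the line-node `baseline` attribute (when attached) and
#' the per-line-edge `shared_roi` label.
#'
#' @param x An `fc_topology` or `fc_line_graph`.
#' @return An undirected igraph object.
#' @export
as_igraph <- function(x) {
  if (inherits(x, "fc_topology")) {
    g <- igraph::make_empty_graph(n = length(x$roi_labels), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = x$roi_labels)
    if (nrow(x$edges) > 0) {
      g <- igraph::add_edges(g, t(x$edges))
      g <- igraph::set_edge_attr(g, "delta_mean", value = colMeans(x$target))
      g <- igraph::set_edge_attr(g, "baseline_mean",
                                 value = colMeans(x$baseline))
    }
    g <- igraph::set_graph_attr(g, "alpha", x$alpha)
    g <- igraph::set_graph_attr(g, "participation_threshold",
                                x$participation_threshold)
    g <- igraph::set_graph_attr(g, "n_participants",
                                length(x$participant_ids))
    g
  } else if (inherits(x, "fc_line_graph")) {
    g <- igraph::make_empty_graph(n = x$n_nodes, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = x$node_labels)
    if (!is.null(x$node_attr))
      g <- igraph::set_vertex_attr(g, "baseline", value = x$node_attr)
    if (nrow(x$line_edges) > 0) {
      g <- igraph::add_edges(g, t(x$line_edges))
      g <- igraph::set_edge_attr(g, "shared_roi",
                                 value = x$roi_labels[x$shared_roi])
    }
    g
  } else stop("cannot convert object of class ", class(x)[1], " to igraph")
}

#' Write a graph as GraphML / read it back
#'
#' @param x An `fc_topology`, `fc_line_graph` or igraph object.
#' @param path GraphML file path.
#' @return `write_graphml` invisibly returns `path`; `read_graphml` returns
#'   an igraph object with all attributes.
#' @export
write_graphml <- function(x, path) {
  g <- if (inherits(x, "igraph")) x else as_igraph(x)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write the participants x edges target table as delimited text
#'
#' @param topo An `fc_topology`.
#' @param path Output TSV path.
#' @param what `"target"` (task-minus-baseline change) or `"baseline"`.
#' @return Invisibly, `path`.
#' @export
write_edge_table <- function(topo, path, what = c("target", "baseline")) {
  what <- match.arg(what)
  tab <- data.frame(participant_id = topo$participant_ids,
                    topo[[what]], check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
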