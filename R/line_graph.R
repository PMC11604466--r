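#' Line-graph transform of an FC topology
#'
#' Builds the derived graph in which every retained functional correlation
#' (edge of the ROI graph) becomes a node, and two such nodes are adjacent
#' exactly when their originating edges share an ROI. The shared ROI is
#' recorded per line-edge so ROI-level attributes (e.g. activation series)
#' can later be attached to line-edges without recomputing incidence.
#'
#' @param g An `fc_topology`, or an m x 2 integer matrix of edges (i < j)
#'   accompanied by `n_rois`.
#' @param n_rois Number of ROIs when `g` is a plain edge matrix.
#' @return An `fc_line_graph` list: `n_nodes`, `node_labels` ("ROIi|ROIj"),
#'   `original_edges`, `line_edges` (L x 2 line-node index pairs, a < b),
#'   `shared_roi` (length L), `roi_labels`, and empty attribute slots
#'   `node_attr` / `edge_attr` (see [attach_line_attributes()]).
#' @export
#' @examples
#' tri <- matrix(c(1, 2, 1, 3, 2, 3), ncol = 2, byrow = TRUE)
#' lg <- line_transform(tri, n_rois = 3)
#' lg$n_nodes      # 3: one line-node per original edge
#' nrow(lg$line_edges)  # 3: L(K3) = K3
line_transform <- function(g, n_rois = NULL) {
  if (inherits(g, "fc_topology")) {
    edges <- g$edges
    n_rois <- length(g$roi_labels)
    roi_labels <- g$roi_labels
  } else {
    edges <- as.matrix(g)
    if (is.null(n_rois)) n_rois <- max(edges)
    roi_labels <- roi_labels_for(n_rois)
  }
  if (nrow(edges) == 0) stop("empty graph: line transform needs >= 1 edge")
  if (any(edges[, 1] >= edges[, 2])) stop("edges must satisfy i < j")
  if (anyDuplicated(paste(edges[, 1], edges[, 2])))
    stop("multi-edges are not allowed")
  m <- nrow(edges)
  le_a <- integer(0); le_b <- integer(0); shared <- integer(0)
  for (v in seq_len(n_rois)) {
    inc <- which(edges[, 1] == v | edges[, 2] == v)
    if (length(inc) >= 2) {
      prs <- utils::combn(inc, 2)
      le_a <- c(le_a, prs[1, ]); le_b <- c(le_b, prs[2, ])
      shared <- c(shared, rep(v, ncol(prs)))
    }
  }
  ord <- order(le_a, le_b)
  structure(list(
    n_nodes = m,
    node_labels = edge_labels(edges, roi_labels),
    original_edges = edges,
    line_edges = cbind(a = le_a[ord], b = le_b[ord]),
    shared_roi = shared[ord],
    roi_labels = roi_labels,
    node_attr = NULL,
    edge_attr = NULL
  ), class = "fc_line_graph")
}

#' Attach one participant's attributes to a line graph
#'
#' Line-node attributes are that participant's baseline FC values in original
#' edge order. When `include_edge_series` is TRUE, every line-edge carries
#' the shared ROI's baseline time series (the information the line GCN
#' consumes and the line GraphSAGE discards).
#'
#' @param L An `fc_line_graph` from [line_transform()].
#' @param topo The `fc_topology` the line graph was derived from.
#' @param participant_index Row index into the topology's participant tables.
#' @param cohort The cohort list (required when `include_edge_series` is
#'   TRUE, to look up ROI time series).
#' @param include_edge_series Attach per-line-edge ROI activation series?
#' @return The line graph with `node_attr` (numeric, length = line nodes)
#'   and, optionally, `edge_attr` (L x T matrix) filled in.
#' @export
attach_line_attributes <- function(L, topo, participant_index,
                                   cohort = NULL,
                                   include_edge_series = FALSE) {
  stopifnot(inherits(L, "fc_line_graph"), inherits(topo, "fc_topology"))
  if (participant_index < 1 || participant_index > nrow(topo$baseline))
    stop("participant_index out of range")
  L$node_attr <- as.numeric(topo$baseline[participant_index, ])
  if (include_edge_series) {
    if (is.null(cohort)) stop("cohort required to attach edge series")
    ts <- cohort[[participant_index]]$baseline_ts
    L$edge_attr <- ts[L$shared_roi, , drop = FALSE]
  } else {
    L$edge_attr <- NULL
  }
  L
}

#' @export
print.fc_line_graph <- function(x, ...) {
  cat("Line graph:", x$n_nodes, "line-nodes (original edges),",
      nrow(x$line_edges), "line-edges (shared-ROI adjacencies)\n")
  invisible(x)
}
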