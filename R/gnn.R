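#' Specify one of the four GNN architectures
#'
#' The four models are the crossing of two message-passing families (GCN,
#' GraphSAGE) with two graph representations: `traditional` (ROIs as nodes,
#' functional correlations as edges, per-timepoint baseline activity as node
#' features, and for the GCN the baseline correlation as edge weight) and
#' `line` (each functional correlation is a node carrying its baseline value;
#' the line GCN additionally receives the shared ROI's activation series on
#' every line-edge through a learned sigmoid gate, while the line GraphSAGE
#' discards it because the aggregator admits no edge attributes).
#'
#' Traditional models end in a two-layer perceptron mapping the two endpoint
#' embeddings to an edge prediction; line models map each line-node embedding
#' to a scalar. Every model ends in a Tanh so predictions lie in (-1, 1).
#'
#' @param family `"gcn"` or `"sage"`.
#' @param representation `"traditional"` or `"line"`.
#' @param n_conv_layers Number of convolutional layers (default 5).
#' @param hidden_width Neurons per layer (default 512).
#' @param leaky_slope Negative slope of the LeakyReLU between layers
#'   (default 0.05).
#' @param learning_rate Default Adam step size for this architecture:
#'   1e-3 for the line GCN (which otherwise trains far more slowly), 2e-6
#'   for the others. Overridable here or in [train_config()].
#' @return A `gnn_spec` list; `readout` is `"edge_mlp"` for traditional
#'   models and `"node_scalar"` for line models, and `uses_edge_series_gate`
#'   is TRUE only for the line GCN.
#' @export
model_spec <- function(family = c("gcn", "sage"),
                       representation = c("traditional", "line"),
                       n_conv_layers = 5L,
                       hidden_width = 512L,
                       leaky_slope = 0.05,
                       learning_rate = NULL) {
  family <- match.arg(family)
  representation <- match.arg(representation)
  n_conv_layers <- as.integer(n_conv_layers)
  hidden_width <- as.integer(hidden_width)
  if (n_conv_layers < 1L) stop("n_conv_layers must be >= 1")
  if (hidden_width < 1L) stop("hidden_width must be >= 1")
  is_line_gcn <- family == "gcn" && representation == "line"
  if (is.null(learning_rate))
    learning_rate <- if (is_line_gcn) 1e-3 else 2e-6
  structure(list(
    family = family,
    representation = representation,
    n_conv_layers = n_conv_layers,
    hidden_width = hidden_width,
    leaky_slope = leaky_slope,
    readout = if (representation == "traditional") "edge_mlp" else "node_scalar",
    learning_rate = learning_rate,
    uses_edge_series_gate = is_line_gcn
  ), class = "gnn_spec")
}

model_label <- function(spec) {
  paste(if (spec$representation == "line") "line" else "traditional",
        if (spec$family == "gcn") "GCN" else "GraphSAGE")
}

#' @export
print.gnn_spec <- function(x, ...) {
  cat(model_label(x), ": ", x$n_conv_layers, " conv layers x ",
      x$hidden_width, " units, LeakyReLU slope ", x$leaky_slope,
      ", lr ", format(x$learning_rate), "\n", sep = "")
  invisible(x)
}

leaky_relu <- function(x, slope) {
  pos <- x > 0
  x * pos + slope * x * !pos
}

leaky_relu_grad <- function(x, slope) {
  pos <- x > 0
  pos + slope * !pos
}

# Symmetrically normalized propagation matrix with unit self-loops.
# Messages keep the signed edge weight; degrees use |weight| so the
# normalization is defined for negative correlations.
gcn_propagation <- function(n, edges, weights) {
  a <- diag(n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a[edges[k, 1], edges[k, 2]] <- weights[k]
      a[edges[k, 2], edges[k, 1]] <- weights[k]
    }
  }
  d <- rowSums(abs(a))
  a / sqrt(tcrossprod(d))
}

# Row-normalized (mean-aggregation) neighbor operator, no self-loops.
sage_mean_operator <- function(n, edges) {
  m <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      m[edges[k, 1], edges[k, 2]] <- 1
      m[edges[k, 2], edges[k, 1]] <- 1
    }
  }
  deg <- rowSums(m)
  deg[deg == 0] <- 1  # isolated node: zero neighbor term either way
  m / deg
}

#' One GCN convolution layer
#'
#' `H' = LeakyReLU(D^{-1/2} A D^{-1/2} H W + b)` where `A` is the weighted
#' adjacency plus unit self-loops and `D` its (absolute-weight) degree.
#'
#' @param h Node x feature matrix.
#' @param adj Symmetric weighted adjacency with zero diagonal; self-loops of
#'   weight one are added internally.
#' @param w,b Weight matrix (in x out) and bias vector (length out).
#' @param slope LeakyReLU negative slope.
#' @return Node x out feature matrix.
#' @export
gcn_layer <- function(h, adj, w, b, slope = 0.05) {
  h <- as.matrix(h)
  if (ncol(h) != nrow(w)) stop("feature/weight dimension mismatch")
  n <- nrow(h)
  adj <- as.matrix(adj)
  ew <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  s <- gcn_propagation(n, ew, adj[ew])
  leaky_relu(s %*% h %*% w + matrix(b, n, length(b), byrow = TRUE), slope)
}

#' One GraphSAGE convolution layer (mean aggregator)
#'
#' `H'_v = LeakyReLU(W_self h_v + W_neigh mean_{u in N(v)} h_u + b)`; the
#' neighbor mean is unweighted and an isolated node contributes a zero
#' neighbor term.
#'
#' @param h Node x feature matrix.
#' @param adj Adjacency pattern (nonzero = neighbor); weights are ignored.
#' @param w_self,w_neigh In x out weight matrices; `b` bias vector.
#' @param slope LeakyReLU negative slope.
#' @return Node x out feature matrix.
#' @export
sage_layer <- function(h, adj, w_self, w_neigh, b, slope = 0.05) {
  h <- as.matrix(h)
  if (ncol(h) != nrow(w_self) || ncol(h) != nrow(w_neigh))
    stop("feature/weight dimension mismatch")
  n <- nrow(h)
  adj <- as.matrix(adj)
  ew <- which(upper.tri(adj) & adj != 0, arr.ind = TRUE)
  m <- sage_mean_operator(n, ew)
  leaky_relu(h %*% w_self + (m %*% h) %*% w_neigh +
               matrix(b, n, length(b), byrow = TRUE), slope)
}

#' Edge readout perceptron
#'
#' Two-layer perceptron converting the two endpoint embeddings of an edge to
#' a prediction in (-1, 1): `tanh(w2 . LeakyReLU(W1 (h_u + h_v) + b1) + b2)`.
#' Summing the endpoints makes the readout symmetric in (u, v), as required
#' for undirected edges.
#'
#' @param h_u,h_v Endpoint embedding vectors (equal length).
#' @param params List with `W1` (h x h), `b1`, `w2` (length h), `b2`.
#' @param slope LeakyReLU negative slope.
#' @return Scalar prediction strictly inside (-1, 1).
#' @export
edge_readout <- function(h_u, h_v, params, slope = 0.05) {
  if (length(h_u) != length(h_v)) stop("embedding width mismatch")
  q <- h_u + h_v
  a <- leaky_relu(drop(q %*% params$W1) + params$b1, slope)
  tanh(sum(params$w2 * a) + params$b2)
}

#' Sigmoid gate converting an ROI activation series to a line-edge weight
#'
#' The line GCN carries per-timepoint ROI activation on its line-edges; the
#' symmetrically normalized propagation rule admits only scalar edge weights,
#' so the series enters as `sigmoid(w . series + b)`, a learned positive
#' weight in (0, 1).
#'
#' @param series Numeric activation series of the shared ROI.
#' @param w Learned projection (same length as `series`).
#' @param b Scalar bias.
#' @return Gate value strictly in (0, 1).
#' @export
line_gcn_edge_gate <- function(series, w, b = 0) {
  if (length(series) != length(w)) stop("gate/series length mismatch")
  stats::plogis(sum(w * series) + b)
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize parameters for a model specification
#'
#' Uniform Glorot (fan-based) initialization, deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param in_dim Input feature width (timepoints for traditional models, 1
#'   for line models).
#' @param series_len Length of the gate input series (line GCN only).
#' @param seed Integer seed.
#' @return A `gnn_params` nested list (`conv` layers, `readout`, optional
#'   `gate`), shapes consistent with `spec`.
#' @export
init_gnn_params <- function(spec, in_dim, series_len = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  h <- spec$hidden_width
  dims <- c(in_dim, rep(h, spec$n_conv_layers))
  conv <- lapply(seq_len(spec$n_conv_layers), function(l) {
    if (spec$family == "gcn") {
      list(W = glorot(dims[l], dims[l + 1]), b = numeric(dims[l + 1]))
    } else {
      list(W_self = glorot(dims[l], dims[l + 1]),
           W_neigh = glorot(dims[l], dims[l + 1]),
           b = numeric(dims[l + 1]))
    }
  })
  readout <- if (spec$readout == "edge_mlp") {
    list(W1 = glorot(h, h), b1 = numeric(h), w2 = drop(glorot(h, 1)), b2 = 0)
  } else {
    list(w = drop(glorot(h, 1)), b = 0)
  }
  gate <- NULL
  if (spec$uses_edge_series_gate) {
    if (is.null(series_len)) stop("series_len required for the line GCN gate")
    gate <- list(w = numeric(series_len), b = 0)  # uniform gates at start
  }
  structure(list(conv = conv, readout = readout, gate = gate),
            class = "gnn_params")
}

zscore_rows <- function(ts) {
  mu <- rowMeans(ts)
  sdv <- apply(ts, 1, stats::sd)
  if (any(sdv == 0)) stop("zero-variance ROI series cannot be z-scored")
  (ts - mu) / sdv
}

#' Assemble one participant's model input
#'
#' Traditional models receive the z-scored baseline ROI x time matrix as node
#' features (and, for the GCN, the participant's baseline correlations as
#' edge weights). Line models receive the participant's baseline correlation
#' per line-node; the line GCN additionally receives the z-scored shared-ROI
#' baseline series per line-edge for its gate.
#'
#' @param spec A [model_spec()].
#' @param topo An `fc_topology`.
#' @param cohort The cohort list the topology was built from.
#' @param participant_index Row index of the participant.
#' @param lg Optional precomputed [line_transform()] of `topo`.
#' @return A `gnn_input` list understood by [gnn_forward()].
#' @export
build_model_input <- function(spec, topo, cohort, participant_index,
                              lg = NULL) {
  stopifnot(inherits(topo, "fc_topology"))
  if (spec$representation == "traditional") {
    structure(list(
      representation = "traditional",
      n_nodes = length(topo$roi_labels),
      edges = topo$edges,
      X = zscore_rows(cohort[[participant_index]]$baseline_ts),
      edge_w = as.numeric(topo$baseline[participant_index, ])
    ), class = "gnn_input")
  } else {
    if (is.null(lg)) lg <- line_transform(topo)
    series <- NULL
    if (spec$uses_edge_series_gate) {
      z <- zscore_rows(cohort[[participant_index]]$baseline_ts)
      series <- z[lg$shared_roi, , drop = FALSE]
    }
    structure(list(
      representation = "line",
      n_nodes = lg$n_nodes,
      edges = lg$line_edges,
      x = as.numeric(topo$baseline[participant_index, ]),
      shared_series = series
    ), class = "gnn_input")
  }
}

#' Forward pass of any of the four architectures (single participant)
#'
#' Reference (unbatched) implementation built from the exported primitives;
#' the training loop uses an algebraically identical vectorized path.
#'
#' @param spec A [model_spec()].
#' @param params Matching [init_gnn_params()] parameters.
#' @param input A `gnn_input` from [build_model_input()].
#' @return Numeric vector of per-edge predictions, all strictly in (-1, 1),
#'   in retained-edge order.
#' @export
gnn_forward <- function(spec, params, input) {
  if (input$representation != spec$representation)
    stop("input representation (", input$representation,
         ") does not match spec (", spec$representation, ")")
  n <- input$n_nodes
  slope <- spec$leaky_slope
  if (spec$representation == "traditional") {
    hmat <- input$X
    op <- if (spec$family == "gcn")
      gcn_propagation(n, input$edges, input$edge_w)
    else sage_mean_operator(n, input$edges)
  } else {
    hmat <- matrix(input$x, ncol = 1)
    if (spec$family == "gcn") {
      gates <- stats::plogis(drop(input$shared_series %*% params$gate$w) +
                               params$gate$b)
      op <- gcn_propagation(n, input$edges, gates)
    } else {
      op <- sage_mean_operator(n, input$edges)
    }
  }
  for (l in seq_len(spec$n_conv_layers)) {
    p <- params$conv[[l]]
    hmat <- if (spec$family == "gcn") {
      leaky_relu(op %*% hmat %*% p$W +
                   matrix(p$b, n, length(p$b), byrow = TRUE), slope)
    } else {
      leaky_relu(hmat %*% p$W_self + (op %*% hmat) %*% p$W_neigh +
                   matrix(p$b, n, length(p$b), byrow = TRUE), slope)
    }
  }
  if (spec$readout == "edge_mlp") {
    vapply(seq_len(nrow(input$edges)), function(k)
      edge_readout(hmat[input$edges[k, 1], ], hmat[input$edges[k, 2], ],
                   params$readout, slope), 0)
  } else {
    as.numeric(tanh(drop(hmat %*% params$readout$w) + params$readout$b))
  }
}
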