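# Shared fixtures and oracles, all generated in code.

# Tiny cohort with a valid (filter-free) topology for model-level tests.
tiny_cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_participants = 6, n_rois = 6,
                        n_timepoints_baseline = 20, n_timepoints_task = 20,
                        base_density = 0.6, effect_edges = 4,
                        effect_size = 0.4, participant_sd = 0.1, seed = 5)
      co <- generate_cohort(cfg)
      topo <- group_topology(co$participants, alpha = 2, participation = 0)
      keep <- seq_len(min(5, nrow(topo$edges)))
      topo$edges <- topo$edges[keep, , drop = FALSE]
      topo$baseline <- topo$baseline[, keep, drop = FALSE]
      topo$target <- topo$target[, keep, drop = FALSE]
      cache <<- list(cohort = co$participants, topo = topo, config = cfg)
    }
    cache
  }
})

# Hand-built two-edge path topology (ROIs a-b-c) with explicit baselines.
path_topology_fixture <- function(baseline = c(0.3, -0.2),
                                  target = c(0.1, 0.05)) {
  structure(list(
    roi_labels = c("A", "B", "C"),
    edges = rbind(c(1L, 2L), c(2L, 3L)),
    baseline = matrix(baseline, nrow = 1,
                      dimnames = list("S001", c("A|B", "B|C"))),
    target = matrix(target, nrow = 1,
                    dimnames = list("S001", c("A|B", "B|C"))),
    participant_ids = "S001",
    alpha = 0.05,
    participation_threshold = 0.85,
    provenance = data.frame()
  ), class = "fc_topology")
}

# Random simple graph as an i < j edge matrix.
random_edge_matrix <- function(n_nodes, n_edges) {
  pairs <- t(utils::combn(n_nodes, 2))
  pairs[sort(sample.int(nrow(pairs), n_edges)), , drop = FALSE]
}

# Independent line-graph oracle: pairwise intersection enumeration.
enumerate_line_edges <- function(edges) {
  m <- nrow(edges)
  cnt <- 0L
  if (m >= 2)
    for (a in 1:(m - 1)) for (b in (a + 1):m)
      if (length(intersect(edges[a, ], edges[b, ])) > 0) cnt <- cnt + 1L
  cnt
}

# Exact Wilcoxon oracle: enumerate all 2^n sign assignments.
enumerate_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, 0)
  min(1, 2 * min(mean(ws <= w_obs + 1e-12), mean(ws >= w_obs - 1e-12)))
}

# Flatten/unflatten parameter trees for finite-difference gradient checks.
flatten_params <- function(p) unlist(p, use.names = FALSE)
unflatten_params <- function(skeleton, v) {
  out <- utils::relist(v, skeleton = rapply(unclass(skeleton), identity,
                                            how = "replace"))
  class(out) <- "list"
  out
}

numeric_gradient <- function(spec, params, batch, eps = 1e-6) {
  v <- flatten_params(params)
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- v[i] + eps
    vm <- v; vm[i] <- v[i] - eps
    lp <- linefc:::gnn_batch_pass(spec, unflatten_params(params, vp), batch)$loss
    lm <- linefc:::gnn_batch_pass(spec, unflatten_params(params, vm), batch)$loss
    g[i] <- (lp - lm) / (2 * eps)
  }
  g
}
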