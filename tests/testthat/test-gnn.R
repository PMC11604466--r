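test_that("gcn layer matches the dense normalized-propagation formula", {
  # single node, no neighbors: self-loop of weight 1, degree 1
  h <- matrix(c(0.4, 1.2), 1, 2)
  out <- gcn_layer(h, matrix(0, 1, 1), diag(2), c(0, 0))
  expect_equal(out, h)

  # two identical nodes joined by a unit edge: symmetric output rows
  h2 <- matrix(rep(c(0.5, -0.3), each = 2), 2, 2)
  adj <- matrix(c(0, 1, 1, 0), 2, 2)
  o2 <- gcn_layer(h2, adj, diag(2), c(0, 0))
  expect_equal(o2[1, ], o2[2, ])

  # 3-node path, weights {0.5, 0.25}: independent dense evaluation
  set.seed(3)
  h3 <- matrix(rnorm(9), 3, 3)
  w <- matrix(rnorm(9), 3, 3)
  b <- rnorm(3)
  adj3 <- matrix(0, 3, 3)
  adj3[1, 2] <- adj3[2, 1] <- 0.5
  adj3[2, 3] <- adj3[3, 2] <- 0.25
  a_tilde <- adj3 + diag(3)
  d <- rowSums(abs(a_tilde))
  s <- diag(1 / sqrt(d)) %*% a_tilde %*% diag(1 / sqrt(d))
  z <- s %*% h3 %*% w + matrix(b, 3, 3, byrow = TRUE)
  ref <- ifelse(z > 0, z, 0.05 * z)
  expect_equal(gcn_layer(h3, adj3, w, b, slope = 0.05), ref,
               tolerance = 1e-6)

  expect_error(gcn_layer(h3, adj3, matrix(0, 2, 2), c(0, 0)), "mismatch")
})

test_that("sage layer matches a per-node aggregation loop", {
  # isolated node: empty neighbor mean contributes nothing
  h <- matrix(c(1.5, -2), 1, 2)
  ws <- matrix(rnorm(4), 2, 2); wn <- matrix(rnorm(4), 2, 2); b <- c(0.1, -0.2)
  z <- h %*% ws + b
  expect_equal(sage_layer(h, matrix(0, 1, 1), ws, wn, b, 0.05),
               ifelse(z > 0, z, 0.05 * z))

  # all neighbors share a feature vector: neighbor term is W_neigh f
  hc <- rbind(c(2, 0), c(1, 1), c(1, 1), c(1, 1))
  adj <- matrix(0, 4, 4); adj[1, 2:4] <- adj[2:4, 1] <- 1
  out <- sage_layer(hc, adj, ws, wn, b, 0.05)
  z1 <- hc[1, , drop = FALSE] %*% ws + c(1, 1) %*% wn + b
  expect_equal(out[1, ], drop(ifelse(z1 > 0, z1, 0.05 * z1)))

  # 4-node star with random features: brute-force per-node loop oracle
  set.seed(5)
  h4 <- matrix(rnorm(8), 4, 2)
  ref <- matrix(0, 4, 2)
  neigh <- list(2:4, 1L, 1L, 1L)
  for (v in 1:4) {
    nb <- colMeans(h4[neigh[[v]], , drop = FALSE])
    z <- drop(h4[v, ] %*% ws + nb %*% wn) + b
    ref[v, ] <- ifelse(z > 0, z, 0.05 * z)
  }
  expect_equal(sage_layer(h4, adj, ws, wn, b, 0.05), ref, tolerance = 1e-6)
})

test_that("edge readout is symmetric, bounded and matches dense arithmetic", {
  p0 <- list(W1 = matrix(0, 3, 3), b1 = numeric(3), w2 = numeric(3), b2 = 0)
  expect_equal(edge_readout(c(1, 2, 3), c(0, 0, 1), p0), 0)  # tanh(0)

  set.seed(11)
  pr <- list(W1 = matrix(rnorm(9), 3, 3), b1 = rnorm(3),
             w2 = rnorm(3), b2 = rnorm(1))
  hu <- rnorm(3); hv <- rnorm(3)
  expect_identical(edge_readout(hu, hv, pr), edge_readout(hv, hu, pr))
  q <- hu + hv
  z1 <- drop(q %*% pr$W1) + pr$b1
  a1 <- ifelse(z1 > 0, z1, 0.05 * z1)
  expect_equal(edge_readout(hu, hv, pr),
               tanh(sum(pr$w2 * a1) + pr$b2), tolerance = 1e-6)
  expect_lt(abs(edge_readout(hu * 3, hv * 3, pr)), 1)
  expect_lte(abs(edge_readout(hu * 1e4, hv * 1e4, pr)), 1)
  expect_error(edge_readout(c(1, 2), c(1, 2, 3), pr), "mismatch")
})

test_that("the line-GCN gate is a sigmoid of the projected series", {
  expect_equal(line_gcn_edge_gate(c(1, 2, 3), c(0, 0, 0)), 0.5)
  expect_equal(line_gcn_edge_gate(c(2, 1), c(1, -1)), stats::plogis(1),
               tolerance = 1e-6)
  expect_equal(round(line_gcn_edge_gate(c(2, 1), c(1, -1)), 4), 0.7311)
  set.seed(2)
  g <- line_gcn_edge_gate(rnorm(10) * 2, rnorm(10))
  expect_gt(g, 0); expect_lt(g, 1)
  expect_error(line_gcn_edge_gate(1:3, 1:2), "length mismatch")
})

test_that("scalar single-layer networks agree with hand arithmetic", {
  # 2-node graph, weight w, hidden width 1, one layer
  topo <- path_topology_fixture()
  topo$edges <- topo$edges[1, , drop = FALSE]     # single edge A-B
  topo$baseline <- topo$baseline[, 1, drop = FALSE]
  topo$target <- topo$target[, 1, drop = FALSE]
  topo$roi_labels <- c("A", "B")
  ts <- rbind(A = c(1, 2, 4), B = c(2, 1, 3))
  cohort <- list(structure(list(participant_id = "S001",
                                baseline_ts = ts, task_ts = ts),
                           class = "participant_record"))
  spec <- model_spec("gcn", "traditional", n_conv_layers = 1, hidden_width = 1)
  params <- init_gnn_params(spec, in_dim = 3, seed = 1)
  inp <- build_model_input(spec, topo, cohort, 1)
  got <- gnn_forward(spec, params, inp)

  # hand computation: rho = 0.3 edge weight, z-scored features
  x <- t(scale(t(ts)))
  a_t <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  d <- rowSums(abs(a_t))
  s <- a_t / sqrt(outer(d, d))
  z <- s %*% x %*% params$conv[[1]]$W + params$conv[[1]]$b
  h <- ifelse(z > 0, z, 0.05 * z)
  q <- h[1, ] + h[2, ]
  z1 <- q * params$readout$W1[1, 1] + params$readout$b1
  a1 <- ifelse(z1 > 0, z1, 0.05 * z1)
  expect_equal(got, tanh(params$readout$w2 * a1 + params$readout$b2),
               tolerance = 1e-10)
})

test_that("forward passes stay strictly inside the tanh range", {
  fx <- tiny_cohort_fixture()
  lg <- line_transform(fx$topo)
  t_len <- ncol(fx$cohort[[1]]$baseline_ts)
  for (fam in c("gcn", "sage")) for (rep_ in c("traditional", "line")) {
    spec <- model_spec(fam, rep_, n_conv_layers = 2, hidden_width = 4)
    in_dim <- if (rep_ == "traditional") t_len else 1L
    params <- init_gnn_params(spec, in_dim, series_len = t_len, seed = 2)
    inp <- build_model_input(spec, fx$topo, fx$cohort, 1, lg)
    preds <- gnn_forward(spec, params, inp)
    expect_length(preds, nrow(fx$topo$edges))
    expect_true(all(abs(preds) < 1))
  }
})

test_that("predictions are equivariant to ROI relabeling", {
  fx <- tiny_cohort_fixture()
  topo <- fx$topo
  cohort <- fx$cohort
  t_len <- ncol(cohort[[1]]$baseline_ts)
  n <- length(topo$roi_labels)
  set.seed(31)
  perm <- sample.int(n)
  # permuted topology: relabel ROI indices, re-sort edges, permute series
  pe <- t(apply(topo$edges, 1, function(e) sort(perm[e])))
  ord <- order(pe[, 1], pe[, 2])
  topo_p <- topo
  topo_p$edges <- pe[ord, , drop = FALSE]
  mode(topo_p$edges) <- "integer"
  topo_p$baseline <- topo$baseline[, ord, drop = FALSE]
  topo_p$target <- topo$target[, ord, drop = FALSE]
  cohort_p <- lapply(cohort, function(p) {
    inv <- order(perm)
    p$baseline_ts <- p$baseline_ts[inv, , drop = FALSE]
    p$task_ts <- p$task_ts[inv, , drop = FALSE]
    p
  })
  for (fam in c("gcn", "sage")) {
    spec <- model_spec(fam, "traditional", n_conv_layers = 2, hidden_width = 4)
    params <- init_gnn_params(spec, t_len, seed = 6)
    y1 <- gnn_forward(spec, params, build_model_input(spec, topo, cohort, 2))
    y2 <- gnn_forward(spec, params,
                      build_model_input(spec, topo_p, cohort_p, 2))
    expect_equal(y2, y1[ord], tolerance = 1e-10)
  }
})

test_that("line GraphSAGE never sees the ROI time series", {
  fx <- tiny_cohort_fixture()
  lg <- line_transform(fx$topo)
  t_len <- ncol(fx$cohort[[1]]$baseline_ts)
  spec <- model_spec("sage", "line", n_conv_layers = 3, hidden_width = 4)
  params <- init_gnn_params(spec, 1, series_len = t_len, seed = 4)
  y1 <- gnn_forward(spec, params, build_model_input(spec, fx$topo, fx$cohort, 1, lg))
  perturbed <- fx$cohort
  perturbed[[1]]$baseline_ts <- perturbed[[1]]$baseline_ts * 3 + 7
  y2 <- gnn_forward(spec, params,
                    build_model_input(spec, fx$topo, perturbed, 1, lg))
  expect_identical(y1, y2)

  # the line GCN, by contrast, is sensitive through its edge gate
  spec_g <- model_spec("gcn", "line", n_conv_layers = 3, hidden_width = 4)
  params_g <- init_gnn_params(spec_g, 1, series_len = t_len, seed = 4)
  params_g$gate$w <- rnorm(t_len) * 0.3
  yg1 <- gnn_forward(spec_g, params_g,
                     build_model_input(spec_g, fx$topo, fx$cohort, 1, lg))
  pert2 <- fx$cohort
  pert2[[1]]$baseline_ts[1, ] <- rev(pert2[[1]]$baseline_ts[1, ])
  yg2 <- gnn_forward(spec_g, params_g,
                     build_model_input(spec_g, fx$topo, pert2, 1, lg))
  expect_false(identical(yg1, yg2))
})

test_that("analytic gradients match finite differences for all models", {
  fx <- tiny_cohort_fixture()
  lg <- line_transform(fx$topo)
  t_len <- ncol(fx$cohort[[1]]$baseline_ts)
  for (fam in c("gcn", "sage")) for (rep_ in c("traditional", "line")) {
    spec <- model_spec(fam, rep_, n_conv_layers = 2, hidden_width = 3)
    in_dim <- if (rep_ == "traditional") t_len else 1L
    params <- unclass(init_gnn_params(spec, in_dim, series_len = t_len,
                                      seed = 11))
    batch <- linefc:::prepare_batch(spec, fx$topo, fx$cohort, 1:4, lg)
    pass <- linefc:::gnn_batch_pass(spec, params, batch, want_grads = TRUE)
    ga <- flatten_params(pass$grads)
    gn <- numeric_gradient(spec, params, batch)
    expect_lt(max(abs(ga - gn)) / max(1e-8, max(abs(gn))), 1e-6)
    expect_true(all(is.finite(ga)))
  }
})

test_that("the vectorized training path equals the reference forward pass", {
  fx <- tiny_cohort_fixture()
  lg <- line_transform(fx$topo)
  t_len <- ncol(fx$cohort[[1]]$baseline_ts)
  for (fam in c("gcn", "sage")) for (rep_ in c("traditional", "line")) {
    spec <- model_spec(fam, rep_, n_conv_layers = 2, hidden_width = 3)
    in_dim <- if (rep_ == "traditional") t_len else 1L
    params <- init_gnn_params(spec, in_dim, series_len = t_len, seed = 3)
    batch <- linefc:::prepare_batch(spec, fx$topo, fx$cohort, 1:3, lg)
    preds <- matrix(linefc:::gnn_batch_pass(spec, params, batch)$preds,
                    nrow = 3, byrow = TRUE)
    for (p in 1:3) {
      ref <- gnn_forward(spec, params,
                         build_model_input(spec, fx$topo, fx$cohort, p, lg))
      expect_equal(preds[p, ], ref, tolerance = 1e-12)
    }
  }
})
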