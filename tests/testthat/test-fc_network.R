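test_that("spearman matrix reproduces hand-ranked values", {
  m <- spearman_matrix(rbind(x = c(1, 2, 3), y = c(10, 20, 30)))
  expect_equal(m["x", "y"], 1)
  m2 <- spearman_matrix(rbind(x = c(1, 2, 3), y = c(30, 20, 10)))
  expect_equal(m2["x", "y"], -1)

  # no-ties formula 1 - 6 sum(d^2) / (n (n^2 - 1)) with hand ranks
  x <- c(1, 2, 3, 4, 5); y <- c(3, 1, 2, 5, 4)
  d <- rank(x) - rank(y)
  expect_equal(spearman_matrix(rbind(x, y))["x", "y"],
               1 - 6 * sum(d^2) / (5 * 24))
  expect_equal(spearman_matrix(rbind(x, y))["x", "y"], 0.6)

  # ties: average ranks, oracle = Pearson on manually averaged ranks
  xt <- c(1, 1, 2, 3, 5); yt <- c(2, 4, 4, 7, 9)
  expect_equal(spearman_matrix(rbind(a = xt, b = yt))["a", "b"],
               stats::cor(rank(xt), rank(yt)))
})

test_that("degenerate inputs are rejected with the offending ROI", {
  expect_error(spearman_matrix(rbind(a = c(1, 1, 1), b = c(1, 2, 3))), "a")
  expect_error(spearman_matrix(matrix(1:4, 2, 2)), "3 timepoints")
})

test_that("subject-level edge p-values match the t approximation", {
  expect_equal(subject_edge_pvalue(0, 20), 1)
  expect_equal(subject_edge_pvalue(1, 20), 0)
  expect_equal(subject_edge_pvalue(-1, 50), 0)
  expect_lt(subject_edge_pvalue(0.999999, 20), 1e-10)
  # independent oracle: incomplete-beta identity for the correlation test
  for (r in c(0.3, 0.6, -0.45)) {
    for (n in c(10, 20, 300)) {
      expect_equal(subject_edge_pvalue(r, n),
                   stats::pbeta(1 - r^2, (n - 2) / 2, 0.5),
                   tolerance = 1e-6)
    }
  }
  expect_error(subject_edge_pvalue(0.5, 3), "n must be")
})

test_that("identical conditions produce an empty topology", {
  set.seed(1)
  cohort <- lapply(1:4, function(i) {
    ts <- matrix(rnorm(4 * 30), 4, 30,
                 dimnames = list(sprintf("R%d", 1:4), NULL))
    structure(list(participant_id = sprintf("S%03d", i),
                   baseline_ts = ts, task_ts = ts),
              class = "participant_record")
  })
  topo <- group_topology(cohort)
  expect_identical(nrow(topo$edges), 0L)
  expect_error(group_topology(cohort[1]), "insufficient")
})

test_that("a strongly planted edge is retained with full participation", {
  cfg <- sim_config(n_participants = 30, n_rois = 5, base_density = 0.3,
                    effect_edges = 1, effect_rule = "constant_delta",
                    effect_size = 0.5, participant_sd = 0.02,
                    seed = 7)
  co <- generate_cohort(cfg)
  topo <- group_topology(co$participants)
  ee <- co$truth$effect_edge_list
  hit <- which(topo$edges[, 1] == ee[1, 1] & topo$edges[, 2] == ee[1, 2])
  expect_length(hit, 1)
  prov <- topo$provenance
  row <- prov[prov$i == ee[1, 1] & prov$j == ee[1, 2], ]
  expect_equal(row$participation, 1.0)

  # brute-force paired-t oracle on the planted pair
  zb <- sapply(co$participants, function(p)
    atanh(spearman_matrix(p$baseline_ts)[ee[1, 1], ee[1, 2]]))
  zt <- sapply(co$participants, function(p)
    atanh(spearman_matrix(p$task_ts)[ee[1, 1], ee[1, 2]]))
  tt <- stats::t.test(zt, zb, paired = TRUE)
  expect_equal(row$p_raw, tt$p.value, tolerance = 1e-10)
  expect_equal(row$p_corrected, min(1, tt$p.value * choose(5, 2)),
               tolerance = 1e-10)
})

test_that("participation filtering uses the threshold inclusively", {
  # craft a cohort where exactly 4 of 5 subjects carry the edge in the task
  set.seed(42)
  make_p <- function(i, coupled) {
    base <- matrix(rnorm(3 * 80), 3, 80)
    task <- matrix(rnorm(3 * 80), 3, 80)
    if (coupled) task[2, ] <- task[1, ] * 0.95 + rnorm(80, sd = 0.2)
    rownames(base) <- rownames(task) <- c("R1", "R2", "R3")
    structure(list(participant_id = sprintf("S%03d", i),
                   baseline_ts = base, task_ts = task),
              class = "participant_record")
  }
  cohort <- lapply(1:5, function(i) make_p(i, coupled = i <= 4))
  prov <- group_topology(cohort, alpha = 2, participation = 0)$provenance
  row <- prov[prov$i == 1 & prov$j == 2, ]
  # oracle: recompute participation from subject-level p-values
  part_oracle <- mean(sapply(cohort, function(p)
    subject_edge_pvalue(spearman_matrix(p$task_ts)[1, 2], 80) < 0.05))
  expect_equal(row$participation, part_oracle)
  expect_equal(row$participation, 0.8)
  # 0.8 participation fails a 0.85 threshold but passes 0.8 exactly
  t85 <- group_topology(cohort, alpha = 2, participation = 0.85)
  expect_false(any(t85$edges[, 1] == 1 & t85$edges[, 2] == 2))
  t80 <- group_topology(cohort, alpha = 2, participation = 0.8)
  expect_true(any(t80$edges[, 1] == 1 & t80$edges[, 2] == 2))
})

test_that("filters are monotone and rank-based", {
  cfg <- sim_config(n_participants = 10, n_rois = 5, base_density = 0.5,
                    effect_edges = 2, effect_size = 0.4,
                    n_timepoints_baseline = 60, n_timepoints_task = 60,
                    seed = 21)
  co <- generate_cohort(cfg)
  key <- function(t) paste(t$edges[, 1], t$edges[, 2])
  loose <- group_topology(co$participants, alpha = 0.2, participation = 0.5)
  tight_part <- group_topology(co$participants, alpha = 0.2, participation = 0.9)
  tight_alpha <- group_topology(co$participants, alpha = 0.01, participation = 0.5)
  expect_true(all(key(tight_part) %in% key(loose)))
  expect_true(all(key(tight_alpha) %in% key(loose)))

  # monotone transform of every series leaves the edge set unchanged
  warped <- lapply(co$participants, function(p) {
    p$baseline_ts <- exp(p$baseline_ts)
    p$task_ts <- exp(p$task_ts)
    p
  })
  expect_identical(key(group_topology(warped, 0.2, 0.5)), key(loose))

  # Bonferroni correction equals naive multiplication, capped at one
  prov <- loose$provenance
  expect_equal(prov$p_corrected, pmin(1, prov$p_raw * choose(5, 2)))
})

test_that("targets are the clipped task-minus-baseline rank correlations", {
  fx <- tiny_cohort_fixture()
  topo <- fx$topo
  p1 <- fx$cohort[[1]]
  sb <- spearman_matrix(p1$baseline_ts)
  st <- spearman_matrix(p1$task_ts)
  e1 <- topo$edges[1, ]
  expect_equal(unname(topo$baseline[1, 1]), sb[e1[1], e1[2]])
  expect_equal(unname(topo$target[1, 1]),
               min(0.999, max(-0.999, st[e1[1], e1[2]] - sb[e1[1], e1[2]])))
  expect_true(all(abs(topo$target) < 2))
})
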