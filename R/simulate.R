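#' Configure a synthetic paired-condition fMRI cohort
#'
#' Defines the population from which [generate_cohort()] draws: a set of ROIs
#' with a sparse baseline correlation structure, a subset of ROI pairs whose
#' correlation shifts between the baseline (control) and task conditions, and
#' per-participant heterogeneity. The simulator emulates *already
#' preprocessed* per-ROI BOLD time series for a block-design experiment in
#' which each subject contributes one baseline and one task series.
#'
#' Two planted-effect rules are available. With `"constant_delta"` every
#' effect edge shifts by `effect_size`; with `"linear_in_baseline"` the shift
#' on an effect edge is `effect_size` times that participant's baseline
#' correlation, so the task-induced change is an exact affine function of the
#' baseline value and is therefore predictable from baseline data.
#'
#' @param n_participants Number of subjects in the cohort.
#' @param n_rois Number of regions of interest (>= 3).
#' @param n_timepoints_baseline,n_timepoints_task Series lengths (>= 10).
#' @param base_density Fraction of ROI pairs given a nonzero baseline
#'   correlation (drawn uniformly in \[0.25, 0.65\]).
#' @param effect_edges Number of baseline edges with a planted task shift.
#' @param effect_rule `"constant_delta"` or `"linear_in_baseline"`.
#' @param effect_size Dimensionless correlation shift (constant rule) or
#'   slope on the baseline correlation (linear rule).
#' @param participant_sd Between-subject jitter applied to all off-diagonal
#'   correlations on the Fisher-z scale, so jittered values stay in (-1, 1).
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A `sim_config` list with the validated fields above.
#' @seealso [make_condition_correlations()], [generate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 6, n_rois = 5, seed = 1)
#' cohort <- generate_cohort(cfg)
#' dim(cohort$participants[[1]]$baseline_ts)
sim_config <- function(n_participants = 60L,
                       n_rois = 12L,
                       n_timepoints_baseline = 300L,
                       n_timepoints_task = 300L,
                       base_density = 0.4,
                       effect_edges = 8L,
                       effect_rule = c("linear_in_baseline", "constant_delta"),
                       effect_size = 0.3,
                       participant_sd = 0.3,
                       seed = 1L) {
  effect_rule <- match.arg(effect_rule)
  n_participants <- as.integer(n_participants)
  n_rois <- as.integer(n_rois)
  n_timepoints_baseline <- as.integer(n_timepoints_baseline)
  n_timepoints_task <- as.integer(n_timepoints_task)
  effect_edges <- as.integer(effect_edges)
  if (n_rois < 3L) stop("n_rois must be >= 3")
  if (n_timepoints_baseline < 10L || n_timepoints_task < 10L)
    stop("timepoint counts must be >= 10")
  if (base_density < 0 || base_density > 1) stop("base_density must be in [0, 1]")
  n_base <- round(base_density * choose(n_rois, 2))
  if (effect_edges > n_base)
    stop("effect_edges (", effect_edges, ") exceeds the number of nonzero ",
         "baseline edges (", n_base, ")")
  if (effect_edges < 0L) stop("effect_edges must be >= 0")
  if (participant_sd < 0) stop("participant_sd must be >= 0")
  if (!is.finite(effect_size)) stop("effect_size must be finite")
  structure(list(
    n_participants = n_participants,
    n_rois = n_rois,
    n_timepoints_baseline = n_timepoints_baseline,
    n_timepoints_task = n_timepoints_task,
    base_density = base_density,
    effect_edges = effect_edges,
    effect_rule = effect_rule,
    effect_size = effect_size,
    participant_sd = participant_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

roi_labels_for <- function(n) sprintf("ROI%02d", seq_len(n))

clip_corr <- function(x, lim = 0.999) pmin(pmax(x, -lim), lim)

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping followed by diagonal renormalization, iterated until
#' the smallest eigenvalue reaches `eig_floor` and the diagonal is exactly
#' one. The simulator uses a floor of 0.05 so every generated matrix is
#' well-conditioned, as empirical FC matrices estimated from hundreds of
#' timepoints are; callers wanting plain PSD repair can pass a floor of 0.
#'
#' @param m Symmetric real matrix.
#' @param max_iter Maximum repair iterations before giving up.
#' @param eig_floor Smallest admissible eigenvalue.
#' @return A symmetric positive (semi-)definite matrix with unit diagonal.
#' @export
nearest_correlation <- function(m, max_iter = 200L, eig_floor = 1e-8) {
  m <- (m + t(m)) / 2
  # overshoot the clip and tolerate 5% slack on the floor: alternating
  # projections converge only asymptotically when the constraint sets touch
  # tangentially, and the floor is a conditioning target, not a hard bound
  tol <- max(1e-9, 0.05 * eig_floor)
  clip <- eig_floor * 1.1
  for (it in seq_len(max_iter)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= eig_floor - tol &&
        max(abs(diag(m) - 1)) < 1e-12) {
      dimnames(m) <- NULL
      return(m)
    }
    lam <- pmax(e$values, clip)
    m <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    diag(m) <- 1
    m <- (m + t(m)) / 2
  }
  stop("simulation infeasible: could not repair correlation matrix in ",
       max_iter, " iterations")
}

# Eigenvalue floor used for every simulator-generated correlation matrix.
sim_eig_floor <- 0.05

# Nearest correlation matrix subject to fixed entries: alternating
# projections between the PSD cone (eigenvalue clipping) and the affine set
# holding the unit diagonal and the pinned entries. Pinning the planted
# effect edges keeps the task-minus-baseline delta exactly as specified;
# the unconstrained entries absorb the PSD repair instead.
nearest_correlation_fixed <- function(m, fix_idx, fix_val,
                                      max_iter = 3000L,
                                      eig_floor = sim_eig_floor) {
  m <- (m + t(m)) / 2
  impose <- function(x) {
    diag(x) <- 1
    if (nrow(fix_idx) > 0)
      for (k in seq_len(nrow(fix_idx))) {
        x[fix_idx[k, 1], fix_idx[k, 2]] <- fix_val[k]
        x[fix_idx[k, 2], fix_idx[k, 1]] <- fix_val[k]
      }
    x
  }
  m <- impose(m)
  tol <- max(1e-9, 0.05 * eig_floor)
  clip <- eig_floor * 1.1
  for (it in seq_len(max_iter)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= eig_floor - tol) {
      dimnames(m) <- NULL
      return(m)
    }
    psd <- e$vectors %*% (pmax(e$values, clip) * t(e$vectors))
    m <- impose((psd + t(psd)) / 2)
  }
  stop("simulation infeasible: could not satisfy planted correlations and ",
       "positive semi-definiteness in ", max_iter, " iterations")
}

# Task condition = baseline with the planted shift applied to the effect
# edges, exactly. Both the shifted effect edges and the untouched baseline
# edges are pinned during the PSD repair, so the two conditions differ on
# the planted edges and nowhere else among the structural edges; only the
# near-zero non-edge entries absorb the correction.
apply_effect <- function(corr, effect_edges, rule, size,
                         preserve_edges = NULL) {
  if (nrow(effect_edges) == 0) return(corr)
  # planted task correlations are capped at 0.95: values nearer one cannot
  # be completed to a valid correlation matrix alongside the other pinned
  # entries, and empirical FC rarely exceeds this
  vals <- vapply(seq_len(nrow(effect_edges)), function(k) {
    r <- corr[effect_edges[k, 1], effect_edges[k, 2]]
    delta <- if (rule == "constant_delta") size else size * r
    clip_corr(r + delta, 0.95)
  }, 0)
  pin_idx <- effect_edges
  pin_val <- vals
  if (!is.null(preserve_edges) && nrow(preserve_edges) > 0) {
    keep <- !(paste(preserve_edges[, 1], preserve_edges[, 2]) %in%
                paste(effect_edges[, 1], effect_edges[, 2]))
    pres <- preserve_edges[keep, , drop = FALSE]
    pin_idx <- rbind(pin_idx, pres)
    pin_val <- c(pin_val, corr[pres])
  }
  task <- corr
  for (k in seq_len(nrow(pin_idx))) {
    task[pin_idx[k, 1], pin_idx[k, 2]] <- pin_val[k]
    task[pin_idx[k, 2], pin_idx[k, 1]] <- pin_val[k]
  }
  nearest_correlation_fixed(task, pin_idx, pin_val)
}

#' Build the population correlation structure of both conditions
#'
#' Samples a sparse baseline correlation matrix (uniform weights on a random
#' `base_density` fraction of ROI pairs, then PSD repair), plants the
#' configured effects on `effect_edges` randomly chosen baseline edges, and
#' repairs the task matrix. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A `ground_truth` list: `baseline_corr`, `task_corr`, `delta`
#'   (elementwise difference), `effect_edge_list` (m x 2 matrix, i < j),
#'   `roi_labels`.
#' @export
make_condition_correlations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  r <- config$n_rois
  pairs <- t(utils::combn(r, 2))
  n_base <- round(config$base_density * nrow(pairs))
  set.seed(config$seed)
  base_idx <- if (n_base > 0) sort(sample.int(nrow(pairs), n_base)) else integer(0)
  corr <- diag(r)
  if (n_base > 0) {
    w <- stats::runif(n_base, 0.25, 0.65)
    for (k in seq_along(base_idx)) {
      i <- pairs[base_idx[k], 1]; j <- pairs[base_idx[k], 2]
      corr[i, j] <- corr[j, i] <- w[k]
    }
  }
  baseline <- nearest_correlation(corr, eig_floor = sim_eig_floor)
  eff_idx <- if (config$effect_edges > 0)
    sort(sample(base_idx, config$effect_edges)) else integer(0)
  effect_edge_list <- pairs[eff_idx, , drop = FALSE]
  base_edge_list <- pairs[base_idx, , drop = FALSE]
  task <- apply_effect(baseline, effect_edge_list, config$effect_rule,
                       config$effect_size, preserve_edges = base_edge_list)
  structure(list(
    baseline_corr = baseline,
    task_corr = task,
    delta = task - baseline,
    effect_edge_list = effect_edge_list,
    base_edge_list = base_edge_list,
    roi_labels = roi_labels_for(r)
  ), class = "ground_truth")
}

participant_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) * 1009 + as.numeric(index) * 9973
  as.integer(s %% 2147483646) + 1L
}

jitter_correlation <- function(corr, sd) {
  if (sd == 0) return(corr)
  r <- nrow(corr)
  z <- atanh(clip_corr(corr, 0.999999))
  noise <- matrix(stats::rnorm(r * r, sd = sd), r, r)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  diag(noise) <- 0
  out <- tanh(z + noise)
  diag(out) <- 1
  nearest_correlation(out, eig_floor = sim_eig_floor)
}

#' Simulate one participant's paired baseline/task time series
#'
#' Draws a participant-specific baseline correlation matrix (population
#' matrix plus Fisher-z Gaussian jitter, PSD-repaired), derives the task
#' matrix by applying the planted effect rule to the *participant's* baseline
#' values, and samples both series as zero-mean multivariate Gaussians.
#' Deterministic given `(config$seed, participant_index)` regardless of call
#' order.
#'
#' @param truth A `ground_truth` from [make_condition_correlations()].
#' @param config The [sim_config()] used to build `truth`.
#' @param participant_index Positive integer identifying the subject.
#' @return A `participant_record` list: `participant_id`, `baseline_ts` and
#'   `task_ts` (ROI x time matrices with ROI row names).
#' @export
simulate_participant <- function(truth, config, participant_index) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  participant_index <- as.integer(participant_index)
  if (participant_index < 1L) stop("participant_index must be >= 1")
  # A rare jitter draw admits no valid task matrix with the planted deltas
  # pinned; such draws are rejected and the trait resampled (deterministic:
  # the attempt counter offsets the seed, and attempt seeds of successive
  # participants cannot collide).
  base_p <- task_p <- NULL
  for (attempt in seq_len(60L)) {
    set.seed(participant_seed(config$seed, participant_index) + attempt - 1L)
    ok <- tryCatch({
      base_p <- jitter_correlation(truth$baseline_corr, config$participant_sd)
      task_p <- apply_effect(base_p, truth$effect_edge_list,
                             config$effect_rule, config$effect_size,
                             preserve_edges = truth$base_edge_list)
      TRUE
    }, error = function(e) FALSE)
    if (ok) break
  }
  if (is.null(task_p))
    stop("simulation infeasible: no valid participant correlation matrix ",
         "after 60 attempts (participant ", participant_index, ")")
  r <- config$n_rois
  baseline_ts <- t(MASS::mvrnorm(config$n_timepoints_baseline, mu = rep(0, r),
                                 Sigma = base_p))
  task_ts <- t(MASS::mvrnorm(config$n_timepoints_task, mu = rep(0, r),
                             Sigma = task_p))
  rownames(baseline_ts) <- rownames(task_ts) <- truth$roi_labels
  structure(list(
    participant_id = sprintf("S%03d", participant_index),
    baseline_ts = baseline_ts,
    task_ts = task_ts
  ), class = "participant_record")
}

#' Generate a full synthetic cohort
#'
#' @param config A [sim_config()].
#' @return List with `participants` (list of `participant_record`) and
#'   `truth` (the shared `ground_truth`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_participants < 1L) stop("empty cohort: n_participants must be >= 1")
  truth <- make_condition_correlations(config)
  participants <- lapply(seq_len(config$n_participants), function(i)
    simulate_participant(truth, config, i))
  list(participants = participants, truth = truth)
}

#' Write a cohort to delimited-text files
#'
#' One tab-separated file per participant per condition (ROIs as rows, first
#' column the ROI label, remaining columns the timepoints), the ground truth
#' as JSON, and a manifest listing every file.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- data.frame(participant_id = character(0), condition = character(0),
                      path = character(0), stringsAsFactors = FALSE)
  for (p in cohort$participants) {
    for (cond in c("baseline", "task")) {
      path <- file.path(dir, sprintf("%s_%s.tsv", p$participant_id, cond))
      write_timeseries(p[[paste0(cond, "_ts")]], path)
      files <- rbind(files, data.frame(participant_id = p$participant_id,
                                       condition = cond, path = basename(path),
                                       stringsAsFactors = FALSE))
    }
  }
  truth <- cohort$truth
  jsonlite::write_json(list(
    roi_labels = truth$roi_labels,
    baseline_corr = truth$baseline_corr,
    task_corr = truth$task_corr,
    delta = truth$delta,
    effect_edge_list = truth$effect_edge_list
  ), file.path(dir, "ground_truth.json"), digits = NA, matrix = "rowmajor")
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(files, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.tsv` and the per-participant
#'   files.
#' @return List with `participants`; `truth` is re-read from
#'   `ground_truth.json` when present (NULL otherwise).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  ids <- unique(manifest$participant_id)
  participants <- lapply(ids, function(id) {
    rows <- manifest[manifest$participant_id == id, ]
    get1 <- function(cond)
      read_timeseries(file.path(dir, rows$path[rows$condition == cond]))
    structure(list(participant_id = id,
                   baseline_ts = get1("baseline"),
                   task_ts = get1("task")),
              class = "participant_record")
  })
  truth <- NULL
  tj <- file.path(dir, "ground_truth.json")
  if (file.exists(tj)) {
    raw <- jsonlite::read_json(tj, simplifyVector = TRUE)
    truth <- structure(list(
      baseline_corr = raw$baseline_corr,
      task_corr = raw$task_corr,
      delta = raw$delta,
      effect_edge_list = matrix(as.integer(raw$effect_edge_list), ncol = 2),
      roi_labels = raw$roi_labels
    ), class = "ground_truth")
  }
  list(participants = participants, truth = truth)
}
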