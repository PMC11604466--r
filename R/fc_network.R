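#' Spearman rank-correlation matrix of an ROI x time matrix
#'
#' Static functional connectivity estimator: rank correlation (average ranks
#' for ties) between every pair of ROI time series.
#'
#' @param ts ROI x time numeric matrix (>= 3 timepoints); row names are used
#'   as ROI labels when present.
#' @return Symmetric matrix with unit diagonal and class
#'   `c("fc_matrix", "matrix")`.
#' @export
#' @examples
#' spearman_matrix(rbind(a = c(1, 2, 3), b = c(30, 20, 10)))
spearman_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("need at least 3 timepoints")
  const <- apply(ts, 1, function(x) length(unique(x)) < 2)
  if (any(const)) {
    bad <- rownames(ts)[const]
    if (is.null(bad)) bad <- which(const)
    stop("undefined correlation: constant time series for ROI ",
         paste(bad, collapse = ", "))
  }
  m <- stats::cor(t(ts), method = "spearman")
  m <- (m + t(m)) / 2
  diag(m) <- 1
  if (!is.null(rownames(ts))) dimnames(m) <- list(rownames(ts), rownames(ts))
  class(m) <- c("fc_matrix", "matrix")
  m
}

#' Two-sided p-value for a single subject-level correlation
#'
#' Uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with
#' `n - 2` degrees of freedom. This is the subject-level "edge presence"
#' test feeding the group participation filter.
#'
#' @param rho Correlation in \[-1, 1\].
#' @param n Number of timepoints (>= 4).
#' @return Two-sided p-value; 0 when `|rho| = 1`.
#' @export
subject_edge_pvalue <- function(rho, n) {
  if (n < 4) stop("n must be >= 4")
  if (any(abs(rho) > 1)) stop("|rho| must be <= 1")
  out <- numeric(length(rho))
  exact1 <- abs(rho) >= 1
  out[exact1] <- 0
  r <- rho[!exact1]
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  out[!exact1] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out
}

fisher_z <- function(rho) atanh(clip_corr(rho, 0.999999))

# Paired t that treats an all-zero difference vector as "no evidence"
# (p = 1) instead of erroring; used edgewise inside group_topology where
# identical conditions must yield an empty topology.
paired_t_safe <- function(d) {
  n <- length(d)
  s <- stats::sd(d)
  if (!is.finite(s) || s == 0) {
    if (all(d == 0)) return(c(statistic = 0, p = 1))
    return(c(statistic = sign(mean(d)) * Inf, p = 0))
  }
  tstat <- mean(d) / (s / sqrt(n))
  c(statistic = tstat, p = 2 * stats::pt(-abs(tstat), df = n - 1))
}

#' Build the group-level thresholded FC topology
#'
#' For every ROI pair the task-vs-baseline contrast is a two-sided paired t
#' test across participants on Fisher-z transformed Spearman correlations,
#' Bonferroni-corrected over all `choose(R, 2)` pairs. An edge additionally
#' needs subject-level support: the fraction of participants whose
#' task-condition correlation is individually significant (uncorrected 0.05,
#' [subject_edge_pvalue()]) must reach `participation`. No edge-strength
#' threshold is applied, so weak but consistent correlations are retained.
#'
#' @param cohort List of `participant_record`s sharing ROI labels.
#' @param alpha Significance level for the Bonferroni-corrected group test.
#' @param participation Minimum fraction of individually significant
#'   subjects (default 0.85).
#' @return An `fc_topology` list: `roi_labels`; `edges` (m x 2, i < j);
#'   `baseline` and `target` (participants x edges matrices of baseline
#'   Spearman rho and task-minus-baseline delta, the latter clipped to
#'   (-1, 1) for the Tanh prediction head); `participant_ids`; `alpha`;
#'   `participation_threshold`; and `provenance`, the per-pair test table.
#' @export
group_topology <- function(cohort, alpha = 0.05, participation = 0.85) {
  if (length(cohort) < 2) stop("insufficient cohort: need >= 2 participants")
  labels <- rownames(cohort[[1]]$baseline_ts)
  r <- nrow(cohort[[1]]$baseline_ts)
  if (is.null(labels)) labels <- roi_labels_for(r)
  n_task <- ncol(cohort[[1]]$task_ts)
  base_list <- lapply(cohort, function(p) spearman_matrix(p$baseline_ts))
  task_list <- lapply(cohort, function(p) spearman_matrix(p$task_ts))
  pairs <- t(utils::combn(r, 2))
  n_pairs <- nrow(pairs)
  n_sub <- length(cohort)
  base_mat <- sapply(seq_len(n_pairs), function(k)
    vapply(base_list, function(m) m[pairs[k, 1], pairs[k, 2]], 0))
  task_mat <- sapply(seq_len(n_pairs), function(k)
    vapply(task_list, function(m) m[pairs[k, 1], pairs[k, 2]], 0))
  base_mat <- matrix(base_mat, nrow = n_sub)
  task_mat <- matrix(task_mat, nrow = n_sub)

  stats_tab <- t(vapply(seq_len(n_pairs), function(k)
    paired_t_safe(fisher_z(task_mat[, k]) - fisher_z(base_mat[, k])),
    c(statistic = 0, p = 0)))
  p_corr <- pmin(1, stats_tab[, "p"] * n_pairs)
  part <- vapply(seq_len(n_pairs), function(k)
    mean(subject_edge_pvalue(task_mat[, k], n_task) < 0.05), 0)
  keep <- p_corr < alpha & part >= participation

  prov <- data.frame(i = pairs[, 1], j = pairs[, 2],
                     roi_i = labels[pairs[, 1]], roi_j = labels[pairs[, 2]],
                     t_statistic = stats_tab[, "statistic"],
                     p_raw = stats_tab[, "p"], p_corrected = p_corr,
                     participation = part, retained = keep,
                     stringsAsFactors = FALSE)
  edges <- pairs[keep, , drop = FALSE]
  baseline <- base_mat[, keep, drop = FALSE]
  target <- clip_corr(task_mat[, keep, drop = FALSE] -
                        base_mat[, keep, drop = FALSE])
  ids <- vapply(cohort, function(p) p$participant_id, "")
  rownames(baseline) <- rownames(target) <- ids
  colnames(baseline) <- colnames(target) <- edge_labels(edges, labels)
  structure(list(
    roi_labels = labels,
    edges = edges,
    baseline = baseline,
    target = target,
    participant_ids = ids,
    alpha = alpha,
    participation_threshold = participation,
    provenance = prov
  ), class = "fc_topology")
}

edge_labels <- function(edges, roi_labels) {
  if (nrow(edges) == 0) return(character(0))
  paste(roi_labels[edges[, 1]], roi_labels[edges[, 2]], sep = "|")
}

#' @export
print.fc_topology <- function(x, ...) {
  cat("Group FC topology:", length(x$roi_labels), "ROIs,",
      nrow(x$edges), "retained edges,", length(x$participant_ids),
      "participants\n")
  cat("  alpha =", x$alpha, "(Bonferroni over", nrow(x$provenance),
      "pairs), participation threshold =", x$participation_threshold, "\n")
  invisible(x)
}
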