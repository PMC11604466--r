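#' Default end-to-end pipeline configuration
#'
#' A small demonstration configuration (24 participants, 10 ROIs, 160
#' timepoints) that runs the full pipeline in well under ten minutes on one
#' CPU. All fields are plain lists so the configuration can round-trip
#' through JSON.
#'
#' @param seed Top-level seed; every stage derives its own seed from it.
#' @return Nested configuration list with `simulation`, `network`, `model`,
#'   `train`, `cv` and `seed` entries.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    simulation = list(n_participants = 24L, n_rois = 10L,
                      n_timepoints_baseline = 160L, n_timepoints_task = 160L,
                      base_density = 0.4, effect_edges = 6L,
                      effect_rule = "linear_in_baseline", effect_size = 0.3,
                      participant_sd = 0.3),
    # the demonstration scan is short, so the subject-level presence test
    # has less power than at full scan length; 0.80 keeps the filter
    # meaningful without emptying the demo topology
    network = list(alpha = 0.05, participation = 0.8),
    model = list(n_conv_layers = 5L, hidden_width = 16L),
    train = list(n_epochs = 30L, learning_rate = 0.003),
    cv = list(k = 5L, alpha = 0.05),
    seed = as.integer(seed)
  )
}

required_config_fields <- list(
  simulation = c("n_participants", "n_rois", "n_timepoints_baseline",
                 "n_timepoints_task", "base_density", "effect_edges",
                 "effect_rule", "effect_size", "participant_sd"),
  network = c("alpha", "participation"),
  model = c("n_conv_layers", "hidden_width"),
  train = c("n_epochs", "learning_rate"),
  cv = c("k", "alpha")
)

validate_pipeline_config <- function(config) {
  for (section in names(required_config_fields)) {
    if (is.null(config[[section]]))
      stop("invalid config: missing section '", section, "'")
    missing <- setdiff(required_config_fields[[section]],
                       names(config[[section]]))
    if (length(missing) > 0)
      stop("invalid config: section '", section, "' is missing field(s) ",
           paste(missing, collapse = ", "))
  }
  if (is.null(config$seed)) stop("invalid config: missing seed")
  invisible(config)
}

#' Serialize a cross-validation report to JSON
#'
#' @param cv An `fc_cv_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_cv_report <- function(cv, path) {
  payload <- list(
    model_names = cv$model_names,
    folds = cv$folds,
    fold_val_mse = cv$fold_val_mse,
    fold_benchmark_mse = cv$fold_benchmark_mse,
    pooled_val_mse = colMeans(cv$participant_val_err),
    pooled_benchmark_mse = mean(cv$participant_benchmark_err),
    participant_val_err = cv$participant_val_err,
    participant_benchmark_err = cv$participant_benchmark_err,
    comparisons = cv$comparisons,
    alpha = cv$alpha,
    topo_summary = cv$topo_summary
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", dataframe = "rows")
  invisible(path)
}

#' Write per-epoch training curves as tidy delimited text
#'
#' @param cv An `fc_cv_report`.
#' @param path Output TSV path (columns: model, fold, epoch, split, mse).
#' @return Invisibly, `path`.
#' @export
write_curves <- function(cv, path) {
  rows <- list()
  for (mname in cv$model_names) {
    for (split in c("train", "val")) {
      mat <- cv$curves[[mname]][[split]]
      rows[[length(rows) + 1]] <- data.frame(
        model = mname,
        fold = rep(seq_len(nrow(mat)), ncol(mat)),
        epoch = rep(seq_len(ncol(mat)), each = nrow(mat)),
        split = split,
        mse = as.numeric(mat),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$model, out$fold, out$epoch, out$split), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline: simulate, build network, transform, train, compare
#'
#' Executes every stage with seeds derived from the single top-level config
#' seed, writes all artifacts under `out_dir` and returns (and writes) a run
#' manifest listing them. Two runs with the same configuration produce
#' identical cross-validation reports.
#'
#' @param config Configuration list (see [default_pipeline_config()]) or the
#'   path of a JSON file containing one.
#' @param out_dir Output directory.
#' @return The manifest list (config hash, seeds, stage outputs, versions),
#'   invisibly. Side effects: cohort files, `topology.graphml`,
#'   `line_graph.graphml`, `targets.tsv`, `cv_report.json`, `curves.tsv`,
#'   `comparisons.tsv`, `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, digits = NA, auto_unbox = TRUE)
  config_hash <- unname(tools::md5sum(cfg_path))

  sim <- config$simulation
  scfg <- sim_config(n_participants = sim$n_participants,
                     n_rois = sim$n_rois,
                     n_timepoints_baseline = sim$n_timepoints_baseline,
                     n_timepoints_task = sim$n_timepoints_task,
                     base_density = sim$base_density,
                     effect_edges = sim$effect_edges,
                     effect_rule = sim$effect_rule,
                     effect_size = sim$effect_size,
                     participant_sd = sim$participant_sd,
                     seed = seed)
  cohort_dir <- file.path(out_dir, "cohort")
  cohort <- tryCatch(generate_cohort(scfg),
                     error = function(e) stop("stage 'simulate' failed: ",
                                              conditionMessage(e)))
  write_cohort(cohort, cohort_dir)

  topo <- tryCatch(
    group_topology(cohort$participants, alpha = config$network$alpha,
                   participation = config$network$participation),
    error = function(e) stop("stage 'build-network' failed: ",
                             conditionMessage(e)))
  write_graphml(topo, file.path(out_dir, "topology.graphml"))
  write_edge_table(topo, file.path(out_dir, "targets.tsv"))

  lg <- tryCatch(line_transform(topo),
                 error = function(e) stop("stage 'transform' failed: ",
                                          conditionMessage(e)))
  write_graphml(lg, file.path(out_dir, "line_graph.graphml"))

  specs <- default_model_specs(
    n_conv_layers = config$model$n_conv_layers,
    hidden_width = config$model$hidden_width,
    learning_rate = config$train$learning_rate)
  tcfg <- train_config(n_epochs = config$train$n_epochs,
                       seed = seed + 1L)
  cv <- tryCatch(
    cross_validate(cohort$participants, specs = specs, config = tcfg,
                   topo = topo, k = config$cv$k, seed = seed + 2L,
                   alpha = config$cv$alpha),
    error = function(e) stop("stage 'train' failed: ", conditionMessage(e)))
  write_cv_report(cv, file.path(out_dir, "cv_report.json"))
  write_curves(cv, file.path(out_dir, "curves.tsv"))
  utils::write.table(cv$comparisons, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = config_hash,
    seed = seed,
    stage_seeds = list(simulate = seed, train_init = seed + 1L,
                       folds = seed + 2L),
    software = list(package = "linefc",
                    version = as.character(utils::packageVersion("linefc")),
                    r_version = R.version.string),
    outputs = list(
      config = "config.json",
      cohort = file.path("cohort", "manifest.tsv"),
      topology = "topology.graphml",
      targets = "targets.tsv",
      line_graph = "line_graph.graphml",
      cv_report = "cv_report.json",
      curves = "curves.tsv",
      comparisons = "comparisons.tsv"
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  missing <- !file.exists(file.path(out_dir, unlist(manifest$outputs)))
  if (any(missing))
    stop("pipeline finished but outputs are missing: ",
         paste(unlist(manifest$outputs)[missing], collapse = ", "))
  invisible(manifest)
}
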