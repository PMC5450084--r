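#' Enumerate sensor combinations
#'
#' All non-empty subsets of the available sensors, canonically ordered by
#' subset size and sensor order (`I`, `H`, `P`, `LS`, `RS`). The full
#' five-sensor study yields 31 combinations.
#'
#' @param sensors Character vector of sensor codes.
#' @return List of character vectors, one per combination, named by the
#'   hyphenated combination label (e.g. `"I-H-P"`).
#' @export
enumerate_combinations <- function(sensors = c("I", "H", "P", "LS", "RS")) {
  if (!length(sensors)) stopf("at least one sensor is required")
  sensors <- match.arg(sensors, names(sensor_prefixes), several.ok = TRUE)
  combos <- list()
  for (size in seq_along(sensors)) {
    cc <- utils::combn(sensors, size, simplify = FALSE)
    combos <- c(combos, cc)
  }
  names(combos) <- vapply(combos, paste, character(1), collapse = "-")
  combos
}

#' Default pipeline configuration
#'
#' @param n_fallers,n_nonfallers Synthetic cohort sizes (ignored when a
#'   cohort manifest is supplied in the config).
#' @param n_iter RRS iterations.
#' @param seed Master seed for every random stage.
#' @param out_dir Output directory.
#' @return Nested configuration list; pass to [run_pipeline()], possibly
#'   after editing. The same structure can be stored as a YAML file.
#' @export
default_config <- function(n_fallers = 24, n_nonfallers = 76,
                           n_iter = 10000, seed = 1L,
                           out_dir = tempfile("gaitfall_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    cohort = list(n_fallers = n_fallers, n_nonfallers = n_nonfallers,
                  manifest = NULL),
    combinations = NULL,       # NULL = all 31
    selection = list(bins = 10, k_neighbors = 10, fcbf_delta = 0,
                     increment = 5, tolerance = 5,
                     on_full_dataset = TRUE),
    models = list(nn_nodes = 5:25, svm_degrees = 1:7,
                  nb_variants = c("linear", "quadratic")),
    evaluation = list(train_fraction = 0.75, n_iter = n_iter,
                      top_models = 20)
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_config(), config)
}

holdout_report <- function(results) {
  metrics_list <- lapply(results, `[[`, "metrics")
  names(metrics_list) <- vapply(results, `[[`, character(1), "id")
  ranked <- rank_models(metrics_list)
  meta <- do.call(rbind, lapply(results, function(r) {
    data.frame(model = r$id, method = r$method, feature_set = r$combo,
               n_features = length(r$subset), stringsAsFactors = FALSE)
  }))
  cm <- lapply(results, `[[`, "metrics")
  names(cm) <- meta$model
  ci <- do.call(rbind, lapply(cm, function(m)
    data.frame(ci_lower = m$ci_lower, ci_upper = m$ci_upper)))
  ci$model <- names(cm)
  out <- merge(meta, ranked, by = "model")
  out <- merge(out, ci, by = "model")
  out[order(out$sr, out$model), ]
}

#' Run the full faller-classification pipeline
#'
#' Executes the study stages in order: (1) simulate or load the cohort;
#' (2) extract the full multi-sensor feature table; (3) run CFS, FCBF and
#' Relief-F (with incremental subset sizing) per sensor combination on the
#' full dataset (selection is not repeated per holdout iteration);
#' (4) train the classifier grid on each selected subset using one 75:25
#' stratified holdout and compute the seven evaluation metrics with Wilson
#' CIs; (5) rank models by summed rank; (6) re-evaluate the top models with
#' repeated random sampling. Every stage's artifacts are written to the
#' output directory with the seeds used.
#'
#' Participants with a missing sensor are excluded from combinations that
#' include that sensor (and retained elsewhere). Feature selection on the
#' full dataset mirrors the study protocol; set
#' `selection$on_full_dataset = FALSE` to restrict selection to the
#' training rows of the model-development holdout instead.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file with the same structure.
#' @return Invisibly, a list with the feature table, subsets, holdout
#'   report, ranking, RRS summary and output paths.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  logf("pipeline start, seed %d", cfg$seed)

  # 1. cohort
  trials <- if (!is.null(cfg$cohort$manifest)) {
    read_cohort(cfg$cohort$manifest)
  } else {
    generate_cohort(cfg$cohort$n_fallers, cfg$cohort$n_nonfallers,
                    seed = cfg$seed)
  }
  logf("cohort: %d trials", length(trials))

  # 2. features
  table <- extract_features(trials)
  write_feature_table(table, file.path(cfg$out_dir, "feature_table.csv"))
  logf("feature table: %d x %d", nrow(table$features), ncol(table$features))

  combos <- cfg$combinations
  if (is.null(combos)) combos <- enumerate_combinations()
  if (is.character(combos)) combos <- strsplit(combos, "-")
  if (is.null(names(combos))) {
    names(combos) <- vapply(combos, paste, character(1), collapse = "-")
  }

  # 3. per-combination feature selection
  sel_split <- stratified_holdout(table$labels, cfg$evaluation$train_fraction,
                                  seed = cfg$seed)
  subsets <- list()
  for (cname in names(combos)) {
    sub <- subset_combination(table, combos[[cname]])
    sel_tab <- if (isTRUE(cfg$selection$on_full_dataset)) sub else {
      feature_table(sub$features[sel_split$train, , drop = FALSE],
                    sub$labels[sel_split$train],
                    sub$participant_id[sel_split$train])
    }
    excluded <- setdiff(table$participant_id, sub$participant_id)
    if (length(excluded)) {
      logf("combination %s: excluded %s (missing sensors)",
           cname, paste(excluded, collapse = ", "))
    }
    w <- relieff_rank(sel_tab, k_neighbors = cfg$selection$k_neighbors)
    subsets[[paste0(cname, "/ReliefF")]] <- c(
      relieff_subset_size(sel_tab, w,
                          increment = cfg$selection$increment,
                          tolerance = cfg$selection$tolerance,
                          seed = cfg$seed),
      list(combo = cname))
    subsets[[paste0(cname, "/CFS")]] <- c(
      cfs_select(sel_tab, bins = cfg$selection$bins), list(combo = cname))
    subsets[[paste0(cname, "/FCBF")]] <- c(
      fcbf_select(sel_tab, delta = cfg$selection$fcbf_delta,
                  bins = cfg$selection$bins), list(combo = cname))
  }
  jsonlite::write_json(
    lapply(subsets, function(s) s[c("method", "combo", "names")]),
    file.path(cfg$out_dir, "feature_subsets.json"), auto_unbox = TRUE)
  logf("feature selection: %d subsets", length(subsets))

  # 4. single stratified holdout over the model grid
  grid <- model_grid(cfg$models$nn_nodes, cfg$models$svm_degrees,
                     cfg$models$nb_variants, seed = cfg$seed)
  results <- list()
  for (sname in names(subsets)) {
    ss <- subsets[[sname]]
    sub <- subset_combination(table, combos[[ss$combo]])
    cols <- ss$names
    sub <- feature_table(sub$features[, cols, drop = FALSE], sub$labels,
                         sub$participant_id)
    split <- stratified_holdout(sub$labels, cfg$evaluation$train_fraction,
                                seed = cfg$seed)
    for (spec in grid) {
      id <- paste0(sname, "/", model_id(spec))
      m <- tryCatch({
        fit <- train(sub, spec, rows = split$train)
        pred <- predict(fit, sub$features[split$test, , drop = FALSE])
        confusion_metrics(confusion_counts(sub$labels[split$test], pred))
      }, error = function(e) {
        logf("model %s failed: %s", id, conditionMessage(e))
        NULL
      })
      if (!is.null(m)) {
        results[[id]] <- list(id = id, method = ss$method, combo = ss$combo,
                              subset = cols, spec = spec, metrics = m,
                              table = sub)
      }
    }
  }
  report <- holdout_report(results)
  write.csv(report, file.path(cfg$out_dir, "holdout_report.csv"),
            row.names = FALSE)
  logf("holdout: %d models evaluated", nrow(report))

  # 5-6. RRS on the top-ranked models
  top_ids <- head(report$model, cfg$evaluation$top_models)
  rrs_rows <- list()
  streams <- list()
  for (id in top_ids) {
    r <- results[[id]]
    out <- rrs(r$table, stats::setNames(list(r$spec), id),
               n_iter = cfg$evaluation$n_iter, seed = cfg$seed,
               train_fraction = cfg$evaluation$train_fraction)
    rrs_rows[[id]] <- out$summary[[id]]
    streams[[id]] <- out$accuracy_stream[[id]]
  }
  rrs_rank <- rank_models(lapply(rrs_rows, function(s) as.list(s$mean)))
  sd_tab <- do.call(rbind, lapply(rrs_rows, function(s)
    stats::setNames(as.data.frame(as.list(s$sd)),
                    paste0(metric_names, "_sd"))))
  sd_tab$model <- rownames(sd_tab)
  rrs_report <- merge(rrs_rank, sd_tab, by = "model")
  rrs_report <- rrs_report[order(rrs_report$sr, rrs_report$model), ]
  write.csv(rrs_report, file.path(cfg$out_dir, "rrs_report.csv"),
            row.names = FALSE)
  stream_df <- as.data.frame(streams, check.names = FALSE)
  write.csv(stream_df, file.path(cfg$out_dir, "rrs_accuracy_stream.csv"),
            row.names = FALSE)
  logf("rrs: %d models x %d iterations", length(top_ids),
       cfg$evaluation$n_iter)

  invisible(list(
    config = cfg, table = table, subsets = subsets,
    holdout_report = report, rrs_report = rrs_report,
    out_dir = cfg$out_dir
  ))
}
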