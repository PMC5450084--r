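#' Confusion counts with faller as the positive class
#'
#' @param truth,pred Label vectors (`faller`/`non_faller`).
#' @return Named list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as_label_factor(truth)
  pred <- as_label_factor(pred)
  pos <- FALLER_LEVELS[1]
  list(TP = sum(truth == pos & pred == pos),
       FP = sum(truth != pos & pred == pos),
       TN = sum(truth != pos & pred != pos),
       FN = sum(truth == pos & pred != pos))
}

safe_div <- function(num, den) if (den > 0) num / den else 0

#' The seven model evaluation metrics plus Wilson CI
#'
#' Computes accuracy, sensitivity, specificity, positive and negative
#' predictive value (as proportions), the F1 score (harmonic mean of
#' precision/PPV and sensitivity) and Matthews correlation coefficient from
#' binary confusion counts, with the Wilson 95% score interval on accuracy.
#' MCC is defined as 0 when any denominator factor is 0; F1 is 0 when
#' PPV + sensitivity is 0.
#'
#' @param counts A [confusion_counts()] result (or named list of TP, FP,
#'   TN, FN).
#' @param z Normal quantile for the accuracy CI (1.96 for 95%).
#' @return An object of class `eval_metrics`: accuracy, sensitivity,
#'   specificity, ppv, npv, f1, mcc, ci_lower, ci_upper, n.
#' @export
confusion_metrics <- function(counts, z = 1.96) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if (any(c(tp, fp, tn, fn) < 0)) stopf("counts must be non-negative")
  n <- tp + fp + tn + fn
  if (n == 0) stopf("all confusion counts are zero")
  acc <- (tp + tn) / n
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  f1 <- if (ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else 0
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  ci <- wilson_ci(acc, n, z)
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 ppv = ppv, npv = npv, f1 = f1, mcc = mcc,
                 ci_lower = ci[1], ci_upper = ci[2], n = n),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.1f%% [%.1f: %.1f], sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%, F1 %.3f, MCC %.3f (n=%d)\n",
    100 * x$accuracy, 100 * x$ci_lower, 100 * x$ci_upper,
    100 * x$sensitivity, 100 * x$specificity, 100 * x$ppv, 100 * x$npv,
    x$f1, x$mcc, x$n))
  invisible(x)
}

#' Wilson score interval for a binomial proportion
#'
#' Both roots of the Wilson interval,
#' (p + z^2/2N +/- z sqrt(p/N - p^2/N + z^2/4N^2)) / (1 + z^2/N),
#' an interval estimator appropriate for the small test sets of holdout
#' validation. For p = 1 the upper bound is exactly 1.
#'
#' @param p Observed proportion in `[0, 1]`.
#' @param n Number of trials (test-set size), >= 1.
#' @param z Normal quantile (default 1.96, 95% coverage).
#' @return Numeric vector `c(lower, upper)` with lower <= p <= upper.
#' @export
wilson_ci <- function(p, n, z = 1.96) {
  if (p < 0 || p > 1) stopf("'p' must lie in [0, 1]")
  if (n < 1) stopf("'n' must be >= 1")
  assert_scalar_pos(z, "z")
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p / n - p^2 / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c((centre - half) / denom, (centre + half) / denom)
}

#' Stratified train/test holdout
#'
#' Splits row indices class by class: the per-class training count is the
#' train fraction rounded to the nearest integer, so a 24/76 cohort at
#' 75:25 yields 18 fallers + 57 non-fallers for training and 6 + 19 for
#' testing. Reproducible from the seed.
#'
#' @param labels Label vector.
#' @param train_fraction Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_holdout <- function(labels, train_fraction = 0.75, seed = 1L) {
  labels <- as_label_factor(labels)
  if (any(table(labels) == 0)) stopf("both classes must be present")
  withr::with_seed(as.integer(seed), {
    train <- integer(0)
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_train <- round(train_fraction * length(idx))
      train <- c(train, idx[sample.int(length(idx), n_train)])
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv",
                  "f1", "mcc")

#' Summed-rank model ranking
#'
#' Each of the seven evaluation metrics is ranked from best (1) to worst
#' across models, ties receiving the mean of their rank positions; the
#' seven ranks are summed (SR) and models ordered by ascending SR, with
#' equal SR broken by model identifier. The lowest summed rank identifies
#' the overall best model.
#'
#' @param metrics_list Named list of [confusion_metrics()] results (or rows
#'   of metric values), one per model.
#' @return Data frame with one row per model: the seven metrics, per-metric
#'   ranks, and `sr`, ordered by ascending `sr`.
#' @export
rank_models <- function(metrics_list) {
  if (!length(metrics_list)) stopf("need at least one model")
  ids <- names(metrics_list)
  if (is.null(ids)) ids <- sprintf("model%02d", seq_along(metrics_list))
  vals <- do.call(rbind, lapply(metrics_list, function(m) {
    m <- unclass(m)
    if (!all(metric_names %in% names(m))) stopf("missing metric in input")
    unlist(m[metric_names])
  }))
  ranks <- apply(vals, 2, function(col) rank(-col, ties.method = "average"))
  ranks <- matrix(ranks, nrow = nrow(vals),
                  dimnames = list(ids, paste0("rank_", metric_names)))
  out <- data.frame(model = ids, vals, ranks, sr = rowSums(ranks),
                    row.names = NULL, check.names = FALSE)
  out[order(out$sr, out$model), , drop = FALSE]
}

#' Repeated-random-sampling stability analysis
#'
#' Trains each model specification on `n_iter` freshly randomized 75:25
#' stratified holdouts of the same feature table (feature subsets are fixed
#' beforehand; selection is never re-run per iteration) and averages the
#' seven evaluation metrics across iterations. Per-iteration seeds are
#' derived from the master seed by iteration index, so results are
#' reproducible and independent of execution order. Iterations whose
#' training fails are logged, counted and excluded from the averages.
#'
#' @param table A [feature_table()] (already restricted to the feature
#'   subset of interest).
#' @param specs Named list of [model_spec()]s (names default to
#'   [model_id()]).
#' @param n_iter Number of randomized holdouts (the study-scale value is
#'   10000).
#' @param seed Master seed.
#' @param train_fraction Training fraction per holdout.
#' @return An object of class `rrs_summary`: per model, `mean` and `sd` of
#'   each metric, the per-iteration accuracy stream (for histograms), the
#'   failure count, `n_iter` and `seed`.
#' @export
rrs <- function(table, specs, n_iter = 10000, seed = 1L,
                train_fraction = 0.75) {
  if (n_iter < 1) stopf("'n_iter' must be >= 1")
  if (inherits(specs, "model_spec")) specs <- list(specs)
  ids <- names(specs)
  if (is.null(ids)) ids <- vapply(specs, model_id, character(1))
  names(specs) <- make.unique(ids)

  streams <- lapply(specs, function(s)
    matrix(NA_real_, n_iter, length(metric_names),
           dimnames = list(NULL, metric_names)))
  failures <- stats::setNames(integer(length(specs)), names(specs))
  for (it in seq_len(n_iter)) {
    split <- stratified_holdout(table$labels, train_fraction,
                                seed = derive_seed(seed, it))
    for (si in seq_along(specs)) {
      m <- tryCatch({
        fit <- train(table, specs[[si]], rows = split$train)
        pred <- predict(fit, table$features[split$test, , drop = FALSE])
        cm <- confusion_metrics(confusion_counts(table$labels[split$test], pred))
        unlist(unclass(cm)[metric_names])
      }, error = function(e) {
        NULL
      })
      if (is.null(m)) failures[si] <- failures[si] + 1L else streams[[si]][it, ] <- m
    }
  }
  summ <- lapply(streams, function(s) {
    list(mean = colMeans(s, na.rm = TRUE),
         sd = apply(s, 2, sd, na.rm = TRUE))
  })
  structure(list(models = names(specs), summary = summ,
                 accuracy_stream = lapply(streams, function(s) s[, "accuracy"]),
                 failures = failures, n_iter = n_iter, seed = seed),
            class = "rrs_summary")
}

#' @export
print.rrs_summary <- function(x, ...) {
  cat(sprintf("<rrs_summary> %d iterations, seed %d\n", x$n_iter, x$seed))
  for (id in x$models) {
    s <- x$summary[[id]]
    cat(sprintf("  %-10s accuracy %.1f +/- %.1f%%, sens %.1f%%, spec %.1f%%\n",
                id, 100 * s$mean["accuracy"], 100 * s$sd["accuracy"],
                100 * s$mean["sensitivity"], 100 * s$mean["specificity"]))
  }
  invisible(x)
}

#' Summarise an RRS run as a table (mean and SD per metric)
#'
#' @param object An `rrs_summary`.
#' @param ... Unused.
#' @return Data frame with one row per model.
#' @export
summary.rrs_summary <- function(object, ...) {
  rows <- lapply(object$models, function(id) {
    s <- object$summary[[id]]
    vals <- c(rbind(s$mean, s$sd))
    names(vals) <- paste0(rep(metric_names, each = 2), c("_mean", "_sd"))
    c(model = id, vals)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  df[-1] <- lapply(df[-1], as.numeric)
  df
}
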