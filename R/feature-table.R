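#' Participants-by-features table with faller labels
#'
#' The central tabular container: one row per participant, named numeric
#' feature columns (namespaced by sensor: `insole.*`, `head.*`, `pelvis.*`,
#' `lshank.*`, `rshank.*`), a faller/non-faller label per row, and a
#' missing-sensor mask (`NA` columns for sensors a participant lacks).
#'
#' @param features Numeric data frame of features (unique column names).
#' @param labels Vector of `"faller"` / `"non_faller"` labels, one per row.
#' @param participant_id Optional character ids.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, labels, participant_id = NULL) {
  features <- as.data.frame(features)
  if (anyDuplicated(names(features))) stopf("feature names must be unique")
  labels <- as_label_factor(labels)
  if (length(labels) != nrow(features)) {
    stopf("one label per row is required")
  }
  if (is.null(participant_id)) {
    participant_id <- sprintf("P%03d", seq_len(nrow(features)))
  }
  structure(
    list(features = features, labels = labels,
         participant_id = as.character(participant_id)),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<feature_table> %d participants x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' Extract the full multi-sensor feature table from a cohort
#'
#' Runs the insole and per-site accelerometer extractors on every trial.
#' A missing accelerometer yields `NA` in that site's columns (the
#' missing-sensor mask); downstream sensor-combination subsetting excludes
#' such participants from combinations that include the missing sensor.
#'
#' @param trials List of `sensor_trial` objects.
#' @param sites Accelerometer sites to extract.
#' @param verbose Print progress.
#' @return A [feature_table()] with 30 insole + 29 x 4 accelerometer
#'   columns (146 features for the full five-sensor set).
#' @export
extract_features <- function(trials,
                             sites = c("head", "pelvis", "lshank", "rshank"),
                             verbose = FALSE) {
  rows <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    if (verbose) message("extracting ", tr$participant_id)
    ins <- insole_feature_vector(tr)
    acc <- lapply(sites, function(s) {
      if (s %in% names(tr$accel) && !is.null(tr$accel[[s]])) {
        accel_feature_vector(tr, s)
      } else {
        stats::setNames(rep(NA_real_, 29L), accel_feature_names(s))
      }
    })
    c(ins, unlist(acc))
  })
  features <- as.data.frame(do.call(rbind, rows))
  feature_table(
    features,
    labels = vapply(trials, `[[`, character(1), "label"),
    participant_id = vapply(trials, `[[`, character(1), "participant_id")
  )
}

sensor_prefixes <- c(I = "insole", H = "head", P = "pelvis",
                     LS = "lshank", RS = "rshank")

#' Column names belonging to a sensor combination
#'
#' @param combo Character vector of sensor codes among `I`, `H`, `P`, `LS`,
#'   `RS`.
#' @param table Optional `feature_table` whose columns are filtered;
#'   defaults to the canonical registry names.
#' @return Character vector of feature names.
#' @export
sensor_columns <- function(combo, table = NULL) {
  combo <- match.arg(combo, names(sensor_prefixes), several.ok = TRUE)
  cols <- unlist(lapply(sensor_prefixes[combo], function(p) {
    if (p == "insole") insole_feature_names() else accel_feature_names(p)
  }), use.names = FALSE)
  if (!is.null(table)) cols <- intersect(names(table$features), cols)
  cols
}

#' Restrict a feature table to one sensor combination
#'
#' Keeps the combination's columns and drops participants with missing data
#' for any sensor in the combination (the missing-sensor exclusion rule).
#'
#' @param table A `feature_table`.
#' @param combo Sensor codes, see [sensor_columns()].
#' @return A `feature_table` restricted to the combination.
#' @export
subset_combination <- function(table, combo) {
  cols <- sensor_columns(combo, table)
  feats <- table$features[, cols, drop = FALSE]
  keep <- stats::complete.cases(feats)
  feature_table(feats[keep, , drop = FALSE], table$labels[keep],
                table$participant_id[keep])
}

#' Write / read a feature table as CSV
#'
#' Columns `participant_id`, `label`, then all feature columns.
#'
#' @param table A `feature_table`.
#' @param path CSV path.
#' @return `write_feature_table` invisibly returns `path`.
#' @export
write_feature_table <- function(table, path) {
  df <- cbind(participant_id = table$participant_id,
              label = as.character(table$labels),
              table$features)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  feature_table(df[, setdiff(names(df), c("participant_id", "label")),
                   drop = FALSE],
                df$label, df$participant_id)
}
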