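#' Equal-frequency discretization
#'
#' Continuous features are discretized before entropy-based scoring.
#' Breakpoints are the empirical quantiles (duplicated quantiles merged), so
#' bins hold approximately equal numbers of observations.
#'
#' @param x Numeric vector (factors/characters pass through as-is).
#' @param bins Target number of bins.
#' @return Integer bin codes (or the original discrete values).
#' @export
discretize_ef <- function(x, bins = 10) {
  if (is.factor(x) || is.character(x) || is.logical(x)) return(as.integer(factor(x)))
  # variables with few distinct values are already discrete
  if (length(unique(x)) <= bins) return(as.integer(factor(x)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), names = FALSE))
  if (length(br) <= 2) return(rep.int(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

entropy_counts <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Symmetrical uncertainty between two variables
#'
#' SU(X, Y) = 2 I(X; Y) / (H(X) + H(Y)), a normalized mutual information in
#' `[0, 1]`: 1 for identical non-constant discrete variables, 0 for
#' independent ones. Continuous inputs are discretized by equal-frequency
#' binning first. A constant variable has zero entropy; SU is defined as 0
#' in that case.
#'
#' @param x,y Feature columns or the class label.
#' @param bins Discretization bins for continuous inputs.
#' @return SU value in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y, bins = 10) {
  su_disc(discretize_ef(x, bins), discretize_ef(y, bins))
}

# SU on already-discrete codes (no re-binning)
su_disc <- function(a, b) {
  n <- length(a)
  joint <- table(a, b) / n
  hx <- entropy_counts(rowSums(joint))
  hy <- entropy_counts(colSums(joint))
  if (hx + hy <= 0) return(0)
  mi <- hx + hy - entropy_counts(as.vector(joint))
  max(0, min(1, 2 * mi / (hx + hy)))
}

# Cached SU structures for one feature table: feature-class vector and a
# lazily filled feature-feature matrix.
su_cache <- function(table, bins = 10) {
  feats <- table$features
  disc <- lapply(feats, discretize_ef, bins = bins)
  y <- as.integer(table$labels)
  rcf <- vapply(disc, function(d) su_disc(d, y), numeric(1))
  p <- length(disc)
  rff <- matrix(NA_real_, p, p, dimnames = list(names(feats), names(feats)))
  diag(rff) <- 1
  env <- new.env(parent = emptyenv())
  env$rff <- rff
  get_rff <- function(i, j) {
    if (is.na(env$rff[i, j])) {
      v <- su_disc(disc[[i]], disc[[j]])
      env$rff[i, j] <- v
      env$rff[j, i] <- v
    }
    env$rff[i, j]
  }
  list(names = names(feats), rcf = rcf, get_rff = get_rff)
}

cfs_merit <- function(subset_idx, cache) {
  k <- length(subset_idx)
  if (k == 0) return(0)
  rcf <- mean(cache$rcf[subset_idx])
  if (k == 1) return(rcf)
  pairs <- utils::combn(subset_idx, 2)
  rff <- mean(apply(pairs, 2, function(p) cache$get_rff(p[1], p[2])))
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature selection (CFS)
#'
#' Selects the feature subset maximizing the heuristic merit
#' k r_cf / sqrt(k + k (k - 1) r_ff), where r_cf is the mean
#' feature-class symmetrical uncertainty of the subset and r_ff its mean
#' pairwise feature-feature SU: features correlated with the faller label
#' but mutually uncorrelated. The search is best-first forward selection,
#' stopping after `stale` consecutive expansions without improvement;
#' irrelevant and exactly redundant features are eliminated. Deterministic,
#' with lexicographic tie-breaks by feature name.
#'
#' @param table A [feature_table()].
#' @param bins SU discretization bins.
#' @param stale Non-improving expansions before the search stops.
#' @return An object of class `feature_subset`: list with `names`
#'   (selected features), `method = "CFS"` and `merit`.
#' @export
cfs_select <- function(table, bins = 10, stale = 5) {
  if (min(table(table$labels)) < 2) stopf("need >= 2 rows per class")
  cache <- su_cache(table, bins)
  p <- length(cache$names)
  if (all(cache$rcf == 0) &&
      all(vapply(table$features, function(f) length(unique(f)) == 1, logical(1)))) {
    stopf("all features are constant")
  }
  ord <- order(-cache$rcf, cache$names)   # expansion order: best rcf first
  best_set <- integer(0)
  best_merit <- 0
  open <- list(list(set = integer(0), merit = 0))
  n_stale <- 0
  expanded <- character(0)
  while (length(open) > 0 && n_stale < stale) {
    merits <- vapply(open, `[[`, numeric(1), "merit")
    pick <- which.max(merits)
    node <- open[[pick]]
    open[[pick]] <- NULL
    key <- paste(sort(node$set), collapse = ",")
    if (key %in% expanded) next
    expanded <- c(expanded, key)
    improved <- FALSE
    for (f in ord) {
      if (f %in% node$set) next
      child <- c(node$set, f)
      m <- cfs_merit(child, cache)
      open[[length(open) + 1]] <- list(set = child, merit = m)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_set <- child
        improved <- TRUE
      }
    }
    n_stale <- if (improved) 0 else n_stale + 1
  }
  if (!length(best_set)) {
    # degenerate: no subset beats merit 0; fall back to single best feature
    best_set <- ord[1]
    best_merit <- cfs_merit(best_set, cache)
  }
  structure(list(names = sort(cache$names[best_set]), method = "CFS",
                 merit = best_merit),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset> %s: %d feature(s)\n", x$method, length(x$names)))
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Fast correlation-based filter (FCBF)
#'
#' Ranks features by symmetrical uncertainty with the faller label, drops
#' those at or below `delta`, then removes each feature F for which an
#' earlier-ranked retained feature G is predominant, i.e.
#' SU(F, G) >= SU(F, label). Identifies predominant features and eliminates
#' redundant ones without all-pairs correlation analysis. Deterministic,
#' lexicographic tie-break.
#'
#' @param table A [feature_table()].
#' @param delta SU relevance threshold (default 0).
#' @param bins SU discretization bins.
#' @return A `feature_subset` with the retained features in rank order and
#'   their SU values.
#' @export
fcbf_select <- function(table, delta = 0, bins = 10) {
  if (min(table(table$labels)) < 2) stopf("need >= 2 rows per class")
  cache <- su_cache(table, bins)
  keep <- which(cache$rcf > delta)
  if (!length(keep)) stopf("no feature exceeds the SU threshold delta = %g", delta)
  ord <- keep[order(-cache$rcf[keep], cache$names[keep])]
  retained <- integer(0)
  for (f in ord) {
    predominant <- TRUE
    for (g in retained) {
      if (cache$get_rff(f, g) >= cache$rcf[f]) {
        predominant <- FALSE
        break
      }
    }
    if (predominant) retained <- c(retained, f)
  }
  structure(list(names = cache$names[retained], method = "FCBF",
                 su = unname(cache$rcf[retained])),
            class = "feature_subset")
}

#' Relief-F feature weights
#'
#' Standard Relief-F: features are range-normalized; for each sampled
#' instance the per-feature distance to its k nearest hits (same class) is
#' subtracted and the class-prior-weighted distance to the k nearest misses
#' of each other class is added. Weights rank features by relevance without
#' eliminating redundant ones (exact duplicates receive equal weight).
#'
#' @param table A [feature_table()].
#' @param k_neighbors Neighbours per class (each class must have more rows).
#' @param n_sample Number of sampled instances, or `NULL` for exhaustive
#'   sampling over all rows (deterministic, row-order invariant).
#' @param seed Seed used only when `n_sample` is given.
#' @return Named numeric vector of feature weights.
#' @export
relieff_rank <- function(table, k_neighbors = 10, n_sample = NULL, seed = 1L) {
  x <- as.matrix(table$features)
  y <- table$labels
  n <- nrow(x)
  classes <- levels(droplevels(y))
  cnt <- table(y)[classes]
  if (any(cnt <= k_neighbors)) {
    stopf("every class needs more than k_neighbors = %d rows", k_neighbors)
  }
  rng <- apply(x, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  xn <- sweep(sweep(x, 2, apply(x, 2, min)), 2, rng, "/")
  priors <- as.numeric(cnt) / n
  names(priors) <- classes
  idx <- if (is.null(n_sample)) {
    seq_len(n)
  } else {
    withr::with_seed(as.integer(seed), sample.int(n, min(n_sample, n)))
  }
  w <- numeric(ncol(x))
  m <- length(idx)
  for (i in idx) {
    di <- colSums((t(xn) - xn[i, ])^2)  # squared Euclidean, monotone for knn
    di[i] <- Inf
    for (cl in classes) {
      members <- which(y == cl & seq_len(n) != i)
      nb <- members[order(di[members], members)][seq_len(k_neighbors)]
      contrib <- colMeans(abs(xn[nb, , drop = FALSE] -
                                matrix(xn[i, ], k_neighbors, ncol(x), byrow = TRUE)))
      if (cl == as.character(y[i])) {
        w <- w - contrib / m
      } else {
        w <- w + (priors[cl] / (1 - priors[as.character(y[i])])) * contrib / m
      }
    }
  }
  stats::setNames(w, colnames(x))
}

#' Relief-F subset sizing by incremental evaluation
#'
#' Orders features by Relief-F weight and evaluates increasingly larger
#' subsets in five-feature increments until the entire feature set is
#' included. Each candidate size is scored by the better test accuracy of a
#' naive Bayes and an SVM classifier on a fixed 75:25 stratified holdout;
#' the smallest size whose accuracy is within `tolerance` percentage points
#' of the full-feature-set accuracy is returned.
#'
#' @param table A [feature_table()].
#' @param weights Relief-F weights for all columns (see [relieff_rank()]).
#' @param increment Subset-size step (default 5).
#' @param tolerance Allowed accuracy drop in percentage points (default 5).
#' @param seed Seed for the evaluation holdout.
#' @return A `feature_subset` with method `"ReliefF"` and the weights of
#'   the selected features.
#' @export
relieff_subset_size <- function(table, weights, increment = 5, tolerance = 5,
                                seed = 1L) {
  p <- ncol(table$features)
  ord <- names(sort(weights, decreasing = TRUE))
  ord <- ord[order(-weights[ord], ord)]   # lexicographic tie-break
  make_subset <- function(nms) {
    structure(list(names = nms, method = "ReliefF",
                   weights = unname(weights[nms])),
              class = "feature_subset")
  }
  if (p <= increment) return(make_subset(ord))
  split <- stratified_holdout(table$labels, train_fraction = 0.75, seed = seed)
  eval_acc <- function(cols) {
    sub <- feature_table(table$features[, cols, drop = FALSE], table$labels,
                         table$participant_id)
    accs <- vapply(list(model_spec("NB", "quadratic"),
                        model_spec("SVM", 1)), function(spec) {
      fit <- train(sub, spec, rows = split$train)
      mean(predict(fit, sub$features[split$test, , drop = FALSE]) ==
             table$labels[split$test])
    }, numeric(1))
    max(accs) * 100
  }
  sizes <- unique(c(seq(increment, p, by = increment), p))
  accs <- vapply(sizes, function(s) eval_acc(ord[seq_len(s)]), numeric(1))
  full_acc <- accs[length(accs)]
  chosen <- sizes[which(accs >= full_acc - tolerance)[1]]
  make_subset(ord[seq_len(chosen)])
}
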