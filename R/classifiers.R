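#' Classifier model specification
#'
#' The classifier bank comprises single-hidden-layer perceptrons with 5 to
#' 25 hidden nodes (`NN`), Gaussian naive Bayes with pooled ("linear") or
#' per-class ("quadratic") variances (`NB`), polynomial-kernel support
#' vector machines of degree 1 to 7 (`SVM`), and a `majority` baseline that
#' always predicts the larger training class.
#'
#' @param family One of `"NN"`, `"NB"`, `"SVM"`, `"majority"`.
#' @param hyper Hidden-node count (NN, 5..25), `"linear"`/`"quadratic"`
#'   (NB), or polynomial degree (SVM, 1..7). Ignored for `majority`.
#' @param seed Seed controlling NN weight initialization.
#' @param standardize Standardize features by training-set mean/SD.
#' @param cost SVM regularization constant.
#' @param maxit NN training epoch cap.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("NN", "NB", "SVM", "majority"),
                       hyper = NULL, seed = 1L, standardize = TRUE,
                       cost = 1, maxit = 2000) {
  family <- match.arg(family)
  if (family == "NN") {
    if (is.null(hyper)) hyper <- 10L
    if (!hyper %in% 5:25) stopf("NN hidden nodes must be in 5..25")
  } else if (family == "NB") {
    if (is.null(hyper)) hyper <- "quadratic"
    hyper <- match.arg(hyper, c("linear", "quadratic"))
  } else if (family == "SVM") {
    if (is.null(hyper)) hyper <- 2L
    if (!hyper %in% 1:7) stopf("SVM polynomial degree must be in 1..7")
  }
  structure(list(family = family, hyper = hyper, seed = as.integer(seed),
                 standardize = isTRUE(standardize), cost = cost,
                 maxit = maxit),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s\n", model_id(x)))
  invisible(x)
}

#' Short model identifier (`NN-15`, `NB-Q`, `SVM-3`, ...)
#' @param spec A `model_spec`.
#' @return Character scalar.
#' @export
model_id <- function(spec) {
  switch(spec$family,
         NN = sprintf("NN-%d", spec$hyper),
         NB = if (spec$hyper == "quadratic") "NB-Q" else "NB-L",
         SVM = sprintf("SVM-%d", spec$hyper),
         majority = "majority")
}

fit_gaussian_nb <- function(x, y, pooled) {
  classes <- levels(y)
  priors <- table(y)[classes] / length(y)
  mu <- do.call(rbind, lapply(classes, function(cl)
    colMeans(x[y == cl, , drop = FALSE])))
  if (pooled) {
    va <- vapply(seq_len(ncol(x)), function(j) {
      resid <- x[, j] - mu[as.integer(y), j]
      max(sum(resid^2) / (nrow(x) - length(classes)), 1e-9)
    }, numeric(1))
    va <- matrix(va, length(classes), ncol(x), byrow = TRUE)
  } else {
    va <- do.call(rbind, lapply(classes, function(cl) {
      v <- apply(x[y == cl, , drop = FALSE], 2, stats::var)
      pmax(ifelse(is.na(v), 1e-9, v), 1e-9)
    }))
  }
  dimnames(mu) <- dimnames(va) <- list(classes, colnames(x))
  list(classes = classes, log_priors = log(as.numeric(priors)),
       mu = mu, va = va)
}

predict_gaussian_nb <- function(fit, x) {
  scores <- vapply(seq_along(fit$classes), function(ci) {
    rowSums(-0.5 * log(2 * pi * matrix(fit$va[ci, ], nrow(x), ncol(x),
                                       byrow = TRUE)) -
              sweep(x, 2, fit$mu[ci, ])^2 /
              (2 * matrix(fit$va[ci, ], nrow(x), ncol(x), byrow = TRUE))) +
      fit$log_priors[ci]
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  fit$classes[max.col(scores, ties.method = "first")]
}

#' Train a classifier on a feature table
#'
#' Features are standardized by training-set mean and SD when the spec's
#' `standardize` flag is set (making predictions invariant to affine
#' rescaling of any input feature). NN training uses a fixed seed for
#' weight initialization; NB fits per-feature Gaussian class-conditionals
#' (pooled variance for the linear variant, per-class for quadratic); the
#' SVM uses an inhomogeneous polynomial kernel at fixed cost.
#'
#' @param table A [feature_table()].
#' @param spec A [model_spec()].
#' @param rows Optional integer indices of training rows (default: all).
#' @return An object of class `trained_model`.
#' @export
train <- function(table, spec, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(table$features))
  x <- as.matrix(table$features[rows, , drop = FALSE])
  y <- droplevels(table$labels[rows])
  if (!all(is.finite(x))) stopf("training features contain non-finite values")
  if (spec$family != "majority" && nlevels(y) < 2) {
    stopf("training set must contain both classes")
  }
  y <- factor(as.character(y), levels = FALLER_LEVELS)
  centers <- rep(0, ncol(x))
  scales <- rep(1, ncol(x))
  if (spec$standardize && spec$family != "majority") {
    centers <- colMeans(x)
    scales <- apply(x, 2, sd)
    scales[!is.finite(scales) | scales == 0] <- 1
    x <- sweep(sweep(x, 2, centers), 2, scales, "/")
  }
  fit <- switch(
    spec$family,
    majority = list(level = names(which.max(table(y)))),
    NB = fit_gaussian_nb(x, y, pooled = (spec$hyper == "linear")),
    SVM = e1071::svm(x, y, kernel = "polynomial", degree = spec$hyper,
                     coef0 = 1, gamma = 1 / ncol(x), cost = spec$cost,
                     scale = FALSE),
    NN = withr::with_seed(spec$seed,
      nnet::nnet(x, class.ind_binary(y), size = spec$hyper,
                 entropy = TRUE, maxit = spec$maxit, trace = FALSE,
                 MaxNWts = 100000))
  )
  structure(list(spec = spec, fit = fit, columns = colnames(x),
                 centers = centers, scales = scales,
                 levels = FALLER_LEVELS),
            class = "trained_model")
}

class.ind_binary <- function(y) {
  matrix(as.numeric(y == FALLER_LEVELS[1]), ncol = 1)
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s on %d feature(s)\n",
              model_id(x$spec), length(x$columns)))
  invisible(x)
}

#' Predict faller labels for new rows
#'
#' @param object A `trained_model`.
#' @param newdata Data frame or matrix with the training columns.
#' @param ... Unused.
#' @return Factor of predicted labels (`faller`/`non_faller`), one per row.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (is.null(colnames(x)) && ncol(x) == length(object$columns)) {
    colnames(x) <- object$columns
  }
  if (!all(object$columns %in% colnames(x))) {
    stopf("newdata is missing training columns")
  }
  x <- x[, object$columns, drop = FALSE]
  if (!all(is.finite(x))) stopf("newdata contains non-finite values")
  x <- sweep(sweep(x, 2, object$centers), 2, object$scales, "/")
  lab <- switch(
    object$spec$family,
    majority = rep(object$fit$level, nrow(x)),
    NB = predict_gaussian_nb(object$fit, x),
    SVM = as.character(predict(object$fit, x)),
    NN = ifelse(predict(object$fit, x)[, 1] >= 0.5,
                FALLER_LEVELS[1], FALLER_LEVELS[2])
  )
  factor(unname(lab), levels = object$levels)
}

#' The full study classifier grid
#'
#' @param nn_nodes Hidden-node counts for the NN family.
#' @param svm_degrees Polynomial degrees for the SVM family.
#' @param nb_variants NB variants.
#' @param seed Shared NN seed.
#' @return List of [model_spec()]s (default: 21 NNs + 2 NBs + 7 SVMs).
#' @export
model_grid <- function(nn_nodes = 5:25, svm_degrees = 1:7,
                       nb_variants = c("linear", "quadratic"), seed = 1L) {
  c(lapply(nn_nodes, function(h) model_spec("NN", h, seed = seed)),
    lapply(nb_variants, function(v) model_spec("NB", v)),
    lapply(svm_degrees, function(d) model_spec("SVM", d)))
}
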