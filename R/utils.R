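#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd median quantile predict fft lm coef
#'   complete.cases setNames aggregate
#' @importFrom utils head tail write.csv read.csv
NULL

# Positive-class label used throughout: retrospective fallers.
FALLER_LEVELS <- c("faller", "non_faller")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("'%s' must be a single positive finite number", name)
  }
  invisible(x)
}

assert_finite <- function(x, name) {
  if (!all(is.finite(x))) stopf("'%s' contains non-finite values", name)
  invisible(x)
}

# Deterministic per-unit sub-seed derivation; keeps seeds within 32-bit range.
derive_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 7919) %% 2147483647)
}

as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (!all(labels %in% FALLER_LEVELS)) {
    stopf("labels must be one of: %s", paste(FALLER_LEVELS, collapse = ", "))
  }
  factor(labels, levels = FALLER_LEVELS)
}
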