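#' Detect stance events from an insole force series
#'
#' Foot-strike is an upward crossing of the force threshold and foot-off the
#' following downward crossing. Incomplete leading/trailing stances (series
#' starting above threshold, or a strike without a matching off) are
#' discarded. The default 10 N threshold is a conventional small fraction of
#' body weight.
#'
#' @param force Numeric vector of total plantar force (N), sampled at `fs`.
#' @param threshold Contact threshold in N (> 0).
#' @param fs Sampling rate in Hz (insole default 120).
#' @return An object of class `stride_events`: lists of `foot_strike` and
#'   `foot_off` sample indices plus derived `stance_time`, `swing_time` and
#'   `stride_time` vectors in seconds (one entry per complete stride;
#'   stance + swing = stride).
#' @export
detect_stance_events <- function(force, threshold = 10, fs = 120) {
  assert_finite(force, "force")
  assert_scalar_pos(threshold, "threshold")
  if (any(force < 0)) stopf("'force' must be non-negative")
  above <- force >= threshold
  d <- diff(as.integer(above))
  strikes <- which(d == 1L) + 1L   # first sample at/above threshold
  offs <- which(d == -1L) + 1L     # first sample back below threshold
  # pair each strike with the next off; drop an off before the first strike
  offs <- offs[offs > if (length(strikes)) strikes[1] else Inf]
  n <- min(length(strikes), length(offs))
  strikes <- strikes[seq_len(n)]
  offs <- offs[seq_len(n)]
  stride <- if (n >= 2) diff(strikes) / fs else numeric(0)
  stance_full <- (offs - strikes) / fs
  stance <- stance_full[seq_len(max(n - 1, 0))]
  structure(
    list(foot_strike = strikes, foot_off = offs, fs = fs,
         stance_time = stance, swing_time = stride - stance,
         stride_time = stride, stance_time_all = stance_full),
    class = "stride_events"
  )
}

#' @export
print.stride_events <- function(x, ...) {
  cat(sprintf("<stride_events> %d stances, %d complete strides @%g Hz\n",
              length(x$foot_strike), length(x$stride_time), x$fs))
  invisible(x)
}

# Stance landmarks for the bimodal force curve: first peak, mid-stance
# minimum, second peak (indices relative to the stance segment). When the
# curve is not bimodal the peaks fall back to the maxima of the first and
# second halves with the minimum between them, and a warning is raised.
stance_landmarks <- function(f) {
  n <- length(f)
  half <- floor(n / 2)
  p1 <- which.max(f[seq_len(half)])
  p2 <- half + which.max(f[(half + 1):n])
  vmin <- p1 + which.min(f[p1:p2]) - 1L
  if (f[vmin] >= min(f[p1], f[p2]) - 1e-9) {
    warning("stance without a bimodal force curve; using half-split landmarks",
            call. = FALSE)
  }
  list(p1 = p1, vmin = vmin, p2 = p2)
}

trapz_seg <- function(t, y, i, j) {
  if (j <= i) return(0)
  pracma::trapz(t[i:j], y[i:j])
}

#' Mass-normalised stance impulse features I1-I7
#'
#' For each complete stance the total force-time curve is divided by the
#' landmarks first peak, mid-stance minimum and second peak, and the force is
#' integrated (trapezoid rule at the native sampling rate) over each
#' landmark-delimited interval, then normalised by body mass (N s/kg):
#' I1 foot-strike to first peak, I2 first peak to minimum, I3 minimum to
#' second peak, I4 second peak to foot-off, I5 foot-strike to minimum,
#' I6 minimum to foot-off, I7 foot-strike to foot-off. By construction
#' I5 = I1 + I2, I6 = I3 + I4 and I7 = I5 + I6.
#'
#' @param force Numeric force vector (N) at `events$fs`.
#' @param events A [detect_stance_events()] result.
#' @param body_mass Body mass in kg (> 0).
#' @return A data frame with one row per stance and columns `i1` .. `i7`.
#' @export
impulse_features <- function(force, events, body_mass) {
  assert_scalar_pos(body_mass, "body_mass")
  if (length(events$foot_strike) < 1) stopf("no complete stances")
  t <- seq_along(force) / events$fs
  out <- lapply(seq_along(events$foot_strike), function(i) {
    a <- events$foot_strike[i]
    b <- events$foot_off[i]
    seg <- force[a:b]
    if (all(seg == 0)) {
      return(data.frame(i1 = 0, i2 = 0, i3 = 0, i4 = 0, i5 = 0, i6 = 0, i7 = 0))
    }
    lm_ <- stance_landmarks(seg)
    p1 <- a + lm_$p1 - 1L
    vm <- a + lm_$vmin - 1L
    p2 <- a + lm_$p2 - 1L
    i1 <- trapz_seg(t, force, a, p1) / body_mass
    i2 <- trapz_seg(t, force, p1, vm) / body_mass
    i3 <- trapz_seg(t, force, vm, p2) / body_mass
    i4 <- trapz_seg(t, force, p2, b) / body_mass
    data.frame(i1 = i1, i2 = i2, i3 = i3, i4 = i4,
               i5 = i1 + i2, i6 = i3 + i4, i7 = i1 + i2 + i3 + i4)
  })
  do.call(rbind, out)
}

run_lengths <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values],
             len = r$lengths[r$values])
}

#' Centre-of-pressure deviation and variability features per stance
#'
#' A posterior deviation is a maximal run of frames with negative AP CoP
#' velocity (movement against the normal anterior progression); per stance
#' the count, summed 2-D CoP path length (mm) and summed duration (s) are
#' reported. An ML deviation is a maximal run where the ML coordinate
#' departs from its running median by more than `ml_band` mm; the count,
#' summed lateral-side and medial-side excursion magnitudes (mm) and summed
#' duration are reported. AP and ML coefficients of variation
#' (SD / |mean| x 100) of the stance CoP coordinate series complete the set.
#'
#' @param cop_ap,cop_ml CoP coordinate vectors (mm) on the insole time grid;
#'   may be `NA` outside stance.
#' @param events A [detect_stance_events()] result.
#' @param ml_band Half-width of the ML deviation band in mm (default 2).
#' @param ml_lateral_positive Sign convention: `TRUE` if positive ML is the
#'   lateral direction for this foot.
#' @return Data frame, one row per stance: `pdev_count`, `pdev_length`,
#'   `pdev_duration`, `mldev_count`, `mldev_lateral_length`,
#'   `mldev_medial_length`, `mldev_duration`, `cop_ap_cov`, `cop_ml_cov`.
#' @export
cop_deviation_features <- function(cop_ap, cop_ml, events, ml_band = 2,
                                   ml_lateral_positive = TRUE) {
  fs <- events$fs
  out <- lapply(seq_along(events$foot_strike), function(i) {
    idx <- events$foot_strike[i]:events$foot_off[i]
    if (length(idx) < 3) {
      warning("stance shorter than 3 frames skipped", call. = FALSE)
      return(NULL)
    }
    ap <- cop_ap[idx]
    ml <- cop_ml[idx]
    if (anyNA(ap) || anyNA(ml)) {
      keep <- !(is.na(ap) | is.na(ml))
      ap <- ap[keep]; ml <- ml[keep]
      if (length(ap) < 3) return(NULL)
    }
    dap <- diff(ap)
    dml <- diff(ml)
    step_len <- sqrt(dap^2 + dml^2)
    post <- run_lengths(dap < 0)
    pdev_length <- if (nrow(post)) {
      sum(vapply(seq_len(nrow(post)), function(j)
        sum(step_len[post$start[j]:post$end[j]]), numeric(1)))
    } else 0
    med <- stats::runmed(ml, k = min(11L, length(ml) - (1 - length(ml) %% 2)))
    dev <- ml - med
    if (!ml_lateral_positive) dev <- -dev
    flag <- abs(dev) > ml_band
    mlr <- run_lengths(flag)
    lat <- sum(pmax(dev[flag], 0))
    medl <- sum(pmax(-dev[flag], 0))
    data.frame(
      pdev_count = nrow(post),
      pdev_length = pdev_length,
      pdev_duration = sum(post$len) / fs,
      mldev_count = nrow(mlr),
      mldev_lateral_length = lat,
      mldev_medial_length = medl,
      mldev_duration = sum(mlr$len) / fs,
      cop_ap_cov = if (abs(mean(ap)) > 0) sd(ap) / abs(mean(ap)) * 100 else 0,
      cop_ml_cov = if (abs(mean(ml)) > 0) sd(ml) / abs(mean(ml)) * 100 else 0
    )
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) stopf("no usable stances")
  do.call(rbind, out)
}

#' Temporal gait features from bilateral stance events
#'
#' Cadence (steps/min, from the merged bilateral foot-strike sequence),
#' means and coefficients of variation of stride, stance and swing time
#' pooled across both limbs, percent stance, percent double support
#' (summed bilateral-contact time per stride time), and the stride-time
#' symmetry index |L - R| / (0.5 (L + R)) x 100.
#'
#' @param events_left,events_right [detect_stance_events()] results.
#' @return Named list of temporal features.
#' @export
temporal_features <- function(events_left, events_right) {
  if (length(events_left$stride_time) < 2 || length(events_right$stride_time) < 2) {
    stopf("at least 2 complete strides per foot are required")
  }
  fs <- events_left$fs
  strikes <- sort(c(events_left$foot_strike, events_right$foot_strike)) / fs
  step_times <- diff(strikes)
  cadence <- 60 / mean(step_times)

  stride <- c(events_left$stride_time, events_right$stride_time)
  stance <- c(events_left$stance_time, events_right$stance_time)
  swing <- c(events_left$swing_time, events_right$swing_time)
  cov <- function(x) if (mean(x) > 0) sd(x) / mean(x) * 100 else 0

  # double support: overlap of left and right contact intervals
  intervals <- function(ev) cbind(ev$foot_strike / ev$fs, ev$foot_off / ev$fs)
  li <- intervals(events_left)
  ri <- intervals(events_right)
  ds <- 0
  for (i in seq_len(nrow(li))) {
    lo <- pmax(li[i, 1], ri[, 1])
    hi <- pmin(li[i, 2], ri[, 2])
    ds <- ds + sum(pmax(hi - lo, 0))
  }
  total_stride_time <- sum(stride)
  lmean <- mean(events_left$stride_time)
  rmean <- mean(events_right$stride_time)

  list(
    cadence = cadence,
    stride_time = mean(stride),
    stance_time = mean(stance),
    swing_time = mean(swing),
    pct_stance = mean(stance) / mean(stride) * 100,
    pct_double_support = if (total_stride_time > 0) 2 * ds / total_stride_time * 100 else 0,
    stride_time_symmetry = abs(lmean - rmean) / (0.5 * (lmean + rmean)) * 100,
    stride_time_cov = cov(stride),
    stance_time_cov = cov(stance),
    swing_time_cov = cov(swing)
  )
}

#' Canonical pressure-insole feature names
#'
#' The insole bank carries 30 features: 9 CoP-path features, 10 temporal
#' features, the 7 mass-normalised impulses I1-I7 (means across strides of
#' both limbs), and 4 across-stride SD features (`extra_sd`, configurable;
#' defaults to the SDs of I3, I6, I7 and stride time, the variables most
#' implicated in faller gait).
#'
#' @param extra_sd Character vector of 4 stance/stride variables whose
#'   across-stride SD fills the remaining registry slots.
#' @return Character vector of 30 names, prefixed `insole.`.
#' @export
insole_feature_names <- function(extra_sd = c("i3", "i6", "i7", "stride_time")) {
  stopifnot(length(extra_sd) == 4)
  paste0("insole.", c(
    "pdev_count", "pdev_length", "pdev_duration",
    "mldev_count", "mldev_lateral_length", "mldev_medial_length",
    "mldev_duration", "cop_ap_cov", "cop_ml_cov",
    "cadence", "stride_time", "stance_time", "swing_time",
    "pct_stance", "pct_double_support", "stride_time_symmetry",
    "stride_time_cov", "stance_time_cov", "swing_time_cov",
    paste0("i", 1:7),
    paste0(extra_sd, "_sd")
  ))
}

#' Extract the full insole feature vector from one trial
#'
#' Runs stance detection on each foot, computes impulse, CoP-deviation and
#' temporal features per stride, pools strides of both limbs, and aggregates
#' (means, plus the four registry SD slots). Swapping the two feet leaves
#' the vector unchanged.
#'
#' @param trial A `sensor_trial`.
#' @param threshold Foot-contact force threshold (N).
#' @param ml_band ML deviation band (mm), see [cop_deviation_features()].
#' @return Named numeric vector of length 30 (see [insole_feature_names()]).
#' @export
insole_feature_vector <- function(trial, threshold = 10, ml_band = 2) {
  feet <- c("left", "right")
  if (!all(feet %in% names(trial$insole))) stopf("both feet must be present")
  ev <- lapply(feet, function(f)
    detect_stance_events(trial$insole[[f]]$force, threshold = threshold))
  names(ev) <- feet
  for (f in feet) {
    if (length(ev[[f]]$stride_time) < 2) {
      stopf("foot '%s' has fewer than 2 complete strides", f)
    }
  }
  imp <- lapply(feet, function(f)
    impulse_features(trial$insole[[f]]$force, ev[[f]], trial$body_mass))
  # insole CoP ML is foot-local with positive = lateral for either foot, so
  # the vector is invariant under left/right relabelling
  cop <- lapply(feet, function(f)
    cop_deviation_features(trial$insole[[f]]$cop_ap, trial$insole[[f]]$cop_ml,
                           ev[[f]], ml_band = ml_band,
                           ml_lateral_positive = TRUE))
  imp_all <- rbind(imp[[1]], imp[[2]])
  cop_all <- rbind(cop[[1]], cop[[2]])
  tmp <- temporal_features(ev$left, ev$right)

  stride_all <- c(ev$left$stride_time, ev$right$stride_time)
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  extra <- c(i3_sd = sd0(imp_all$i3), i6_sd = sd0(imp_all$i6),
             i7_sd = sd0(imp_all$i7), stride_time_sd = sd0(stride_all))

  vec <- c(
    colMeans(cop_all),
    unlist(tmp),
    colMeans(imp_all),
    extra
  )
  names(vec) <- paste0("insole.", names(vec))
  vec <- vec[insole_feature_names()]
  stopifnot(!anyNA(names(vec)))
  vec
}
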