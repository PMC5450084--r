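#' Zero-phase low-pass filtering of acceleration signals
#'
#' Fifth-order low-pass Butterworth filter with a 12.5 Hz cut-off, applied
#' forward-backward (zero phase) so gait landmarks are not lagged.
#' Descriptive statistics and the Lyapunov exponent consume the filtered
#' signal; the FFT first-quartile and even/odd-harmonic features use the
#' unfiltered signal.
#'
#' @param x Numeric vector (one acceleration axis) sampled at `fs`.
#' @param fs Sampling rate in Hz (accelerometer default 50).
#' @param cutoff Cut-off frequency in Hz.
#' @param order Filter order.
#' @return Filtered numeric vector of the same length.
#' @export
lowpass <- function(x, fs = 50, cutoff = 12.5, order = 5) {
  assert_finite(x, "x")
  if (length(x) < 30) stopf("signal too short for filter warm-up (need >= 30 samples)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding suppresses the forward-backward pass's edge
  # transients (matches the conventional filtfilt treatment)
  n <- length(x)
  np <- min(n - 1, 3 * (order + 1) * 2)
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(np + 1):(np + n)]
}

#' Directional half-axis statistics
#'
#' Each signed anatomical axis is split into its two directional half-axes
#' (superior/inferior for vertical, anterior/posterior for AP, right/left
#' for ML). For each direction the magnitudes of the samples on that side
#' are collected and their maximum, mean and SD reported (zeros for an
#' empty side), giving 18 non-negative statistics in g.
#'
#' @param vertical,ap,ml Filtered axis signals (g); vertical + = superior,
#'   AP + = anterior, ML + = right.
#' @return Named numeric vector of 18 values, e.g. `superior_max`,
#'   `posterior_mean`, `left_sd`.
#' @export
directional_stats <- function(vertical, ap, ml) {
  half_stats <- function(x, pos_name, neg_name) {
    one <- function(v) {
      if (!length(v)) return(c(max = 0, mean = 0, sd = 0))
      c(max = max(v), mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
    }
    pos <- one(x[x > 0])
    neg <- one(-x[x < 0])
    stats::setNames(c(pos, neg),
                    c(paste0(pos_name, "_", c("max", "mean", "sd")),
                      paste0(neg_name, "_", c("max", "mean", "sd"))))
  }
  c(half_stats(vertical, "superior", "inferior"),
    half_stats(ap, "anterior", "posterior"),
    half_stats(ml, "right", "left"))
}

#' Cadence and stride time from the vertical acceleration
#'
#' Step peaks are located on the filtered vertical axis by local-maximum
#' detection with a minimum inter-peak distance of 0.35 s. Stride time is
#' the median interval between every second step peak (robust to the
#' asymmetric spacing of the two step peaks within one stride) and cadence
#' is steps per minute, two steps per stride, so
#' cadence x stride time = 120.
#'
#' @param vertical Filtered vertical acceleration (g).
#' @param fs Sampling rate (Hz).
#' @param min_step_time Minimum admissible step interval (s).
#' @return List with `cadence` (steps/min), `stride_time` (s) and the step
#'   peak indices.
#' @export
stride_events_accel <- function(vertical, fs = 50, min_step_time = 0.35) {
  rng <- diff(range(vertical))
  if (rng <= 0) stopf("flat signal: no step peaks detectable")
  pk <- pracma::findpeaks(vertical,
                          minpeakdistance = ceiling(min_step_time * fs),
                          minpeakheight = min(vertical) + 0.5 * rng)
  if (is.null(pk) || nrow(pk) < 3) stopf("fewer than 3 step peaks detected")
  peaks <- sort(pk[, 2])
  n <- length(peaks)
  stride_time <- median(peaks[3:n] - peaks[1:(n - 2)]) / fs
  list(cadence = 120 / stride_time, stride_time = stride_time, peaks = peaks)
}

spectrum_mag <- function(x, fs) {
  n <- length(x)
  mag <- Mod(fft(x))[seq_len(floor(n / 2) + 1)]
  freq <- (seq_len(floor(n / 2) + 1) - 1) * fs / n
  # DC excluded
  list(freq = freq[-1], mag = mag[-1])
}

#' Percentage of spectral magnitude in the first frequency quartile
#'
#' Magnitude spectrum of the unfiltered signal (DC excluded) over the
#' analyzable band 0 to `fs`/2; returns the percentage of total magnitude at
#' frequencies at or below the first quartile of that band (`fs`/8, i.e.
#' 6.25 Hz at 50 Hz sampling).
#'
#' @param x Unfiltered axis signal.
#' @param fs Sampling rate (Hz).
#' @return Percentage in `[0, 100]`.
#' @export
fft_quartile <- function(x, fs = 50) {
  if (length(x) < 64) stopf("need at least 64 samples for the spectrum")
  sp <- spectrum_mag(x, fs)
  total <- sum(sp$mag)
  if (total <= 0) stopf("all-zero signal: FFT quartile undefined")
  100 * sum(sp$mag[sp$freq <= fs / 8]) / total
}

#' Ratio of even to odd stride-frequency harmonics (REOH)
#'
#' Reads the spectral amplitude at harmonics k f0, k = 1..`n_harmonics`
#' (harmonics above Nyquist truncated), of the unfiltered signal. Each
#' harmonic amplitude is the maximum spectral magnitude within a small
#' frequency window of the harmonic, making the estimate robust to slight
#' stride-frequency error. Returns the proportion of harmonic content at
#' even harmonics, even / (even + odd) in `[0, 1]`: the share of the signal
#' in phase with the step (rather than stride) cycle. `proportion = FALSE`
#' gives the plain even/odd ratio instead.
#'
#' @param x Unfiltered axis signal.
#' @param stride_frequency Fundamental stride frequency f0 (Hz, > 0).
#' @param fs Sampling rate (Hz).
#' @param n_harmonics Number of harmonics considered.
#' @param tol Half-width (Hz) of the window around each harmonic.
#' @param proportion Return even/(even+odd) (default) or even/odd.
#' @return Numeric scalar.
#' @export
reoh <- function(x, stride_frequency, fs = 50, n_harmonics = 20, tol = 0.1,
                 proportion = TRUE) {
  assert_scalar_pos(stride_frequency, "stride_frequency")
  sp <- spectrum_mag(x, fs)
  df <- sp$freq[2] - sp$freq[1]
  ks <- seq_len(n_harmonics)
  ks <- ks[ks * stride_frequency <= fs / 2]
  if (length(ks) < 2) stopf("fewer than 2 usable harmonics below Nyquist")
  amp <- vapply(ks, function(k) {
    sel <- abs(sp$freq - k * stride_frequency) <= max(tol, df / 2 + 1e-9)
    if (!any(sel)) 0 else max(sp$mag[sel])
  }, numeric(1))
  even <- sum(amp[ks %% 2 == 0])
  odd <- sum(amp[ks %% 2 == 1])
  if (proportion) {
    if (even + odd <= 0) return(0)
    even / (even + odd)
  } else {
    if (odd <= 0) stopf("odd-harmonic content is zero; ratio undefined")
    even / odd
  }
}

# Average mutual information between x(t) and x(t+lag) with equal-width
# binning; used to pick the embedding delay.
ami <- function(x, lag, bins = 16) {
  n <- length(x) - lag
  a <- x[seq_len(n)]
  b <- x[seq_len(n) + lag]
  br <- seq(min(x), max(x), length.out = bins + 1)
  ia <- findInterval(a, br, rightmost.closed = TRUE, all.inside = TRUE)
  ib <- findInterval(b, br, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(ia, ib) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}

first_ami_minimum <- function(x, max_lag, bins = 16) {
  vals <- vapply(seq_len(max_lag), function(l) ami(x, l, bins), numeric(1))
  for (l in 2:(max_lag - 1)) {
    if (vals[l] < vals[l - 1] && vals[l] <= vals[l + 1]) return(l)
  }
  max(1L, round(max_lag / 4))
}

#' Maximum Lyapunov exponent of a gait signal (Rosenstein method)
#'
#' Delay-embeds the filtered axis signal (delay = first minimum of the
#' average mutual information, embedding dimension `dim`), finds each
#' point's nearest neighbour outside a Theiler window of one stride, tracks
#' the mean log-divergence of neighbour pairs over time, and returns the
#' least-squares slope of that curve over 0 to `fit_strides` stride times,
#' in 1/s. Positive values indicate local dynamic instability. Estimates
#' from short walks (fewer than ~35 strides) are low-reliability and should
#' be interpreted comparatively.
#'
#' @param x Filtered axis signal.
#' @param stride_time Stride time in seconds (Theiler window and fit region
#'   are expressed in strides).
#' @param fs Sampling rate (Hz).
#' @param dim Embedding dimension.
#' @param delay Embedding delay in samples; `NULL` selects it by the first
#'   AMI minimum.
#' @param fit_strides Length of the divergence-fit region in strides.
#' @param trim Seconds discarded at each end of the series before
#'   embedding, to keep zero-phase filter edge transients out of the
#'   neighbour search.
#' @return Exponent in 1/s.
#' @export
mle <- function(x, stride_time, fs = 50, dim = 5, delay = NULL,
                fit_strides = 0.5, trim = 0.5) {
  assert_scalar_pos(stride_time, "stride_time")
  n_trim <- round(trim * fs)
  if (length(x) > 3 * n_trim + 2) {
    x <- x[(n_trim + 1):(length(x) - n_trim)]
  }
  # exclusion window spans strictly less than one stride so the natural
  # one-period recurrence of a periodic signal remains admissible
  theiler <- max(1L, round(stride_time * fs) - 1L)
  if (is.null(delay)) {
    max_lag <- min(max(4L, theiler), length(x) - dim * 2L)
    if (max_lag < 3) stopf("series too short for delay selection")
    delay <- first_ami_minimum(x, max_lag)
  }
  m <- length(x) - (dim - 1) * delay
  if (m < 3 * theiler) stopf("series too short for embedding")
  emb <- sapply(0:(dim - 1), function(j) x[(1:m) + j * delay])
  k_max <- max(2L, round(fit_strides * stride_time * fs))
  k_max <- min(k_max, m - 1L)

  d2 <- as.matrix(stats::dist(emb))
  diag(d2) <- Inf
  nn <- integer(m)
  for (i in seq_len(m)) {
    row <- d2[i, ]
    row[abs(seq_len(m) - i) <= theiler] <- Inf
    nn[i] <- which.min(row)
    if (!is.finite(row[nn[i]])) nn[i] <- NA_integer_
  }
  valid <- which(!is.na(nn) & seq_len(m) + k_max <= m & nn + k_max <= m)
  if (length(valid) < 5) stopf("too few neighbour pairs for divergence fit")

  # distances floored at a tiny fraction of signal scale: exactly periodic
  # signals then give a flat divergence curve (slope ~ 0) instead of
  # numerical-level drift driving the log
  floor_d <- 1e-4 * max(sd(x), .Machine$double.eps)
  mean_log_div <- vapply(0:k_max, function(k) {
    dk <- sqrt(rowSums((emb[valid + k, , drop = FALSE] -
                          emb[nn[valid] + k, , drop = FALSE])^2))
    mean(log(pmax(dk, floor_d)))
  }, numeric(1))
  kk <- 0:k_max
  ok <- is.finite(mean_log_div)
  if (sum(ok) < 3) return(0)
  unname(coef(lm(mean_log_div[ok] ~ I(kk[ok] / fs)))[2])
}

accel_feature_basenames <- c(
  paste0(rep(c("superior", "inferior", "anterior", "posterior", "right", "left"),
             each = 3), "_", c("max", "mean", "sd")),
  "cadence", "stride_time",
  paste0("fftq_", c("vertical", "ap", "ml")),
  paste0("reoh_", c("vertical", "ap", "ml")),
  paste0("mle_", c("vertical", "ap", "ml"))
)

#' Accelerometer feature names for one body site
#'
#' @param location Site prefix (`head`, `pelvis`, `lshank`, `rshank`).
#' @return Character vector of the 29 namespaced feature names.
#' @export
accel_feature_names <- function(location) {
  paste0(location, ".", accel_feature_basenames)
}

#' Extract the 29-feature accelerometer bank for one body site
#'
#' Assembles, in fixed order: 18 directional half-axis statistics (filtered
#' signal), cadence and stride time (filtered vertical axis), FFT
#' first-quartile percentage and REOH for the vertical/AP/ML axes
#' (unfiltered signal), and the maximum Lyapunov exponent for the three
#' axes (filtered signal).
#'
#' @param trial A `sensor_trial`.
#' @param location Body site name present in `trial$accel`.
#' @param fs Sampling rate (Hz).
#' @return Named numeric vector of length 29.
#' @export
accel_feature_vector <- function(trial, location, fs = 50) {
  if (!location %in% names(trial$accel) || is.null(trial$accel[[location]])) {
    stopf("sensor '%s' missing from trial %s", location, trial$participant_id)
  }
  df <- trial$accel[[location]]
  filt <- lapply(df[c("vertical", "ap", "ml")], lowpass, fs = fs)
  ev <- stride_events_accel(filt$vertical, fs = fs)
  f0 <- 1 / ev$stride_time
  axes <- c("vertical", "ap", "ml")
  fftq <- vapply(axes, function(a) fft_quartile(df[[a]], fs), numeric(1))
  reohs <- vapply(axes, function(a) reoh(df[[a]], f0, fs), numeric(1))
  mles <- vapply(axes, function(a) mle(filt[[a]], ev$stride_time, fs), numeric(1))
  vec <- c(
    directional_stats(filt$vertical, filt$ap, filt$ml),
    cadence = ev$cadence, stride_time = ev$stride_time,
    stats::setNames(fftq, paste0("fftq_", axes)),
    stats::setNames(reohs, paste0("reoh_", axes)),
    stats::setNames(mles, paste0("mle_", axes))
  )
  names(vec) <- paste0(location, ".", names(vec))
  stopifnot(identical(names(vec), accel_feature_names(location)))
  vec
}
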