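fs <- 50

test_that("low-pass filter matches its design response", {
  t <- seq(0, 10, by = 1 / fs)
  expect_equal(lowpass(rep(0.7, 500)), rep(0.7, 500), tolerance = 1e-7)

  s20 <- sin(2 * pi * 20 * t)
  out20 <- lowpass(s20)
  mid <- 100:(length(t) - 100)
  expect_lt(max(abs(out20[mid])), 0.1)   # 20 Hz well above cut-off

  s1 <- sin(2 * pi * 1 * t)
  out1 <- lowpass(s1)
  expect_equal(max(abs(out1[mid])), 1, tolerance = 0.01)

  expect_error(lowpass(rnorm(10)), "short")
})

test_that("directional stats split half-axes correctly", {
  n <- 200
  d <- directional_stats(rep(1, n), rep(0, n), rep(0, n))
  expect_equal(unname(d[c("superior_max", "superior_mean", "superior_sd")]),
               c(1, 1, 0))
  expect_equal(unname(d[c("inferior_max", "inferior_mean", "inferior_sd")]),
               c(0, 0, 0))

  # dense unit sine: mean of rectified half-samples tends to 2/pi
  t <- seq(0, 100, length.out = 100000)
  d2 <- directional_stats(rep(0, length(t)), sin(2 * pi * t), rep(0, length(t)))
  expect_equal(unname(d2["anterior_mean"]), 2 / pi, tolerance = 1e-3)
  expect_equal(unname(d2["anterior_max"]), 1, tolerance = 1e-6)

  ml <- rnorm(500)
  a <- directional_stats(rnorm(500), rnorm(500), ml)
  b <- directional_stats(rnorm(500), rnorm(500), -ml)
  for (s in c("max", "mean", "sd")) {
    expect_equal(a[[paste0("right_", s)]], b[[paste0("left_", s)]])
    expect_equal(a[[paste0("left_", s)]], b[[paste0("right_", s)]])
  }
})

test_that("accelerometer stride timing matches generator truth", {
  tr <- generate_trial(noiseless_profile(), seed = 5)
  ev <- stride_events_accel(lowpass(tr$accel$pelvis$vertical))
  expect_equal(ev$stride_time, 1.0, tolerance = 0.02)
  expect_equal(ev$cadence * ev$stride_time, 120, tolerance = 1e-9)
  expect_error(stride_events_accel(rep(0, 300)), "flat")
})

test_that("FFT first-quartile percentage behaves as a spectral fraction", {
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(fft_quartile(sin(2 * pi * 2 * t)), 100, tolerance = 0.5)
  expect_lt(fft_quartile(sin(2 * pi * 10 * t)), 1)
  expect_error(fft_quartile(rep(0, 500)), "all-zero")
  expect_error(fft_quartile(rnorm(32)), "64 samples")

  # flat-spectrum expectation: white noise concentrates 25% of magnitude
  # in the first quartile of the band, Monte-Carlo averaged
  vals <- withr::with_seed(42,
    vapply(1:100, function(i) fft_quartile(rnorm(512)), numeric(1)))
  expect_equal(mean(vals), 25, tolerance = 1)
})

test_that("REOH separates stride- and step-locked content", {
  # exact-period signals: 10 s at 50 Hz, f0 = 1 Hz
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  f0 <- 1
  expect_equal(reoh(sin(2 * pi * 2 * f0 * t), f0), 1.0, tolerance = 1e-6)
  expect_equal(reoh(sin(2 * pi * f0 * t), f0), 0.0, tolerance = 1e-6)
  mix <- sin(2 * pi * f0 * t) + sin(2 * pi * 2 * f0 * t + 0.7)
  expect_equal(reoh(mix, f0), 0.5, tolerance = 1e-6)
  expect_error(reoh(mix, stride_frequency = 20), "harmonics")
})

test_that("REOH and FFT quartile are bounded; directional stats non-negative", {
  tr <- generate_trial(gait_profile(), seed = 17)
  for (site in c("head", "lshank")) {
    v <- accel_feature_vector(tr, site)
    expect_true(all(v[paste0(site, ".", c("reoh_vertical", "reoh_ap", "reoh_ml"))] >= 0))
    expect_true(all(v[paste0(site, ".", c("reoh_vertical", "reoh_ap", "reoh_ml"))] <= 1))
    fq <- v[paste0(site, ".", c("fftq_vertical", "fftq_ap", "fftq_ml"))]
    expect_true(all(fq >= 0 & fq <= 100))
    expect_true(all(v[1:18] >= 0))
  }
})

test_that("MLE is ~0 for periodic signals and positive for noise", {
  t <- seq(0, 20, by = 1 / fs)
  periodic <- cos(2 * pi * t) + 0.4 * cos(4 * pi * t + 1)
  noise_scale <- withr::with_seed(7, mle(rnorm(1000), 1.0))
  expect_gt(noise_scale, 0)
  expect_lt(abs(mle(periodic, 1.0)), 0.05 * noise_scale)
})

test_that("MLE agrees with an independent Rosenstein implementation on Lorenz data", {
  lorenz <- function(t, y, p) {
    list(c(10 * (y[2] - y[1]),
           y[1] * (28 - y[3]) - y[2],
           y[1] * y[2] - 8 / 3 * y[3]))
  }
  times <- seq(0, 60, by = 0.02)
  sol <- deSolve::ode(c(1, 1, 20), times, lorenz, NULL, method = "rk4")
  x <- sol[1001:3000, 2]   # transient discarded
  pseudo_period <- 0.75
  delay <- 5

  est <- mle(x, pseudo_period, fs = 50, dim = 5, delay = delay, trim = 0)

  # brute-force second implementation: plain loops, same hyper-parameters
  oracle_mle <- function(x, dim, delay, theiler, k_max, fs) {
    m <- length(x) - (dim - 1) * delay
    emb <- sapply(0:(dim - 1), function(j) x[(1:m) + j * delay])
    nn <- rep(NA_integer_, m)
    for (i in 1:m) {
      best <- Inf
      for (j in 1:m) {
        if (abs(i - j) <= theiler) next
        d <- sqrt(sum((emb[i, ] - emb[j, ])^2))
        if (d < best) { best <- d; nn[i] <- j }
      }
    }
    keep <- which(1:m + k_max <= m & nn + k_max <= m)
    curve <- sapply(0:k_max, function(k) {
      d <- sqrt(rowSums((emb[keep + k, ] - emb[nn[keep] + k, ])^2))
      mean(log(d[d > 0]))
    })
    kk <- (0:k_max) / fs
    sum((kk - mean(kk)) * (curve - mean(curve))) / sum((kk - mean(kk))^2)
  }
  ref <- oracle_mle(x, dim = 5, delay = delay,
                    theiler = round(pseudo_period * 50) - 1,
                    k_max = round(0.5 * pseudo_period * 50), fs = 50)
  expect_gt(est, 0)
  expect_equal(est, ref, tolerance = 0.2)
})

test_that("the 29-feature vector is complete, named and routed correctly", {
  tr <- generate_trial(gait_profile(), seed = 19)
  v <- accel_feature_vector(tr, "head")
  expect_length(v, 29)
  expect_identical(names(v), accel_feature_names("head"))
  expect_false(anyDuplicated(names(v)) > 0)
  expect_error(accel_feature_vector(tr, "sacrum"), "missing")

  # a 20 Hz contaminant passes the raw path (FFT/REOH) but is filtered out
  # of the descriptive-stat and MLE path
  tr2 <- tr
  t <- tr$accel$head$time
  tr2$accel$head$ap <- tr$accel$head$ap + 0.5 * sin(2 * pi * 20 * t)
  v2 <- accel_feature_vector(tr2, "head")
  ap_stats <- paste0("head.", c("anterior_max", "anterior_mean", "anterior_sd",
                                "posterior_max", "posterior_mean",
                                "posterior_sd", "mle_ap"))
  expect_equal(v2[ap_stats], v[ap_stats], tolerance = 0.02)
  expect_lt(v2["head.fftq_ap"], v["head.fftq_ap"] - 5)

  # noiseless periodic trial: MLE ~ 0 on every axis
  tr0 <- generate_trial(noiseless_profile(), seed = 23)
  v0 <- accel_feature_vector(tr0, "pelvis")
  expect_true(all(abs(v0[paste0("pelvis.", c("mle_vertical", "mle_ap",
                                             "mle_ml"))]) < 0.05))
})

test_that("negating the ML axis swaps left/right stats and fixes the rest", {
  tr <- generate_trial(gait_profile(), seed = 29)
  v <- accel_feature_vector(tr, "rshank")
  tr2 <- tr
  tr2$accel$rshank$ml <- -tr$accel$rshank$ml
  v2 <- accel_feature_vector(tr2, "rshank")
  for (s in c("max", "mean", "sd")) {
    expect_equal(v2[[paste0("rshank.right_", s)]],
                 v[[paste0("rshank.left_", s)]])
    expect_equal(v2[[paste0("rshank.left_", s)]],
                 v[[paste0("rshank.right_", s)]])
  }
  inv <- paste0("rshank.", c("fftq_ml", "reoh_ml", "mle_ml",
                             "cadence", "stride_time"))
  expect_equal(v2[inv], v[inv], tolerance = 1e-9)
})
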