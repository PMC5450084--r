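test_that("stance detection matches generator truth within one sample", {
  tr <- generate_trial(noiseless_profile(), seed = 8)
  truth <- attr(tr, "truth")
  for (foot in c("left", "right")) {
    ev <- detect_stance_events(tr$insole[[foot]]$force)
    det_strike <- tr$insole[[foot]]$time[ev$foot_strike]
    det_off <- tr$insole[[foot]]$time[ev$foot_off]
    n <- length(det_strike)
    expect_equal(det_strike, truth[[foot]]$strike[seq_len(n)],
                 tolerance = 1 / 120 + 1e-9)
    expect_equal(det_off, truth[[foot]]$off[seq_len(n)],
                 tolerance = 2 / 120 + 1e-9)
  }
})

test_that("degenerate force series yield no stances", {
  expect_length(detect_stance_events(rep(0, 500))$foot_strike, 0)
  ev <- detect_stance_events(rep(400, 500))  # constant above threshold
  expect_length(ev$stride_time, 0)
  expect_error(detect_stance_events(c(0, NA, 5)), "non-finite")
  expect_error(detect_stance_events(rep(1, 10), threshold = -2), "positive")
})

test_that("impulses match an independent trapezoid oracle on a piecewise-linear stance", {
  # rise 0 -> 700 N over 0.2 s, dip to 500 N, rise to 700 N, fall to 0,
  # each segment 0.2 s; mass 70 kg
  fs <- 120
  seg <- function(from, to) seq(from, to, length.out = 0.2 * fs + 1)[-1]
  f <- c(0, seg(0, 700), seg(700, 500), seg(500, 700), seg(700, 0))
  force <- c(rep(0, 50), f, rep(0, 50), f, rep(0, 50), f, rep(0, 50))
  ev <- detect_stance_events(force, threshold = 10, fs = fs)
  imp <- impulse_features(force, ev, body_mass = 70)

  t <- seq_along(force) / fs
  a <- ev$foot_strike[1]; b <- ev$foot_off[1]
  seg_f <- force[a:b]
  half <- floor(length(seg_f) / 2)
  p1 <- a + which.max(seg_f[1:half]) - 1
  p2 <- a + half + which.max(seg_f[(half + 1):length(seg_f)]) - 1
  vm <- p1 + which.min(force[p1:p2]) - 1
  oracle <- c(
    trapz_oracle(t[a:p1], force[a:p1]),
    trapz_oracle(t[p1:vm], force[p1:vm]),
    trapz_oracle(t[vm:p2], force[vm:p2]),
    trapz_oracle(t[p2:b], force[p2:b])
  ) / 70
  expect_equal(unlist(imp[1, c("i1", "i2", "i3", "i4")]), oracle,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(imp$i7[1], sum(oracle), tolerance = 1e-9)
})

test_that("impulse additivity holds on every synthetic stance", {
  for (seed in c(1, 2, 3)) {
    tr <- generate_trial(gait_profile(), seed = seed)
    for (foot in c("left", "right")) {
      ev <- detect_stance_events(tr$insole[[foot]]$force)
      imp <- impulse_features(tr$insole[[foot]]$force, ev, tr$body_mass)
      expect_equal(imp$i5, imp$i1 + imp$i2, tolerance = 1e-9)
      expect_equal(imp$i6, imp$i3 + imp$i4, tolerance = 1e-9)
      expect_equal(imp$i7, imp$i5 + imp$i6, tolerance = 1e-9)
      expect_true(all(unlist(imp) >= 0))
    }
  }
})

test_that("impulses scale with force and are mass-normalized", {
  tr <- generate_trial(noiseless_profile(), seed = 4)
  f <- tr$insole$left$force
  ev <- detect_stance_events(f)
  base <- impulse_features(f, ev, 70)
  doubled <- impulse_features(2 * f, detect_stance_events(2 * f), 70)
  expect_equal(as.matrix(doubled), 2 * as.matrix(base), tolerance = 1e-6)
  both <- impulse_features(3 * f, detect_stance_events(3 * f), 3 * 70)
  expect_equal(as.matrix(both), as.matrix(base), tolerance = 1e-6)
})

test_that("zero-force stance gives all-zero impulses", {
  ev <- structure(list(foot_strike = 5L, foot_off = 60L, fs = 120,
                       stride_time = numeric(0), stance_time = numeric(0),
                       swing_time = numeric(0)), class = "stride_events")
  imp <- impulse_features(rep(0, 100), ev, 70)
  expect_true(all(unlist(imp) == 0))
  expect_error(impulse_features(rep(0, 100), ev, body_mass = 0), "positive")
})

test_that("CoP deviation features detect injected reversals exactly", {
  fs <- 120
  n <- 120
  ap <- seq(0, 200, length.out = n)
  ml <- rep(0, n)
  ev <- structure(list(foot_strike = 1L, foot_off = n, fs = fs),
                  class = "stride_events")
  clean <- cop_deviation_features(ap, ml, ev)
  expect_equal(clean$pdev_count, 0)
  expect_equal(clean$mldev_count, 0)
  expect_equal(clean$cop_ml_cov, 0)

  # one injected 5-frame backward segment
  ap2 <- ap
  ap2[50:60] <- ap[50] + cumsum(c(0, rep(-2, 5), rep(3, 5)))
  dev <- cop_deviation_features(ap2, ml, ev)
  expect_equal(dev$pdev_count, 1)
  expect_equal(dev$pdev_duration, 5 / fs)
  expect_equal(dev$pdev_length, 10, tolerance = 1e-9)  # 5 frames x 2 mm

  const <- cop_deviation_features(rep(80, n), rep(5, n), ev)
  expect_equal(const$cop_ap_cov, 0)
})

test_that("temporal features recover generator timing", {
  tr <- generate_trial(noiseless_profile(), seed = 6)
  evl <- detect_stance_events(tr$insole$left$force)
  evr <- detect_stance_events(tr$insole$right$force)
  tmp <- temporal_features(evl, evr)
  expect_equal(tmp$stride_time, 1.0, tolerance = 0.01)
  expect_equal(tmp$cadence, 120, tolerance = 2)
  # stance fraction 0.6 less the sub-threshold taper edges
  expect_equal(tmp$pct_stance, 60, tolerance = 2)
  expect_equal(tmp$pct_double_support, 20, tolerance = 2.5)
  expect_equal(tmp$stride_time_symmetry, 0, tolerance = 1e-9)
  expect_equal(tmp$stride_time_cov, 0, tolerance = 1e-9)
  expect_equal(tmp$stance_time_cov, 0, tolerance = 1e-6)
  expect_gt(tmp$pct_stance, 0)
  expect_lt(tmp$pct_stance, 100)
  expect_equal(tmp$stance_time + tmp$swing_time, tmp$stride_time,
               tolerance = 1e-9)
  expect_error(temporal_features(detect_stance_events(rep(0, 100)), evr),
               "2 complete strides")
})

test_that("insole vector has the canonical 30 names and pools limbs symmetrically", {
  nm <- insole_feature_names()
  expect_length(nm, 30)
  expect_false(anyDuplicated(nm) > 0)
  expect_true(all(startsWith(nm, "insole.")))

  tr <- generate_trial(noiseless_profile(), seed = 10)
  v <- insole_feature_vector(tr)
  expect_identical(names(v), nm)
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["insole.stride_time_symmetry"]), 0, tolerance = 1e-9)
  expect_equal(unname(v["insole.stride_time_cov"]), 0, tolerance = 1e-9)

  swapped <- tr
  swapped$insole <- list(left = tr$insole$right, right = tr$insole$left)
  expect_equal(insole_feature_vector(swapped), v, tolerance = 1e-12)
})

test_that("I7 from the full vector equals the per-stride oracle mean", {
  tr <- generate_trial(noiseless_profile(), seed = 12)
  v <- insole_feature_vector(tr)
  t <- tr$insole$left$time
  oracle_foot <- function(foot) {
    ev <- detect_stance_events(tr$insole[[foot]]$force)
    vapply(seq_along(ev$foot_strike), function(i) {
      idx <- ev$foot_strike[i]:ev$foot_off[i]
      trapz_oracle(t[idx], tr$insole[[foot]]$force[idx]) / tr$body_mass
    }, numeric(1))
  }
  expect_equal(unname(v["insole.i7"]),
               mean(c(oracle_foot("left"), oracle_foot("right"))),
               tolerance = 1e-9)
})
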