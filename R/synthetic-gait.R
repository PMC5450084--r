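#' Gait profile for synthetic trial generation
#'
#' A `gait_profile` collects the walking parameters of one (virtual)
#' participant: stride timing, walking speed over the fixed short-walk
#' distance, body mass, faller status, and a set of multiplicative effect
#' parameters through which faller-specific gait changes are injected at the
#' signal-generation level (never on extracted features).
#'
#' @param stride_time_mean Mean stride time in seconds.
#' @param stride_time_sd Inter-participant SD of stride time (seconds); used
#'   by [generate_cohort()] when jittering per-participant profiles.
#' @param walk_distance Walk length in metres (default 7.62 m, i.e. 25 ft).
#' @param gait_speed Walking speed in m/s.
#' @param body_mass Body mass in kg.
#' @param faller Logical faller label (positive class: at least one fall in
#'   the six months before assessment).
#' @param effect_config Named list of positive effect multipliers. Recognised
#'   names: `late_stance_impulse_scale` (scales plantar force in the second
#'   half of stance; values below 1 reduce late-stance impulses I3, I4, I6,
#'   I7) and `posterior_accel_scale` (scales the posterior half-axis of the
#'   head AP acceleration; values above 1 increase posterior acceleration
#'   magnitude).
#' @param stance_fraction Stance time as a fraction of stride time.
#' @param stride_jitter_sd Within-trial stride-to-stride SD (seconds).
#' @param accel_noise_sd Accelerometer white-noise SD in g.
#' @param force_noise_sd Insole force noise SD as a fraction of body weight.
#' @param cop_noise_sd Centre-of-pressure noise SD in mm.
#' @param n_posterior_deviations Number of posterior CoP deviations injected
#'   per stance.
#' @param n_ml_deviations Number of medial-lateral CoP deviations injected
#'   per stance.
#'
#' @return An object of class `gait_profile`.
#' @examples
#' prof <- gait_profile(stride_time_mean = 1.0, gait_speed = 1.27)
#' trial <- generate_trial(prof, seed = 1)
#' @export
gait_profile <- function(stride_time_mean = 1.0,
                         stride_time_sd = 0.05,
                         walk_distance = 7.62,
                         gait_speed = 1.27,
                         body_mass = 72,
                         faller = FALSE,
                         effect_config = list(),
                         stance_fraction = 0.6,
                         stride_jitter_sd = 0.01,
                         accel_noise_sd = 0.02,
                         force_noise_sd = 0.005,
                         cop_noise_sd = 0.3,
                         n_posterior_deviations = 1L,
                         n_ml_deviations = 1L) {
  assert_scalar_pos(stride_time_mean, "stride_time_mean")
  assert_scalar_pos(walk_distance, "walk_distance")
  assert_scalar_pos(gait_speed, "gait_speed")
  assert_scalar_pos(body_mass, "body_mass")
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    stopf("'stance_fraction' must lie strictly between 0 and 1")
  }
  effects <- utils::modifyList(
    list(late_stance_impulse_scale = 1, posterior_accel_scale = 1),
    as.list(effect_config)
  )
  if (any(unlist(effects) <= 0)) stopf("effect multipliers must be > 0")
  structure(
    list(
      stride_time_mean = stride_time_mean,
      stride_time_sd = stride_time_sd,
      walk_distance = walk_distance,
      gait_speed = gait_speed,
      body_mass = body_mass,
      faller = isTRUE(faller),
      effect_config = effects,
      stance_fraction = stance_fraction,
      stride_jitter_sd = stride_jitter_sd,
      accel_noise_sd = accel_noise_sd,
      force_noise_sd = force_noise_sd,
      cop_noise_sd = cop_noise_sd,
      n_posterior_deviations = as.integer(n_posterior_deviations),
      n_ml_deviations = as.integer(n_ml_deviations)
    ),
    class = "gait_profile"
  )
}

#' @export
print.gait_profile <- function(x, ...) {
  cat("<gait_profile>\n")
  cat(sprintf("  stride time : %.3f s (jitter %.3f s)\n",
              x$stride_time_mean, x$stride_jitter_sd))
  cat(sprintf("  walk        : %.2f m at %.2f m/s\n",
              x$walk_distance, x$gait_speed))
  cat(sprintf("  body mass   : %.1f kg, label: %s\n",
              x$body_mass, if (x$faller) "faller" else "non_faller"))
  cat(sprintf("  effects     : %s\n",
              paste(names(x$effect_config), unlist(x$effect_config),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# Bimodal stance-phase vertical force curve on normalised stance phase s in
# [0, 1], in units of body weight. Two smooth bumps (~1.1 and ~1.05 BW) with
# a mid-stance minimum (~0.8 BW), linearly tapered to zero at foot-strike
# and foot-off so threshold crossings are well defined. The late-stance
# impulse effect scales the second half of the curve through a smooth
# logistic transition at mid-stance.
stance_force_shape <- function(s, late_scale = 1) {
  bump1 <- 1.10 * exp(-((s - 0.28) / 0.22)^2)
  bump2 <- 1.05 * exp(-((s - 0.72) / 0.22)^2)
  taper <- pmin(1, s / 0.08) * pmin(1, (1 - s) / 0.08)
  late <- 1 + (late_scale - 1) / (1 + exp(-(s - 0.5) / 0.03))
  (bump1 + bump2) * taper * late
}

# One foot's stance-by-stance CoP trajectories on the insole time grid.
# AP progresses monotonically heel -> toe (0 -> 200 mm); injected posterior
# deviations are runs of `dev_len` frames with negative AP velocity. ML is
# flat at 0 with injected square deviations of +/- 5 mm, short enough that
# an 11-frame running median keeps tracking the baseline.
make_cop_stance <- function(n, n_post, n_ml, dev_len = 5L) {
  v <- rep(200 / max(n - 1, 1), n - 1)
  ml <- rep(0, n)
  n_dev <- n_post + n_ml
  if (n_dev > 0 && n - 1 > (dev_len + 2) * n_dev + 10) {
    # non-overlapping windows in the middle 80% of stance, >= 2 frames apart
    lo <- ceiling(0.1 * n)
    hi <- floor(0.9 * n) - dev_len
    starts <- integer(0)
    pos <- lo:hi
    cand <- pos[sample.int(length(pos), min(50L, length(pos)))]
    for (s0 in cand) {
      if (length(starts) >= n_dev) break
      if (all(abs(s0 - starts) > dev_len + 2L)) starts <- c(starts, s0)
    }
    starts <- sort(starts)
    kinds <- rep(c("post", "ml"), c(n_post, n_ml))[seq_along(starts)]
    kinds <- sample(kinds)
    for (j in seq_along(starts)) {
      idx <- starts[j]:(starts[j] + dev_len - 1L)
      if (kinds[j] == "post") {
        v[idx] <- -1.5 * 200 / (n - 1)
      } else {
        side <- if (runif(1) < 0.5) 1 else -1
        ml[idx + 1L] <- ml[idx + 1L] + side * 5
      }
    }
  }
  list(ap = cumsum(c(0, v)), ml = ml,
       n_post = if (n_dev > 0 && n - 1 > (dev_len + 2) * n_dev + 10) n_post else 0L,
       n_ml = if (n_dev > 0 && n - 1 > (dev_len + 2) * n_dev + 10) n_ml else 0L)
}

# Quasi-periodic tri-axial acceleration: stride-frequency fundamental plus
# harmonics 2..6 with decaying amplitudes; the step frequency (2 f0)
# dominates the vertical axis. Returns a data frame time/vertical/ap/ml.
make_accel_site <- function(t, f0, amp, noise_sd) {
  harmonics <- function(amps) {
    phases <- runif(length(amps), 0, 2 * pi)
    x <- rep(0, length(t))
    for (k in seq_along(amps)) {
      x <- x + amps[k] * cos(2 * pi * k * f0 * t + phases[k])
    }
    x
  }
  vert <- harmonics(amp * c(0.30, 1.00, 0.25, 0.12, 0.06, 0.03))
  ap   <- harmonics(amp * 0.8 * c(1.00, 0.50, 0.25, 0.12, 0.06, 0.03))
  ml   <- harmonics(amp * 0.5 * c(1.00, 0.35, 0.15, 0.08, 0.04, 0.02))
  if (noise_sd > 0) {
    vert <- vert + rnorm(length(t), 0, noise_sd)
    ap   <- ap + rnorm(length(t), 0, noise_sd)
    ml   <- ml + rnorm(length(t), 0, noise_sd)
  }
  data.frame(time = t, vertical = vert, ap = ap, ml = ml)
}

#' Generate one synthetic multi-sensor gait trial
#'
#' Produces one participant's recording of a short straight-line walk:
#' tri-axial accelerometer streams at 50 Hz for four body sites (head,
#' pelvis, left shank, right shank; axes in anatomical convention, vertical +
#' = superior, AP + = anterior, ML + = right) and per-foot pressure-insole
#' streams at 120 Hz (total vertical force in N and CoP coordinates in mm).
#' The generated structure is exactly what the downstream feature extractors
#' assume: alternating left/right stances with bimodal force curves,
#' posterior-to-anterior CoP progression with injected deviations, and
#' harmonic acceleration signals phase-locked to the stride.
#'
#' Ground truth (stance event times, injected deviation counts, stride
#' times) is attached as the `"truth"` attribute for testing.
#'
#' @param profile A [gait_profile()].
#' @param seed Integer seed; trials are byte-identical for a fixed
#'   `(profile, seed)` pair.
#' @return An object of class `sensor_trial`: a list with elements
#'   `participant_id`, `label`, `body_mass`, `accel` (named list of
#'   data frames `time/vertical/ap/ml`, one per site), and `insole` (named
#'   list `left`/`right` of data frames `time/force/cop_ap/cop_ml`).
#' @export
generate_trial <- function(profile, seed = 1L) {
  if (!inherits(profile, "gait_profile")) {
    stopf("'profile' must be a gait_profile object")
  }
  withr::with_seed(as.integer(seed), generate_trial_impl(profile))
}

generate_trial_impl <- function(profile) {
  fs_accel <- 50
  fs_insole <- 120
  duration <- profile$walk_distance / profile$gait_speed
  effects <- profile$effect_config

  # Stance event schedule: left foot leads, right offset by one step.
  schedule_foot <- function(t0) {
    strikes <- numeric(0)
    t <- t0
    repeat {
      if (t > duration - 0.05) break
      strikes <- c(strikes, t)
      dt <- profile$stride_time_mean +
        if (profile$stride_jitter_sd > 0) rnorm(1, 0, profile$stride_jitter_sd) else 0
      t <- t + max(dt, 0.3)
    }
    strides <- diff(c(strikes, t))
    offs <- strikes + profile$stance_fraction * strides
    keep <- offs <= duration
    list(strike = strikes[keep], off = offs[keep])
  }
  ev_left <- schedule_foot(0.2)
  ev_right <- schedule_foot(0.2 + profile$stride_time_mean / 2)

  t_ins <- seq(0, duration, by = 1 / fs_insole)
  bw <- profile$body_mass * 9.81

  build_foot <- function(ev) {
    force <- rep(0, length(t_ins))
    cop_ap <- rep(NA_real_, length(t_ins))
    cop_ml <- rep(NA_real_, length(t_ins))
    truth_dev <- data.frame(n_post = integer(0), n_ml = integer(0))
    for (i in seq_along(ev$strike)) {
      idx <- which(t_ins >= ev$strike[i] & t_ins <= ev$off[i])
      if (length(idx) < 10) next
      s <- (t_ins[idx] - ev$strike[i]) / (ev$off[i] - ev$strike[i])
      f <- bw * stance_force_shape(s, effects$late_stance_impulse_scale)
      if (profile$force_noise_sd > 0) {
        f <- pmax(0, f + rnorm(length(f), 0, profile$force_noise_sd * bw))
      }
      force[idx] <- f
      cop <- make_cop_stance(length(idx),
                             profile$n_posterior_deviations,
                             profile$n_ml_deviations)
      ap <- cop$ap
      ml <- cop$ml
      if (profile$cop_noise_sd > 0) {
        ap <- ap + rnorm(length(ap), 0, profile$cop_noise_sd)
        ml <- ml + rnorm(length(ml), 0, profile$cop_noise_sd)
      }
      cop_ap[idx] <- ap
      cop_ml[idx] <- ml
      truth_dev <- rbind(truth_dev,
                         data.frame(n_post = cop$n_post, n_ml = cop$n_ml))
    }
    list(df = data.frame(time = t_ins, force = force,
                         cop_ap = cop_ap, cop_ml = cop_ml),
         dev = truth_dev)
  }
  left <- build_foot(ev_left)
  right <- build_foot(ev_right)

  t_acc <- seq(0, duration, by = 1 / fs_accel)
  f0 <- 1 / profile$stride_time_mean
  site_amp <- c(head = 0.12, pelvis = 0.20, lshank = 0.35, rshank = 0.35)
  accel <- lapply(names(site_amp), function(site) {
    df <- make_accel_site(t_acc, f0, site_amp[[site]], profile$accel_noise_sd)
    if (site == "head" && effects$posterior_accel_scale != 1) {
      neg <- df$ap < 0
      df$ap[neg] <- df$ap[neg] * effects$posterior_accel_scale
    }
    df
  })
  names(accel) <- names(site_amp)

  structure(
    list(
      participant_id = NA_character_,
      label = if (profile$faller) "faller" else "non_faller",
      body_mass = profile$body_mass,
      accel = accel,
      insole = list(left = left$df, right = right$df)
    ),
    truth = list(
      left = ev_left, right = ev_right,
      stride_time = profile$stride_time_mean,
      stance_fraction = profile$stance_fraction,
      f0 = f0,
      deviations = list(left = left$dev, right = right$dev)
    ),
    class = "sensor_trial"
  )
}

#' @export
print.sensor_trial <- function(x, ...) {
  cat("<sensor_trial>", x$participant_id, sprintf("(%s)\n", x$label))
  cat(sprintf("  accel sites : %s @50 Hz\n", paste(names(x$accel), collapse = ", ")))
  cat(sprintf("  insole      : %s @120 Hz, mass %.1f kg\n",
              paste(names(x$insole), collapse = ", "), x$body_mass))
  invisible(x)
}

#' Generate a synthetic cohort of gait trials
#'
#' Builds `n_fallers + n_nonfallers` trials from a base profile.
#' Per-participant stride time, gait speed and body mass are jittered by
#' inter-participant SDs; faller trials have the effect multipliers in
#' `effect_config` applied at the generator level, non-faller trials use
#' identity effects. Reproducible from a single master seed; per-participant
#' sub-seeds are derived deterministically from the participant index.
#'
#' @param n_fallers,n_nonfallers Non-negative participant counts (the study
#'   cohort analogue is 24 fallers and 76 non-fallers).
#' @param base_profile A [gait_profile()] supplying shared defaults.
#' @param effect_config Effect multipliers applied to faller trials only.
#' @param seed Master integer seed.
#' @return A list of [generate_trial()] results with `participant_id` set
#'   (`P001`, `P002`, ...), fallers first.
#' @export
generate_cohort <- function(n_fallers, n_nonfallers,
                            base_profile = gait_profile(),
                            effect_config = list(
                              late_stance_impulse_scale = 0.85,
                              posterior_accel_scale = 1.25
                            ),
                            seed = 1L) {
  if (n_fallers < 0 || n_nonfallers < 0) stopf("counts must be >= 0")
  n <- n_fallers + n_nonfallers
  if (n == 0) return(list())
  jitter <- withr::with_seed(as.integer(seed), {
    data.frame(
      stride = rnorm(n, 0, base_profile$stride_time_sd),
      speed = rnorm(n, 0, 0.05 * base_profile$gait_speed),
      mass = rnorm(n, 0, 0.1 * base_profile$body_mass)
    )
  })
  lapply(seq_len(n), function(i) {
    is_faller <- i <= n_fallers
    prof <- base_profile
    prof$stride_time_mean <- max(0.5, prof$stride_time_mean + jitter$stride[i])
    prof$gait_speed <- max(0.5, prof$gait_speed + jitter$speed[i])
    prof$body_mass <- max(40, prof$body_mass + jitter$mass[i])
    prof$faller <- is_faller
    if (is_faller) {
      prof$effect_config <- utils::modifyList(prof$effect_config,
                                              as.list(effect_config))
    }
    trial <- generate_trial(prof, seed = derive_seed(seed, i))
    trial$participant_id <- sprintf("P%03d", i)
    trial
  })
}

#' Write / read a cohort as delimited text files
#'
#' One CSV per sensor per participant (`<id>_accel_<site>.csv` with columns
#' `time,vertical,ap,ml`; `<id>_insole_<foot>.csv` with columns
#' `time,force,cop_ap,cop_ml`) plus a cohort `manifest.csv` holding
#' participant id, label, body mass and relative file paths.
#'
#' @param trials List of `sensor_trial` objects.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` invisibly returns the manifest path;
#'   `read_cohort` returns the list of trials.
#' @export
write_cohort <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(trials, function(tr) {
    id <- tr$participant_id
    files <- c()
    for (site in names(tr$accel)) {
      fn <- sprintf("%s_accel_%s.csv", id, site)
      write.csv(tr$accel[[site]], file.path(dir, fn), row.names = FALSE)
      files[paste0("accel_", site)] <- fn
    }
    for (foot in names(tr$insole)) {
      fn <- sprintf("%s_insole_%s.csv", id, foot)
      write.csv(tr$insole[[foot]], file.path(dir, fn), row.names = FALSE)
      files[paste0("insole_", foot)] <- fn
    }
    c(participant_id = id, label = tr$label,
      body_mass = as.character(tr$body_mass), files)
  })
  manifest <- do.call(rbind, lapply(rows, function(r) as.data.frame(as.list(r))))
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param manifest_path Path to a cohort `manifest.csv`.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    accel_cols <- grep("^accel_", names(row), value = TRUE)
    insole_cols <- grep("^insole_", names(row), value = TRUE)
    accel <- lapply(accel_cols, function(cn) {
      if (is.na(row[[cn]]) || row[[cn]] == "") return(NULL)
      read.csv(file.path(dir, row[[cn]]))
    })
    names(accel) <- sub("^accel_", "", accel_cols)
    accel <- Filter(Negate(is.null), accel)
    insole <- lapply(insole_cols, function(cn) read.csv(file.path(dir, row[[cn]])))
    names(insole) <- sub("^insole_", "", insole_cols)
    structure(
      list(participant_id = row$participant_id, label = row$label,
           body_mass = as.numeric(row$body_mass),
           accel = accel, insole = insole),
      class = "sensor_trial"
    )
  })
}
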