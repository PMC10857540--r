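# Synthetic-data generators for the 10-task clinical battery.
#
# Signals are piecewise-scripted deterministic motifs (Gaussian angular-
# velocity lobes for postural transitions, narrow Gaussian impact bumps for
# gait events) plus filtered-noise postural sway and additive white sensor
# noise, so every downstream detector has an unambiguous ground truth.

# --- generator constants (the study conditions emulated) ------------------

BASE_SWAY_THORAX <- c(a1 = 0.030, a2 = 0.025, a3 = 0.015)  # m/s^2
SWAY_SENSOR_FACTOR <- c(thorax = 1, pelvis = 0.8, thigh_L = 0.5, thigh_R = 0.5)
CLOSED_EYES_MULT <- 1.4

BASE_STRIDE_S   <- 1.1    # nominal stride time, s
STRIDE_SD_S     <- 0.04   # stride-to-stride variability, s
STRIDE_LENGTH_M <- 1.15   # constant stride length, m
SWING_FRAC      <- 0.35   # swing = TO -> next HS, fraction of stride
SIGMA_IMPACT_S  <- 0.025  # impact bump width, s
HS_AMP <- c(a1 = 1.5, a3 = 2.5)  # m/s^2, heel-strike bump per axis
TO_AMP <- c(a1 = 0.5, a3 = 1.0)  # m/s^2, toe-off bump per axis
FOOT_AMP_FACTOR <- 1.2           # feet see slightly larger impacts than shanks

TUG_SIT_QUIET_S <- 1.0
TUG_STS_S       <- 1.4   # sit-to-stand duration, nominal
TUG_TURN_S      <- 1.8
TUG_TURNSIT_S   <- 2.2
TUG_WALK_LEAD_S <- 0.35  # first heel strike after phase start
TUG_WALK_M      <- 3

STS_LEAD_S  <- 1.0
STS_UP_S    <- 1.1
STS_DOWN_S  <- 1.2
STS_STAND_S <- 0.4
STS_SIT_S   <- 0.8
THIGH_LOBE_AMP  <- 85  # deg/s
THORAX_LOBE_AMP <- 45
PELVIS_LOBE_AMP <- 30

C10 <- sqrt(2 * log(10))  # Gaussian 10%-of-peak half-width, in sigmas

# --- small helpers --------------------------------------------------------

# Trial-to-trial performance variability (lognormal SD of the difficulty
# scale per trial). Without it the groups would be perfectly separable on
# sway for any plausible latent-mobility spread; with it they are separable
# but overlapping, as in real cohorts. Magnitudes follow typical
# test-retest variability: postural sway amplitude ~15% CV, transition
# times ~7%, stride time ~5%.
TRIAL_CV_SWAY       <- 0.15
TRIAL_CV_TRANSITION <- 0.07
TRIAL_CV_STRIDE     <- 0.05

# Per-subject difficulty multipliers given group, dual condition and the
# latent mobility factor (difficulty = 1 / latent_mobility >= 1), with a
# per-trial lognormal jitter drawn from the current RNG stream. Because
# every simulator seeds its stream before calling this, same-seed
# comparisons (faller vs nonfaller, dual vs single) share the jitter draw
# and remain strictly monotone in the effect multipliers.
movement_scales <- function(profile, effect, dual) {
  faller <- identical(profile$group, "faller")
  dc <- if (isTRUE(dual)) {
    if (faller) effect$dual_task_cost_faller else effect$dual_task_cost_nonfaller
  } else 1
  diffic <- 1 / profile$latent_mobility
  jit <- exp(rnorm(3, 0, c(TRIAL_CV_SWAY, TRIAL_CV_TRANSITION, TRIAL_CV_STRIDE)))
  list(
    sway        = (if (faller) effect$sway_std_faller else 1) * dc * diffic * jit[1],
    transition  = (if (faller) effect$transition_time_faller else 1) * dc * diffic * jit[2],
    stride_time = (if (faller) 1 / effect$gait_speed_faller else 1) * dc * diffic * jit[3]
  )
}

# Add amp * exp(-(t - center)^2 / (2 sigma^2)) to x over a +/-5 sigma window.
add_bump <- function(x, fs, center, amp, sigma) {
  n <- length(x)
  i0 <- max(1L, floor((center - 5 * sigma) * fs) + 1L)
  i1 <- min(n, ceiling((center + 5 * sigma) * fs) + 1L)
  if (i0 > n || i1 < 1L) return(x)
  idx <- i0:i1
  t <- (idx - 1) / fs
  x[idx] <- x[idx] + amp * exp(-(t - center)^2 / (2 * sigma^2))
  x
}

# Add a Gaussian lobe whose 10%-of-peak crossings fall at onset/offset.
add_lobe <- function(x, fs, onset, offset, amp) {
  center <- (onset + offset) / 2
  sigma <- (offset - onset) / (2 * C10)
  add_bump(x, fs, center, amp, sigma)
}

# Band-limited unit-variance sway carriers: white noise through a 1 Hz
# low-pass shaping filter, each column rescaled to population SD exactly 1.
sway_carrier <- function(n, fs, k = 1) {
  s <- lowpass_mat(matrix(rnorm(n * k), n, k),
                   filter_spec(cutoff_hz = 1, order = 2, fs_hz = fs))
  s <- sweep(s, 2, colMeans(s))
  sweep(s, 2, sqrt(colMeans(s^2)), "/")
}

new_annotation <- function(trial, true_events = list(), true_params = list()) {
  structure(
    list(subject_id = trial$subject_id, task_id = trial$task_id,
         duration_s = trial$n / trial$fs_hz,
         true_events = true_events, true_params = true_params),
    class = "trial_annotation"
  )
}

jitter_mult <- function(n = 1, sd = 0.05) pmax(0.5, 1 + rnorm(n, 0, sd))

# --- balance --------------------------------------------------------------

#' Simulate a quiet-standing balance trial
#'
#' Thorax, pelvis and both thigh acceleration channels carry zero-mean
#' band-limited stochastic sway plus white sensor noise. The target sway SD
#' per axis is `base x group multiplier x closed-eyes multiplier (if eyes
#' closed) x dual-task multiplier (if dual) / latent mobility`; the
#' annotation records the target SD per axis and sensor.
#'
#' @param profile One-row subject profile (see [draw_subject_profiles()]).
#' @param eyes `"open"` or `"closed"`.
#' @param dual Dual-task (counting-backward) condition?
#' @param duration_s Trial duration in seconds (default 30).
#' @param seed Integer seed.
#' @param effect An [effect_profile()].
#' @param noise_level Sensor-noise SD.
#' @param fs_hz Sampling rate.
#'
#' @return A list with elements `trial` (a `trial_recording`) and
#'   `annotation` (a `trial_annotation`).
#' @export
simulate_balance <- function(profile, eyes = c("open", "closed"), dual = FALSE,
                             duration_s = 30, seed = 1,
                             effect = effect_profile(), noise_level = 0.02,
                             fs_hz = 60) {
  eyes <- match.arg(eyes)
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  withr::with_seed(seed, {
    n <- round(duration_s * fs_hz)
    task <- if (eyes == "open") "BAL_EO" else "BAL_CE"
    trial <- new_trial_recording(profile$subject_id, task, dual, fs_hz, n, noise_level)
    sc <- movement_scales(profile, effect, dual)
    ce <- if (eyes == "closed") CLOSED_EYES_MULT else 1
    targets <- list()
    for (sensor in names(SWAY_SENSOR_FACTOR)) {
      tgt <- BASE_SWAY_THORAX * SWAY_SENSOR_FACTOR[[sensor]] * sc$sway * ce
      sway <- sweep(sway_carrier(n, fs_hz, 3), 2, tgt, "*")
      trial$sensors[[sensor]]$linear_acceleration <-
        trial$sensors[[sensor]]$linear_acceleration + sway
      targets[[sensor]] <- tgt
    }
    ann <- new_annotation(trial,
                          true_events = list(),
                          true_params = list(sway_std = targets, eyes = eyes,
                                             dual = isTRUE(dual)))
    list(trial = trial, annotation = ann)
  })
}

# --- gait engine ----------------------------------------------------------

# Draw per-foot heel-strike / toe-off truth for n_strides strides starting
# at t0. Left and right feet alternate with a half-stride offset; toe-off
# precedes the next ipsilateral heel strike by SWING_FRAC of the stride.
draw_gait_truth <- function(n_strides, stride_mean, t0) {
  strides <- pmax(0.4 * stride_mean, rnorm(n_strides, stride_mean, STRIDE_SD_S))
  hs_L <- t0 + cumsum(c(0, strides[-n_strides]))
  hs_R <- hs_L + strides / 2
  to_L <- hs_L + (1 - SWING_FRAC) * strides
  to_R <- hs_R + (1 - SWING_FRAC) * strides
  list(hs = list(foot_L = hs_L, foot_R = hs_R),
       to = list(foot_L = to_L, foot_R = to_R),
       strides = strides)
}

# Overlay heel-strike / toe-off impact bumps on the foot and shank
# acceleration channels of a trial.
add_gait_bumps <- function(trial, truth) {
  fs <- trial$fs_hz
  for (side in c("L", "R")) {
    foot <- paste0("foot_", side); shank <- paste0("shank_", side)
    for (sensor in c(foot, shank)) {
      fac <- if (sensor == foot) FOOT_AMP_FACTOR else 1
      acc <- trial$sensors[[sensor]]$linear_acceleration
      for (te in truth$hs[[foot]]) {
        acc[, "a1"] <- add_bump(acc[, "a1"], fs, te, fac * HS_AMP[["a1"]], SIGMA_IMPACT_S)
        acc[, "a3"] <- add_bump(acc[, "a3"], fs, te, fac * HS_AMP[["a3"]], SIGMA_IMPACT_S)
      }
      for (te in truth$to[[foot]]) {
        acc[, "a1"] <- add_bump(acc[, "a1"], fs, te, fac * TO_AMP[["a1"]], SIGMA_IMPACT_S)
        acc[, "a3"] <- add_bump(acc[, "a3"], fs, te, fac * TO_AMP[["a3"]], SIGMA_IMPACT_S)
      }
      trial$sensors[[sensor]]$linear_acceleration <- acc
    }
  }
  trial
}

#' Simulate a free gait stream
#'
#' Generates `n_strides` strides of walking: per-foot heel-strike (HS) and
#' toe-off (TO) truth, and foot/shank channel blocks whose resultant
#' acceleration shows one dominant impact bump at each HS and a smaller one
#' at each TO. Stride times are i.i.d. normal (truncated positive) with a
#' mean scaled by the group gait-speed and dual-task multipliers.
#'
#' @inheritParams simulate_balance
#' @param n_strides Number of strides per foot (>= 1).
#'
#' @return A list: `sensors` (foot/shank channel blocks), `truth` (HS/TO
#'   lists per foot), `params` (stride times, mean stride, cadence in
#'   steps/min), `fs_hz`, `n`.
#' @export
simulate_gait_stream <- function(profile, n_strides, dual = FALSE, seed = 1,
                                 effect = effect_profile(), noise_level = 0.02,
                                 fs_hz = 60) {
  if (n_strides < 1) abort("`n_strides` must be >= 1.")
  withr::with_seed(seed, {
    sc <- movement_scales(profile, effect, dual)
    stride_mean <- BASE_STRIDE_S * sc$stride_time
    truth <- draw_gait_truth(n_strides, stride_mean, t0 = 0.4)
    dur <- max(unlist(truth$to)) + 0.5
    n <- ceiling(dur * fs_hz)
    trial <- new_trial_recording(profile$subject_id, "GAIT", dual, fs_hz, n, noise_level)
    trial <- add_gait_bumps(trial, truth)
    blocks <- trial$sensors[c("foot_L", "foot_R", "shank_L", "shank_R")]
    mean_stride <- mean(truth$strides)
    list(sensors = blocks,
         truth = truth[c("hs", "to")],
         params = list(strides = truth$strides, mean_stride = mean_stride,
                       cadence_spm = 120 / mean_stride,
                       stride_length_m = STRIDE_LENGTH_M),
         fs_hz = fs_hz, n = n)
  })
}

# --- 10 m walk ------------------------------------------------------------

#' Simulate a 10 m walk test trial
#'
#' A straight 10 m walk without a turn: the stride count is
#' `ceiling(10 / stride length)` and the gait stream is embedded into a full
#' 8-sensor recording. The annotation carries HS/TO truth and the
#' truth-derived spatiotemporal parameters (walk time, cadence, stride,
#' swing, single support).
#'
#' @inheritParams simulate_balance
#' @return A list with `trial` and `annotation`.
#' @export
simulate_10mwt <- function(profile, dual = FALSE, seed = 1,
                           effect = effect_profile(), noise_level = 0.02,
                           fs_hz = 60) {
  withr::with_seed(seed, {
    sc <- movement_scales(profile, effect, dual)
    stride_mean <- BASE_STRIDE_S * sc$stride_time
    n_strides <- ceiling(10 / STRIDE_LENGTH_M)
    truth <- draw_gait_truth(n_strides, stride_mean, t0 = 0.4)
    ev <- unlist(c(truth$hs, truth$to))
    n <- ceiling((max(ev) + 0.5) * fs_hz)
    trial <- new_trial_recording(profile$subject_id, "MWT10", dual, fs_hz, n, noise_level)
    trial <- add_gait_bumps(trial, truth)
    walk_time <- max(ev) - min(ev)
    swings <- SWING_FRAC * truth$strides
    ann <- new_annotation(trial,
      true_events = list(hs = truth$hs, to = truth$to),
      true_params = list(
        strides = truth$strides, mean_stride = mean(truth$strides),
        cadence_spm = 60 * 2 * n_strides / walk_time,
        walk_time = walk_time, swing = swings,
        gait_speed = 10 / walk_time, n_strides = n_strides))
    list(trial = trial, annotation = ann)
  })
}

# --- timed up and go ------------------------------------------------------

#' Simulate a timed-up-and-go (TUG) trial
#'
#' Scripted as quiet sit, sit-to-stand (thorax pitch angular-velocity lobe),
#' 3 m walk to the cone, turn (thorax yaw lobe), walk back, and turn-and-sit
#' (yaw lobe followed by a reversed pitch lobe). The annotation carries the
#' six boundary times t1..t6 (t1 = sit-to-stand onset, t2 = first heel
#' strike out, t3 = turn start, t4 = first heel strike back, t5 =
#' turn-and-sit start, t6 = task end), the five phase durations, and HS/TO
#' truth per foot. All durations scale with the group and dual multipliers.
#'
#' @inheritParams simulate_balance
#' @param turn_scale Extra multiplier on the mid-task turn duration
#'   (useful for sensitivity checks).
#' @return A list with `trial` and `annotation`.
#' @export
simulate_tug <- function(profile, dual = FALSE, seed = 1,
                         effect = effect_profile(), noise_level = 0.02,
                         fs_hz = 60, turn_scale = 1) {
  withr::with_seed(seed, {
    sc <- movement_scales(profile, effect, dual)
    stride_mean <- BASE_STRIDE_S * sc$stride_time
    n_w <- ceiling(TUG_WALK_M / STRIDE_LENGTH_M)

    d1 <- TUG_STS_S * sc$transition * jitter_mult()
    t1 <- TUG_SIT_QUIET_S
    walk1 <- draw_gait_truth(n_w, stride_mean, t0 = t1 + d1 + TUG_WALK_LEAD_S)
    t2 <- walk1$hs$foot_L[1]
    t3 <- t2 + sum(walk1$strides)
    d3 <- TUG_TURN_S * turn_scale * sc$transition * jitter_mult()
    walk2 <- draw_gait_truth(n_w, stride_mean, t0 = t3 + d3 + TUG_WALK_LEAD_S)
    t4 <- walk2$hs$foot_L[1]
    t5 <- t4 + sum(walk2$strides)
    d5 <- TUG_TURNSIT_S * sc$transition * jitter_mult()
    t6 <- t5 + d5

    n <- ceiling((t6 + 1.0) * fs_hz)
    trial <- new_trial_recording(profile$subject_id, "TUG", dual, fs_hz, n, noise_level)
    trial <- add_gait_bumps(trial, walk1)
    trial <- add_gait_bumps(trial, walk2)

    av <- trial$sensors$thorax$angular_velocity
    av[, "a2"] <- add_lobe(av[, "a2"], fs_hz, t1, t1 + d1, 55)            # rise
    av[, "a3"] <- add_lobe(av[, "a3"], fs_hz, t3, t3 + d3, 70)            # turn
    av[, "a3"] <- add_lobe(av[, "a3"], fs_hz, t5, t5 + 0.55 * d5, 60)     # turn before sit
    av[, "a2"] <- add_lobe(av[, "a2"], fs_hz, t5 + 0.45 * d5, t6, -50)    # sit down
    trial$sensors$thorax$angular_velocity <- av

    hs <- map(c(foot_L = "foot_L", foot_R = "foot_R"),
              function(f) sort(c(walk1$hs[[f]], walk2$hs[[f]])))
    to <- map(c(foot_L = "foot_L", foot_R = "foot_R"),
              function(f) sort(c(walk1$to[[f]], walk2$to[[f]])))
    boundaries <- c(t1 = t1, t2 = t2, t3 = t3, t4 = t4, t5 = t5, t6 = t6)
    ann <- new_annotation(trial,
      true_events = list(boundaries = boundaries, hs = hs, to = to),
      true_params = list(
        phase_durations = diff(boundaries),
        total_time = t6 - t1,
        steps_walk1 = sum(unlist(hs) >= t2 & unlist(hs) < t3),
        steps_walk2 = sum(unlist(hs) >= t4 & unlist(hs) < t5)))
    list(trial = trial, annotation = ann)
  })
}

# --- five-repetition sit-to-stand ----------------------------------------

#' Simulate a five-repetition sit-to-stand (STS) trial
#'
#' Thigh angular-velocity channels show one convex lobe per sit-to-stand
#' transition and one (reversed) per stand-to-sit, separated by quiet gaps;
#' thorax and pelvis lobes co-occur with scaled amplitude. The annotation
#' lists per-cycle boundary quadruples (start, sit-to-stand end,
#' stand-to-sit start, end) and the per-cycle peak thorax/pelvis angular
#' velocities.
#'
#' @inheritParams simulate_balance
#' @param n_cycles Number of sit-stand-sit repetitions (default 5).
#' @return A list with `trial` and `annotation`.
#' @export
simulate_sts <- function(profile, dual = FALSE, seed = 1,
                         effect = effect_profile(), noise_level = 0.02,
                         fs_hz = 60, n_cycles = 5) {
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  withr::with_seed(seed, {
    sc <- movement_scales(profile, effect, dual)
    d_up <- STS_UP_S * sc$transition * jitter_mult(n_cycles, 0.06)
    d_down <- STS_DOWN_S * sc$transition * jitter_mult(n_cycles, 0.06)
    gap_stand <- STS_STAND_S * jitter_mult(n_cycles, 0.05)
    gap_sit <- STS_SIT_S * jitter_mult(n_cycles, 0.05)
    thorax_amp <- THORAX_LOBE_AMP * jitter_mult(n_cycles, 0.05)
    pelvis_amp <- PELVIS_LOBE_AMP * jitter_mult(n_cycles, 0.05)

    start <- numeric(n_cycles); up_end <- numeric(n_cycles)
    down_start <- numeric(n_cycles); cend <- numeric(n_cycles)
    t <- STS_LEAD_S
    for (i in seq_len(n_cycles)) {
      start[i] <- t
      up_end[i] <- t + d_up[i]
      down_start[i] <- up_end[i] + gap_stand[i]
      cend[i] <- down_start[i] + d_down[i]
      t <- cend[i] + gap_sit[i]
    }
    n <- ceiling((cend[n_cycles] + 1.0) * fs_hz)
    trial <- new_trial_recording(profile$subject_id, "STS", dual, fs_hz, n, noise_level)

    overlay <- function(av, amp_up, amp_down) {
      for (i in seq_len(n_cycles)) {
        av[, "a2"] <- add_lobe(av[, "a2"], fs_hz, start[i], up_end[i], amp_up[i])
        av[, "a2"] <- add_lobe(av[, "a2"], fs_hz, down_start[i], cend[i], -amp_down[i])
      }
      av
    }
    amp_thigh <- rep(THIGH_LOBE_AMP, n_cycles)
    trial$sensors$thigh_L$angular_velocity <-
      overlay(trial$sensors$thigh_L$angular_velocity, amp_thigh, amp_thigh)
    trial$sensors$thigh_R$angular_velocity <-
      overlay(trial$sensors$thigh_R$angular_velocity, 0.95 * amp_thigh, 0.95 * amp_thigh)
    trial$sensors$thorax$angular_velocity <-
      overlay(trial$sensors$thorax$angular_velocity, thorax_amp, thorax_amp)
    trial$sensors$pelvis$angular_velocity <-
      overlay(trial$sensors$pelvis$angular_velocity, pelvis_amp, pelvis_amp)

    cycles <- tibble(start = start, sit_to_stand_end = up_end,
                     stand_to_sit_start = down_start, end = cend)
    ann <- new_annotation(trial,
      true_events = list(cycles = cycles),
      true_params = list(
        n_cycles = n_cycles,
        cycle_durations = cend - start,
        sit_to_stand = d_up, stand_to_sit = d_down,
        thorax_peak = thorax_amp, pelvis_peak = pelvis_amp))
    list(trial = trial, annotation = ann)
  })
}

# --- whole cohort ---------------------------------------------------------

#' Generate a full synthetic cohort
#'
#' Draws subject profiles, then simulates the complete 10-task battery
#' (balance eyes open/closed, TUG, 10 m walk, five-repetition STS, each
#' single- and dual-task) for every subject, with one ground-truth
#' annotation per trial. Identical specs (including seed) give identical
#' cohorts.
#'
#' @param spec A [cohort_spec()].
#'
#' @return A `fall_cohort` object: a list with `spec`, `profiles`,
#'   `trials` (named list of `trial_recording`s, names
#'   `<subject>_<task>_<single|dual>`), `annotations` (parallel list) and
#'   `clinical_table` (one row per subject, `label` = 1 for fallers).
#' @export
#' @examples
#' co <- generate_cohort(cohort_spec(n_fallers = 1, n_nonfallers = 1, seed = 3))
#' length(co$trials)  # 2 subjects x 10 tasks
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_subj <- spec$n_fallers + spec$n_nonfallers
  variants <- task_variants()
  seeds <- withr::with_seed(spec$seed, {
    profiles <- draw_subject_profiles(spec)
    list(profiles = profiles,
         seeds = matrix(sample.int(2147483646L, n_subj * length(variants)),
                        nrow = n_subj))
  })
  profiles <- seeds$profiles
  seed_mat <- seeds$seeds

  trials <- list(); annotations <- list()
  for (i in seq_len(n_subj)) {
    prof <- as.list(profiles[i, ])
    for (k in seq_along(variants)) {
      v <- variants[k]
      task <- sub("_(single|dual)$", "", v)
      dual <- grepl("_dual$", v)
      s <- seed_mat[i, k]
      sim <- switch(task,
        BAL_EO = simulate_balance(prof, "open", dual, seed = s,
                                  effect = spec$effect_profile,
                                  noise_level = spec$noise_level, fs_hz = spec$fs_hz),
        BAL_CE = simulate_balance(prof, "closed", dual, seed = s,
                                  effect = spec$effect_profile,
                                  noise_level = spec$noise_level, fs_hz = spec$fs_hz),
        TUG = simulate_tug(prof, dual, seed = s, effect = spec$effect_profile,
                           noise_level = spec$noise_level, fs_hz = spec$fs_hz),
        MWT10 = simulate_10mwt(prof, dual, seed = s, effect = spec$effect_profile,
                               noise_level = spec$noise_level, fs_hz = spec$fs_hz),
        STS = simulate_sts(prof, dual, seed = s, effect = spec$effect_profile,
                           noise_level = spec$noise_level, fs_hz = spec$fs_hz))
      key <- paste0(prof$subject_id, "_", v)
      trials[[key]] <- sim$trial
      annotations[[key]] <- sim$annotation
    }
  }
  clinical <- profiles |>
    mutate(label = as.integer(.data$group == "faller"))
  structure(
    list(spec = spec, profiles = profiles, trials = trials,
         annotations = annotations, clinical_table = clinical),
    class = "fall_cohort"
  )
}

#' @export
print.fall_cohort <- function(x, ...) {
  cat(sprintf("<fall_cohort> %d fallers + %d non-fallers, %d trials @ %g Hz\n",
              x$spec$n_fallers, x$spec$n_nonfallers, length(x$trials), x$spec$fs_hz))
  invisible(x)
}
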