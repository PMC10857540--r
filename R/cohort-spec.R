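#' Faller / non-faller effect-size profile
#'
#' Multipliers applied to the generator's base movement parameters. They
#' encode the study conditions the cohort generator emulates: fallers sway
#' more, walk slower and transition more slowly, and pay a larger
#' motor-cognitive dual-task cost than non-fallers. All multipliers act on
#' the *difficulty* scale (a gait-speed multiplier of 0.8 slows stride time
#' by 1/0.8).
#'
#' @param sway_std_faller Multiplier on postural sway standard deviation for
#'   fallers (default 1.5).
#' @param gait_speed_faller Multiplier on gait speed for fallers (default
#'   0.8, i.e. 20% slower).
#' @param transition_time_faller Multiplier on postural-transition durations
#'   (sit-to-stand, turns) for fallers (default 1.3).
#' @param dual_task_cost_faller Multiplier applied to faller parameters in
#'   dual-task trials (default 1.2).
#' @param dual_task_cost_nonfaller Same for non-fallers (default 1.05).
#'
#' @return A named list of positive multipliers.
#' @export
effect_profile <- function(sway_std_faller = 1.5,
                           gait_speed_faller = 0.8,
                           transition_time_faller = 1.3,
                           dual_task_cost_faller = 1.2,
                           dual_task_cost_nonfaller = 1.05) {
  out <- list(
    sway_std_faller = sway_std_faller,
    gait_speed_faller = gait_speed_faller,
    transition_time_faller = transition_time_faller,
    dual_task_cost_faller = dual_task_cost_faller,
    dual_task_cost_nonfaller = dual_task_cost_nonfaller
  )
  bad <- names(out)[!map_lgl(out, function(v) is.numeric(v) && length(v) == 1 && v > 0)]
  if (length(bad)) {
    abort(sprintf("Invalid effect_profile field(s): %s (must be positive scalars).",
                  paste(bad, collapse = ", ")))
  }
  out
}

#' Cohort specification for the synthetic-data generator
#'
#' Describes a cohort of stroke survivors to simulate: group sizes, sampling
#' rate, random seed, effect-size profile and sensor-noise level. The
#' default cohort mirrors the study conditions: 11 fallers and 10
#' non-fallers recorded at 60 Hz.
#'
#' @param n_fallers,n_nonfallers Non-negative group sizes
#'   (`n_fallers + n_nonfallers >= 1`; modeling requires >= 2 and both
#'   classes present).
#' @param fs_hz Sampling rate in Hz (default 60). Must exceed twice the
#'   5 Hz filter cut-off.
#' @param seed Integer seed; identical specs yield identical cohorts.
#' @param effect_profile See [effect_profile()].
#' @param noise_level Additive white sensor-noise standard deviation, in
#'   m/s^2 for acceleration channels and deg/s for angular velocity
#'   (default 0.02).
#'
#' @return A `cohort_spec` object.
#' @export
#' @examples
#' spec <- cohort_spec(n_fallers = 2, n_nonfallers = 2, seed = 7)
cohort_spec <- function(n_fallers = 11, n_nonfallers = 10, fs_hz = 60,
                        seed = 1, effect_profile = fallrisk::effect_profile(),
                        noise_level = 0.02) {
  if (!is.numeric(n_fallers) || n_fallers < 0 || n_fallers != round(n_fallers)) {
    abort("Invalid cohort_spec field `n_fallers`: must be a non-negative integer.")
  }
  if (!is.numeric(n_nonfallers) || n_nonfallers < 0 || n_nonfallers != round(n_nonfallers)) {
    abort("Invalid cohort_spec field `n_nonfallers`: must be a non-negative integer.")
  }
  if (n_fallers + n_nonfallers < 1) {
    abort("Invalid cohort_spec: `n_fallers` + `n_nonfallers` must be >= 1.")
  }
  if (!is.numeric(fs_hz) || fs_hz <= 2 * 5) {
    abort("Invalid cohort_spec field `fs_hz`: must exceed twice the 5 Hz filter cut-off.")
  }
  if (!is.numeric(noise_level) || noise_level < 0) {
    abort("Invalid cohort_spec field `noise_level`: must be non-negative.")
  }
  ep <- do.call(fallrisk::effect_profile, effect_profile)  # re-validate fields
  structure(
    list(n_fallers = as.integer(n_fallers),
         n_nonfallers = as.integer(n_nonfallers),
         fs_hz = fs_hz, seed = as.integer(seed),
         effect_profile = ep, noise_level = noise_level),
    class = "cohort_spec"
  )
}

# Group-level sampling parameters for the clinical/demographic table.
# Means/SDs and item proportions follow the cohort statistics the
# generator is asked to emulate (faller vs non-faller rows).
clinical_targets <- list(
  faller = list(
    p_female = 7 / 11, age = c(64.1, 12.3), height = c(172.7, 8.0),
    weight = c(84.0, 13.3), fes = c(13.1, 5.1),
    p_items = c(feel_unsteady = 9 / 11, worried_when_walking = 7 / 11,
                joint_pain = 8 / 11, poor_vision = 1 / 11,
                joint_replacement = 3 / 11),
    p_comorbid = 0.20
  ),
  nonfaller = list(
    p_female = 3 / 10, age = c(67.6, 7.1), height = c(175.0, 9.1),
    weight = c(90.8, 16.2), fes = c(9.1, 3.0),
    p_items = c(feel_unsteady = 6 / 10, worried_when_walking = 3 / 10,
                joint_pain = 6 / 10, poor_vision = 1 / 10,
                joint_replacement = 3 / 10),
    p_comorbid = 0.15
  )
)

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Draw subject profiles for a cohort
#'
#' Samples the per-subject clinical/demographic table: gender, age, height,
#' weight (BMI computed from them), five binary questionnaire items, number
#' of neurological comorbidities, the short FES-I fear-of-falling score
#' (range 7-28; rounded truncated normal per group), and a latent mobility
#' factor in (0, 1] that scales all task-difficulty draws (1 = best
#' mobility).
#'
#' Meant to be called inside a seeded context; [generate_cohort()] does so.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject.
#' @export
draw_subject_profiles <- function(spec) {
  draw_group <- function(n, group) {
    if (n == 0) return(NULL)
    tg <- clinical_targets[[group]]
    height <- rnorm_trunc(n, tg$height[1], tg$height[2], 150, 200)
    weight <- rnorm_trunc(n, tg$weight[1], tg$weight[2], 45, 140)
    items <- map(names(tg$p_items), function(it) rbinom(n, 1, tg$p_items[[it]]))
    names(items) <- names(tg$p_items)
    tibble(
      group = group,
      gender = ifelse(runif(n) < tg$p_female, "F", "M"),
      age = round(rnorm_trunc(n, tg$age[1], tg$age[2], 35, 95)),
      height = round(height, 1),
      weight = round(weight, 1),
      bmi = round(weight, 1) / (round(height, 1) / 100)^2,
      !!!items,
      n_neuro_comorbid = rbinom(n, 2, tg$p_comorbid),
      fes_short = pmin(28L, pmax(7L, round(rnorm(n, tg$fes[1], tg$fes[2])))),
      # Half-normal log-frailty with sd 0.3: the typical cohort's frailest
      # subject reaches a difficulty (1 / latent_mobility) around 1.6-1.7,
      # inside the gap between the single-task (x1.5) and dual-task-widened
      # (x1.71) sway effect sizes, so groups overlap rather than split
      # cleanly and dual-task trials carry genuine extra signal.
      latent_mobility = exp(-abs(rnorm(n, 0, 0.3)))
    )
  }
  out <- bind_rows(draw_group(spec$n_fallers, "faller"),
                   draw_group(spec$n_nonfallers, "nonfaller"))
  out$subject_id <- sprintf("S%02d", seq_len(nrow(out)))
  select(out, "subject_id", everything())
}
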