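# The 92-feature pool: 42 single-task motion features, the same 42
# recomputed on dual-task trials (prefix "Dual_"), and 8 clinical features.

balance_base <- function() {
  tibble(
    base = c(paste0("Balance_Thorax Linear Acc ", 1:4),
             "Balance_Pelvic Linear Acc 4",
             "Balance_Right Thigh Linear Acc 4",
             "Balance_Left Thigh Linear Acc 4"),
    sensors = list("thorax", "thorax", "thorax", "thorax",
                   "pelvis", "thigh_R", "thigh_L")
  )
}

#' The feature catalogue
#'
#' The ordered 92-entry feature pool: for every feature its printed name,
#' source test variant, whether it is a dual-task recomputation, the sensor
#' placements required to compute it, and its unit. The sensor-requirement
#' map is data (editable), used by [available_features()] for the
#' sensor-configuration search; clinical entries require no sensors.
#'
#' @return A tibble with columns `name`, `test`, `task_id`, `dual`,
#'   `block` (`"motion"`/`"clinical"`), `sensors` (list column), `unit`.
#' @export
#' @examples
#' nrow(feature_catalogue())  # 92
feature_catalogue <- function() {
  bal <- balance_base()
  feet <- c("foot_L", "foot_R")
  thighs <- c("thigh_L", "thigh_R")
  shanks <- c("shank_L", "shank_R")
  single <- bind_rows(
    tibble(name = bal$base, test = "BAL_EO", sensors = bal$sensors, unit = "m/s^2"),
    tibble(name = paste0("CE_", bal$base), test = "BAL_CE", sensors = bal$sensors,
           unit = "m/s^2"),
    tibble(
      name = c("TUG_Time", "TUG_Sit to Stand", "TUG_Walk toward Cone",
               "TUG_Turn around the Cone", "TUG_Walk toward Chair",
               "TUG_Turn and Sit", "TUG_Steps toward Cone",
               "TUG_Steps toward Chair", "TUG_Cadence toward Cone",
               "TUG_Cadence toward Chair"),
      test = "TUG",
      sensors = c(rep(list(c("thorax", feet)), 6), rep(list(feet), 4)),
      unit = c(rep("s", 6), "steps", "steps", "steps/min", "steps/min")),
    tibble(
      name = c("10MWT_Walk Time", "10MWT_Step", "10MWT_Cadence",
               "10MWT_mean Swing Total", "10MWT_std Swing Total",
               "10MWT_Single Support", "10MWT_Stride Duration",
               "10MWT_std Stride Duration"),
      test = "MWT10",
      sensors = rep(list(shanks), 8),
      unit = c("s", "steps", "steps/min", "s", "s", "s", "s", "s")),
    tibble(
      name = c("STS_Time", "STS_Mean Sit to Stand", "STS_Mean Stand to Sit",
               "STS_Thorax Ang Vel", "STS_Pelvic Ang Vel", "STS_std STS",
               "STS_std Sit to Stand", "STS_std Stand to Sit",
               "STS_std Thorax Ang Vel", "STS_std Pelvic Ang Vel"),
      test = "STS",
      sensors = list(thighs, thighs, thighs, c(thighs, "thorax"),
                     c(thighs, "pelvis"), thighs, thighs, thighs,
                     c(thighs, "thorax"), c(thighs, "pelvis")),
      unit = c(rep("s", 3), "deg/s", "deg/s", rep("s", 3), "deg/s", "deg/s"))
  )
  motion <- bind_rows(
    mutate(single, dual = FALSE, task_id = paste0(.data$test, "_single")),
    mutate(single, dual = TRUE, task_id = paste0(.data$test, "_dual"),
           name = paste0("Dual_", .data$name))
  )
  clinical <- tibble(
    name = c("BMI", "Gender", "Age", "Feel Unsteady", "Worried when Walking",
             "Joint Pain", "Number Neurological Disease beside Stroke",
             "Fear of Fall (FES Questionnaire)"),
    test = "CLIN", task_id = NA_character_, dual = FALSE,
    sensors = rep(list(character(0)), 8),
    unit = c("kg/m^2", "M=0/F=1", "years", "0/1", "0/1", "0/1", "count", "score"))
  out <- bind_rows(mutate(motion, block = "motion"),
                   mutate(clinical, block = "clinical")) |>
    select("name", "test", "task_id", "dual", "block", "sensors", "unit")
  stopifnot(nrow(out) == 92, !anyDuplicated(out$name))
  out
}

feature_prefix <- function(trial) {
  paste0(if (trial$dual) "Dual_" else "",
         if (trial$task == "BAL_CE") "CE_" else "")
}

#' Balance (postural sway) features of one trial
#'
#' Seven sway summaries: [sway_summary()] of the low-passed thorax
#' acceleration axes 1-3 and of the resultant, plus the resultant sway of
#' the pelvis and both thighs. Names carry the `CE_` / `Dual_` prefixes
#' according to the trial condition.
#'
#' @param trial A balance `trial_recording`.
#' @param fspec [filter_spec()] used before summarising.
#' @return Named numeric vector of length 7.
#' @export
balance_features <- function(trial, fspec = filter_spec(fs_hz = trial$fs_hz)) {
  if (!trial$task %in% c("BAL_EO", "BAL_CE")) abort("Not a balance trial.")
  need <- c("thorax", "pelvis", "thigh_R", "thigh_L")
  miss <- setdiff(need, names(trial$sensors))
  if (length(miss)) {
    abort(sprintf("Balance features need sensor(s) %s, missing from trial.",
                  paste(miss, collapse = ", ")))
  }
  th <- filtered_channel(trial, "thorax", "linear_acceleration", fspec)
  vals <- c(
    sway_summary(th[, 1]), sway_summary(th[, 2]), sway_summary(th[, 3]),
    sway_summary(resultant(th[, 1], th[, 2], th[, 3])),
    sway_summary(filtered_resultant(trial, "pelvis", "linear_acceleration", fspec)),
    sway_summary(filtered_resultant(trial, "thigh_R", "linear_acceleration", fspec)),
    sway_summary(filtered_resultant(trial, "thigh_L", "linear_acceleration", fspec))
  )
  base <- if (trial$task == "BAL_CE") paste0("CE_", balance_base()$base) else balance_base()$base
  setNames(vals, paste0(if (trial$dual) "Dual_" else "", base))
}

#' Timed-up-and-go features of one trial
#'
#' Ten values: total time (t6 - t1), the five phase durations, heel-strike
#' counts in the two walk phases (events in the half-open phase interval),
#' and the cadence of each walk phase (60 x steps / phase duration,
#' steps/min).
#'
#' @param trial A TUG `trial_recording`.
#' @param tug A valid `tug_events` result from [segment_tug()].
#' @param gait Named list of `gait_events` per foot
#'   (`foot_L`, `foot_R`), e.g. from [detect_gait_events()] on the filtered
#'   foot resultants.
#' @return Named numeric vector of length 10.
#' @export
tug_features <- function(trial, tug, gait) {
  if (!inherits(tug, "tug_events") || !tug$valid) {
    abort(paste0("TUG segmentation invalid: ",
                 paste(names(tug$diagnostics), tug$diagnostics,
                       sep = "=", collapse = "; ")))
  }
  t <- tug$t
  hs_all <- sort(unlist(map(gait, "hs")))
  steps_in <- function(a, b) sum(hs_all >= a & hs_all < b)
  s1 <- steps_in(t[2], t[3]); s2 <- steps_in(t[4], t[5])
  d <- unname(diff(t))
  vals <- c(t[6] - t[1], d[1], d[2], d[3], d[4], d[5],
            s1, s2, 60 * s1 / d[2], 60 * s2 / d[4])
  nm <- c("TUG_Time", "TUG_Sit to Stand", "TUG_Walk toward Cone",
          "TUG_Turn around the Cone", "TUG_Walk toward Chair",
          "TUG_Turn and Sit", "TUG_Steps toward Cone", "TUG_Steps toward Chair",
          "TUG_Cadence toward Cone", "TUG_Cadence toward Chair")
  setNames(as.numeric(vals), paste0(feature_prefix(trial), nm))
}

# pair each toe-off with the next ipsilateral heel strike -> swing durations
swing_durations <- function(ev) {
  map_dbl(ev$to, function(to) {
    nxt <- ev$hs[ev$hs > to]
    if (length(nxt)) nxt[1] - to else NA_real_
  }) |> (\(x) x[!is.na(x)])()
}

#' 10 m walk test features of one trial
#'
#' Eight spatiotemporal values from per-foot gait events: walk time (first
#' to last event), step count (total heel strikes), cadence, mean and SD of
#' swing duration pooled over feet (toe-off to next ipsilateral heel
#' strike), single-support duration (mean contralateral swing), and mean
#' and SD of stride duration (heel strike to next ipsilateral heel strike).
#'
#' @param trial A 10MWT `trial_recording` (used for naming prefixes).
#' @param gait Named list of `gait_events` per foot.
#' @return Named numeric vector of length 8.
#' @export
walk_features <- function(trial, gait) {
  strides <- unlist(map(gait, function(e) diff(e$hs)))
  if (length(strides) < 3 || any(map_int(gait, function(e) length(e$hs)) < 2)) {
    abort("Fewer than 3 strides detected; cannot compute walk features.")
  }
  ev <- unlist(map(gait, function(e) c(e$hs, e$to)))
  walk_time <- max(ev) - min(ev)
  steps <- sum(map_int(gait, function(e) length(e$hs)))
  swings <- unlist(map(gait, swing_durations))
  # single support of one foot = swing of the contralateral foot
  single_support <- mean(unlist(map(seq_along(gait), function(i) {
    swing_durations(gait[[setdiff(seq_along(gait), i)[1]]])
  })))
  vals <- c(walk_time, steps, 60 * steps / walk_time,
            mean(swings), sd(swings), single_support,
            mean(strides), sd(strides))
  nm <- c("10MWT_Walk Time", "10MWT_Step", "10MWT_Cadence",
          "10MWT_mean Swing Total", "10MWT_std Swing Total",
          "10MWT_Single Support", "10MWT_Stride Duration",
          "10MWT_std Stride Duration")
  setNames(as.numeric(vals), paste0(feature_prefix(trial), nm))
}

#' Sit-to-stand features of one trial
#'
#' Ten values from the detected cycles: total task time, mean and SD of
#' cycle duration and of the sit-to-stand / stand-to-sit sub-durations, and
#' mean and SD over cycles of the peak filtered resultant thorax and pelvis
#' angular velocities within each cycle.
#'
#' @param trial An STS `trial_recording`.
#' @param cycles An `sts_cycles` result from [detect_sts_cycles()].
#' @param fspec [filter_spec()] for the thorax/pelvis channels.
#' @return Named numeric vector of length 10.
#' @export
sts_features <- function(trial, cycles, fspec = filter_spec(fs_hz = trial$fs_hz)) {
  if (cycles$mismatch) {
    abort("STS cycle count mismatch flagged by detection; refusing to extract.")
  }
  cy <- cycles$cycles
  if (nrow(cy) < 2) abort("Fewer than 2 STS cycles; SDs undefined.")
  fs <- trial$fs_hz
  peak_in <- function(series, a, b) {
    i0 <- max(1L, floor(a * fs) + 1L); i1 <- min(length(series), ceiling(b * fs) + 1L)
    max(series[i0:i1])
  }
  th <- filtered_resultant(trial, "thorax", "angular_velocity", fspec)
  pv <- filtered_resultant(trial, "pelvis", "angular_velocity", fspec)
  th_pk <- map_dbl(seq_len(nrow(cy)), function(i) peak_in(th, cy$start[i], cy$end[i]))
  pv_pk <- map_dbl(seq_len(nrow(cy)), function(i) peak_in(pv, cy$start[i], cy$end[i]))
  dur <- cy$end - cy$start
  up <- cy$sit_to_stand_end - cy$start
  down <- cy$end - cy$stand_to_sit_start
  vals <- c(max(cy$end) - min(cy$start), mean(up), mean(down),
            mean(th_pk), mean(pv_pk), sd(dur), sd(up), sd(down),
            sd(th_pk), sd(pv_pk))
  nm <- c("STS_Time", "STS_Mean Sit to Stand", "STS_Mean Stand to Sit",
          "STS_Thorax Ang Vel", "STS_Pelvic Ang Vel", "STS_std STS",
          "STS_std Sit to Stand", "STS_std Stand to Sit",
          "STS_std Thorax Ang Vel", "STS_std Pelvic Ang Vel")
  setNames(as.numeric(vals), paste0(feature_prefix(trial), nm))
}

#' Clinical features of one subject
#'
#' BMI (kg/m^2), gender (M = 0, F = 1), age, three binary questionnaire
#' items (yes = 1), neurological comorbidity count, and the short FES-I
#' fear-of-falling score.
#'
#' @param profile One-row subject profile.
#' @return Named numeric vector of length 8.
#' @export
clinical_features <- function(profile) {
  need <- c("height", "weight", "gender", "age", "feel_unsteady",
            "worried_when_walking", "joint_pain", "n_neuro_comorbid", "fes_short")
  miss <- need[map_lgl(need, function(f) is.null(profile[[f]]) || is.na(profile[[f]]))]
  if (length(miss)) {
    abort(sprintf("Profile missing field(s): %s.", paste(miss, collapse = ", ")))
  }
  c("BMI" = profile$weight / (profile$height / 100)^2,
    "Gender" = as.numeric(profile$gender == "F"),
    "Age" = as.numeric(profile$age),
    "Feel Unsteady" = as.numeric(profile$feel_unsteady),
    "Worried when Walking" = as.numeric(profile$worried_when_walking),
    "Joint Pain" = as.numeric(profile$joint_pain),
    "Number Neurological Disease beside Stroke" = as.numeric(profile$n_neuro_comorbid),
    "Fear of Fall (FES Questionnaire)" = as.numeric(profile$fes_short))
}

#' Segment one trial and extract its motion features
#'
#' Runs the task-appropriate segmentation (gait events, TUG phases or STS
#' cycles) on the low-passed channels and returns the trial's named motion
#' features.
#'
#' @param trial A `trial_recording`.
#' @param fspec [filter_spec()].
#' @param expected_sts_cycles Scripted STS repetition count checked against
#'   detection (default 5; `NULL` disables the check).
#' @return Named numeric vector (7, 8 or 10 values depending on task).
#' @export
extract_trial_features <- function(trial, fspec = filter_spec(fs_hz = trial$fs_hz),
                                   expected_sts_cycles = 5) {
  switch(trial$task,
    BAL_EO = ,
    BAL_CE = balance_features(trial, fspec),
    TUG = {
      th <- filtered_channel(trial, "thorax", "angular_velocity", fspec)
      feet <- list(
        foot_L = filtered_resultant(trial, "foot_L", "linear_acceleration", fspec),
        foot_R = filtered_resultant(trial, "foot_R", "linear_acceleration", fspec))
      tug <- segment_tug(th, feet, trial$fs_hz)
      gait <- map(feet, detect_gait_events, fs_hz = trial$fs_hz)
      tug_features(trial, tug, gait)
    },
    MWT10 = {
      gait <- map(
        list(shank_L = "shank_L", shank_R = "shank_R"),
        function(s) detect_gait_events(
          filtered_resultant(trial, s, "linear_acceleration", fspec), trial$fs_hz))
      walk_features(trial, gait)
    },
    STS = {
      thigh <- filtered_resultant(trial, "thigh_L", "angular_velocity", fspec)
      cycles <- detect_sts_cycles(thigh, trial$fs_hz,
                                  expected_cycles = expected_sts_cycles)
      sts_features(trial, cycles, fspec)
    },
    abort(sprintf("Unknown task '%s'.", trial$task)))
}

#' Assemble the subjects x 92 feature table
#'
#' Extracts all motion features from every trial of a cohort, joins the
#' clinical features, and returns the model-ready table with columns in
#' catalogue order plus the binary faller label. Any failed extraction
#' aborts with the subject/task named -- missing values are never silently
#' introduced.
#'
#' @param cohort A `fall_cohort` from [generate_cohort()].
#' @param fspec [filter_spec()]; defaults to the 5 Hz zero-phase filter at
#'   the cohort's sampling rate.
#' @return A tibble: `subject_id`, the 92 feature columns, `label`
#'   (faller = 1). The catalogue is attached as attribute `"catalogue"`.
#' @export
assemble_feature_table <- function(cohort,
                                   fspec = filter_spec(fs_hz = cohort$spec$fs_hz)) {
  stopifnot(inherits(cohort, "fall_cohort"))
  cat_tbl <- feature_catalogue()
  rows <- map(seq_len(nrow(cohort$profiles)), function(i) {
    prof <- as.list(cohort$profiles[i, ])
    vals <- clinical_features(prof)
    for (v in task_variants()) {
      key <- paste0(prof$subject_id, "_", v)
      trial <- cohort$trials[[key]]
      if (is.null(trial)) abort(sprintf("Missing trial %s.", key))
      fv <- tryCatch(
        extract_trial_features(trial, fspec),
        error = function(e) abort(sprintf(
          "Feature extraction failed for subject %s task %s: %s",
          prof$subject_id, v, conditionMessage(e))))
      vals <- c(vals, fv)
    }
    miss <- setdiff(cat_tbl$name, names(vals))
    if (length(miss)) {
      abort(sprintf("Subject %s: missing feature(s) %s.",
                    prof$subject_id, paste(head(miss, 3), collapse = ", ")))
    }
    if (anyNA(vals[cat_tbl$name])) {
      bad <- cat_tbl$name[is.na(vals[cat_tbl$name])]
      abort(sprintf("Subject %s: NA feature(s) %s.",
                    prof$subject_id, paste(head(bad, 3), collapse = ", ")))
    }
    tibble(subject_id = prof$subject_id, !!!as.list(vals[cat_tbl$name]),
           label = as.integer(prof$group == "faller"))
  })
  out <- list_rbind(rows)
  attr(out, "catalogue") <- cat_tbl
  attr(out, "provenance") <- list(seed = cohort$spec$seed, fs_hz = cohort$spec$fs_hz,
                                  filter = unclass(fspec))
  out
}
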