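# Feature catalogue bookkeeping and per-task extractors against oracles.

test_that("the catalogue has 92 uniquely named entries: 42 + 42 + 8", {
  cat_tbl <- feature_catalogue()
  expect_equal(nrow(cat_tbl), 92)
  expect_false(anyDuplicated(cat_tbl$name) > 0)
  motion_single <- cat_tbl$block == "motion" & !cat_tbl$dual
  motion_dual <- cat_tbl$block == "motion" & cat_tbl$dual
  expect_equal(sum(motion_single), 42)
  expect_equal(sum(motion_dual), 42)
  expect_equal(sum(cat_tbl$block == "clinical"), 8)
  # single-task decomposition: 7 + 7 + 10 + 8 + 10 = 42
  counts <- table(cat_tbl$test[motion_single])
  expect_equal(as.integer(counts[c("BAL_EO", "BAL_CE", "TUG", "MWT10", "STS")]),
               c(7L, 7L, 10L, 8L, 10L))
  # every dual entry is the Dual_-prefixed twin of a single entry
  expect_setequal(cat_tbl$name[motion_dual],
                  paste0("Dual_", cat_tbl$name[motion_single]))
  expect_true(all(c("Dual_Balance_Thorax Linear Acc 2",
                    "Fear of Fall (FES Questionnaire)",
                    "10MWT_Stride Duration") %in% cat_tbl$name))
})

test_that("balance features: zeros on a constant trial, truth on a nominal one", {
  tr0 <- fallrisk:::new_trial_recording("S01", "BAL_EO", FALSE, 60, 900,
                                        noise_level = 0)
  expect_identical(unname(balance_features(tr0)), rep(0, 7))

  sim <- simulate_balance(mini_profile("faller"), eyes = "closed", dual = TRUE,
                          seed = 12)
  vals <- balance_features(sim$trial)
  expect_named(vals, paste0("Dual_CE_",
                            c(paste0("Balance_Thorax Linear Acc ", 1:4),
                              "Balance_Pelvic Linear Acc 4",
                              "Balance_Right Thigh Linear Acc 4",
                              "Balance_Left Thigh Linear Acc 4")))
  # thorax per-axis sway within 10% of the annotated target
  tgt <- sim$annotation$true_params$sway_std$thorax
  for (i in 1:3) expect_equal(unname(vals[i]), unname(tgt[i]), tolerance = 0.1)
  # resultant feature equals sway_summary of the recomposed resultant
  fsp <- filter_spec(fs_hz = 60)
  th <- fallrisk:::filtered_channel(sim$trial, "thorax", "linear_acceleration", fsp)
  expect_equal(unname(vals[4]),
               sway_summary(resultant(th[, 1], th[, 2], th[, 3])))
})

test_that("TUG features follow the step/cadence formulas on a hand fixture", {
  t <- c(t1 = 0, t2 = 1, t3 = 5, t4 = 7, t5 = 11, t6 = 13)
  tug <- structure(list(t = t, valid = TRUE, diagnostics = character(0),
                        phase_durations = setNames(diff(t),
                          c("sit_to_stand", "walk1", "turn", "walk2",
                            "turn_and_sit"))),
                   class = "tug_events")
  gait <- list(
    foot_L = structure(list(hs = c(1, 2, 3, 7.5, 9.5), to = numeric(0),
                            warning = FALSE), class = "gait_events"),
    foot_R = structure(list(hs = c(1.5, 2.5, 8.5, 10.5), to = numeric(0),
                            warning = FALSE), class = "gait_events"))
  trial <- list(task = "TUG", dual = FALSE)
  vals <- tug_features(trial, tug, gait)
  expect_equal(unname(vals[["TUG_Time"]]), 13)
  expect_equal(unname(vals[["TUG_Walk toward Cone"]]), 4)
  expect_equal(unname(vals[["TUG_Steps toward Cone"]]), 5)   # HS in [1, 5)
  expect_equal(unname(vals[["TUG_Steps toward Chair"]]), 4)  # HS in [7, 11)
  expect_equal(unname(vals[["TUG_Cadence toward Cone"]]), 60 * 5 / 4)
  expect_equal(unname(vals[["TUG_Cadence toward Chair"]]), 60 * 4 / 4)
  # invalid segmentation refuses with the diagnostics in the message
  bad <- structure(list(t = t, valid = FALSE,
                        diagnostics = c(t2 = "no foot impact")),
                   class = "tug_events")
  expect_error(tug_features(trial, bad, gait), "no foot impact")
})

test_that("walk features on a metronomic fixture match closed forms", {
  hs_L <- c(0, 1, 2, 3); hs_R <- hs_L + 0.5
  gait <- list(
    foot_L = structure(list(hs = hs_L, to = hs_L[-4] + 0.65, warning = FALSE),
                       class = "gait_events"),
    foot_R = structure(list(hs = hs_R, to = hs_R[-4] + 0.65, warning = FALSE),
                       class = "gait_events"))
  trial <- list(task = "MWT10", dual = TRUE)
  vals <- walk_features(trial, gait)
  walk_time <- 3.5   # first event 0, last event 3.5
  expect_equal(unname(vals[["Dual_10MWT_Walk Time"]]), walk_time)
  expect_equal(unname(vals[["Dual_10MWT_Step"]]), 8)
  expect_equal(unname(vals[["Dual_10MWT_Cadence"]]), 60 * 8 / walk_time)
  expect_equal(unname(vals[["Dual_10MWT_mean Swing Total"]]), 0.35)
  expect_equal(unname(vals[["Dual_10MWT_std Swing Total"]]), 0)
  expect_equal(unname(vals[["Dual_10MWT_Single Support"]]), 0.35)
  expect_equal(unname(vals[["Dual_10MWT_Stride Duration"]]), 1)
  expect_equal(unname(vals[["Dual_10MWT_std Stride Duration"]]), 0)
  # too few strides is an error, not an NA
  short <- list(
    foot_L = structure(list(hs = c(0, 1), to = 0.65, warning = FALSE),
                       class = "gait_events"),
    foot_R = structure(list(hs = 0.5, to = numeric(0), warning = FALSE),
                       class = "gait_events"))
  expect_error(walk_features(trial, short), "[Ff]ewer than 3 strides")
})

test_that("STS features: identical cycles give zero SDs; mismatch refuses", {
  trial <- fallrisk:::new_trial_recording("S01", "STS", FALSE, 60, 800,
                                          noise_level = 0)
  start <- c(1, 3, 5, 7, 9)
  cyc <- structure(list(
    cycles = tibble::tibble(start = start, sit_to_stand_end = start + 1,
                            stand_to_sit_start = start + 1.4, end = start + 2),
    warning = FALSE, mismatch = FALSE), class = "sts_cycles")
  vals <- sts_features(trial, cyc)
  expect_equal(unname(vals[["STS_Time"]]), 10)
  expect_equal(unname(vals[["STS_Mean Sit to Stand"]]), 1)
  expect_equal(unname(vals[["STS_Mean Stand to Sit"]]), 0.6)
  expect_equal(unname(vals[["STS_std STS"]]), 0)
  expect_equal(unname(vals[["STS_std Sit to Stand"]]), 0)
  expect_equal(unname(vals[["STS_std Thorax Ang Vel"]]), 0)
  # the angular-velocity channels are all-zero here
  expect_equal(unname(vals[["STS_Thorax Ang Vel"]]), 0)
  bad <- cyc; bad$mismatch <- TRUE
  expect_error(sts_features(trial, bad), "mismatch")
  one <- cyc; one$cycles <- cyc$cycles[1, ]
  expect_error(sts_features(trial, one), "[Ff]ewer than 2")
})

test_that("clinical features use the documented codings", {
  prof <- list(height = 170, weight = 68, gender = "F", age = 71,
               feel_unsteady = 1, worried_when_walking = 0, joint_pain = 1,
               n_neuro_comorbid = 2, fes_short = 14)
  vals <- clinical_features(prof)
  expect_equal(unname(vals[["BMI"]]), 68 / 1.70^2)
  expect_equal(unname(vals[["Gender"]]), 1)
  prof$gender <- "M"
  expect_equal(unname(clinical_features(prof)[["Gender"]]), 0)
  expect_equal(unname(vals[["Fear of Fall (FES Questionnaire)"]]), 14)
  prof$fes_short <- NULL
  expect_error(clinical_features(prof), "fes_short")
})

test_that("assemble_feature_table returns catalogue-ordered, NA-free rows", {
  tbl <- small_table()
  cat_tbl <- feature_catalogue()
  expect_equal(nrow(tbl), 6)
  expect_equal(names(tbl), c("subject_id", cat_tbl$name, "label"))
  expect_false(anyNA(tbl))
  expect_equal(tbl$label, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_s3_class(attr(tbl, "catalogue"), "tbl_df")
  # feature values differ between the single and dual variant of a feature
  expect_false(identical(tbl[["TUG_Time"]], tbl[["Dual_TUG_Time"]]))
})

test_that("noise-free temporal features match annotation-derived oracles", {
  sp <- cohort_spec(n_fallers = 1, n_nonfallers = 1, seed = 77, noise_level = 0)
  co <- generate_cohort(sp)
  tol <- 1 / sp$fs_hz
  for (sid in c("S01", "S02")) {
    ann <- co$annotations[[paste0(sid, "_TUG_single")]]
    vals <- extract_trial_features(co$trials[[paste0(sid, "_TUG_single")]])
    expect_equal(unname(vals[["TUG_Time"]]),
                 ann$true_params$total_time, tolerance = tol)
    expect_equal(unname(vals[["TUG_Turn around the Cone"]]),
                 unname(ann$true_params$phase_durations[3]), tolerance = tol)
    ann <- co$annotations[[paste0(sid, "_STS_single")]]
    vals <- extract_trial_features(co$trials[[paste0(sid, "_STS_single")]])
    expect_equal(unname(vals[["STS_Mean Sit to Stand"]]),
                 mean(ann$true_params$sit_to_stand), tolerance = tol)
    ann <- co$annotations[[paste0(sid, "_MWT10_single")]]
    vals <- extract_trial_features(co$trials[[paste0(sid, "_MWT10_single")]])
    expect_equal(unname(vals[["10MWT_Stride Duration"]]),
                 mean(ann$true_params$strides), tolerance = tol)
  }
})
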