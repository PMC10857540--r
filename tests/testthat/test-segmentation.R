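# Event detectors against simulator ground truth and hand-built fixtures.

fs <- 60
fsp <- filter_spec(fs_hz = fs)

# distance from each detected event to its nearest truth event, in seconds
event_errors <- function(detected, truth) {
  vapply(detected, function(d) min(abs(truth - d)), 0)
}

gauss_bump <- function(n, center_s, amp = 2, sigma = 0.025) {
  t <- (seq_len(n) - 1) / fs
  amp * exp(-(t - center_s)^2 / (2 * sigma^2))
}

test_that("gait events of a 10-stride stream are recovered within 50 ms", {
  gs <- simulate_gait_stream(mini_profile(), n_strides = 10, seed = 14)
  for (foot in c("foot_L", "foot_R")) {
    acc <- gs$sensors[[foot]]$linear_acceleration
    res <- lowpass(resultant(acc[, 1], acc[, 2], acc[, 3]), fsp)
    ev <- detect_gait_events(res, fs)
    expect_false(ev$warning)
    expect_length(ev$hs, 10)
    expect_length(ev$to, 10)
    expect_true(all(event_errors(ev$hs, gs$truth$hs[[foot]]) <= 0.05))
    expect_true(all(event_errors(ev$to, gs$truth$to[[foot]]) <= 0.05))
  }
})

test_that("a single impact bump yields one heel strike and no toe-off", {
  x <- gauss_bump(600, 5) + 0.001 * sin(2 * pi * 0.3 * (0:599) / fs)
  ev <- detect_gait_events(x, fs)
  expect_length(ev$hs, 1)
  expect_length(ev$to, 0)
  expect_equal(ev$hs, 5, tolerance = 1 / fs)
})

test_that("a flat signal warns and returns no events", {
  expect_warning(ev <- detect_gait_events(rep(0.5, 600), fs), "[Nn]o gait events")
  expect_true(ev$warning)
  expect_length(ev$hs, 0)
})

test_that("detection is time-shift equivariant and amplitude-scale invariant", {
  x <- gauss_bump(900, 3) + gauss_bump(900, 4.1) + gauss_bump(900, 5.2)
  shift <- 2                                 # whole seconds: stays on-grid
  xs <- c(numeric(shift * fs), x)[seq_along(x)]
  ev <- detect_gait_events(x, fs)
  evs <- detect_gait_events(xs, fs)
  expect_equal(evs$hs, ev$hs + shift)
  ev3 <- detect_gait_events(3 * x, fs)
  expect_identical(ev3$hs, ev$hs)
  expect_identical(ev3$to, ev$to)
})

test_that("count_steps sums heel strikes over feet", {
  e1 <- detect_gait_events(gauss_bump(600, 2) + gauss_bump(600, 3.2), fs)
  e2 <- detect_gait_events(gauss_bump(600, 2.6), fs)
  expect_identical(count_steps(e1, e2), 3L)
})

test_that("TUG segmentation recovers all six boundaries within 100 ms", {
  for (grp in c("nonfaller", "faller")) {
    sim <- simulate_tug(mini_profile(grp), dual = (grp == "faller"), seed = 8)
    th <- lowpass(sim$trial$sensors$thorax$angular_velocity, fsp)
    feet <- lapply(c(foot_L = "foot_L", foot_R = "foot_R"), function(f) {
      acc <- lowpass(sim$trial$sensors[[f]]$linear_acceleration, fsp)
      resultant(acc[, 1], acc[, 2], acc[, 3])
    })
    tug <- segment_tug(th, feet, fs)
    expect_true(tug$valid)
    truth <- sim$annotation$true_events$boundaries
    expect_true(all(abs(tug$t - truth) <= 0.1))
    expect_length(tug$phase_durations, 5)
    expect_named(tug$phase_durations,
                 c("sit_to_stand", "walk1", "turn", "walk2", "turn_and_sit"))
    # additivity: phases partition the total duration
    expect_equal(sum(tug$phase_durations), tug$t[["t6"]] - tug$t[["t1"]])
  }
})

test_that("a longer scripted turn lengthens the detected turn phase", {
  seg <- function(scale) {
    sim <- simulate_tug(mini_profile(), seed = 10, turn_scale = scale)
    th <- lowpass(sim$trial$sensors$thorax$angular_velocity, fsp)
    feet <- lapply(c("foot_L", "foot_R"), function(f) {
      acc <- lowpass(sim$trial$sensors[[f]]$linear_acceleration, fsp)
      resultant(acc[, 1], acc[, 2], acc[, 3])
    })
    segment_tug(th, feet, fs)$phase_durations[["turn"]]
  }
  expect_gt(seg(2), seg(1) + 1)  # nominal turn is 1.8 s; doubled adds ~1.8 s
})

test_that("segment_tug reports named diagnostics on unusable input", {
  tug <- segment_tug(matrix(0, 600, 3), list(rep(0, 600)), fs)
  expect_false(tug$valid)
  expect_gt(length(tug$diagnostics), 0)
  expect_true(all(nzchar(names(tug$diagnostics))))
  expect_null(tug$phase_durations)
})

test_that("STS cycles are detected exactly, with boundaries near truth", {
  for (k in c(3L, 5L)) {
    sim <- simulate_sts(mini_profile(), seed = 31 + k, n_cycles = k)
    th <- lowpass(abs(sim$trial$sensors$thigh_L$angular_velocity[, "a2"]), fsp)
    cyc <- detect_sts_cycles(th, fs, expected_cycles = k)
    expect_false(cyc$mismatch)
    expect_equal(nrow(cyc$cycles), k)
    truth <- sim$annotation$true_events$cycles
    for (col in names(truth)) {
      expect_true(all(abs(cyc$cycles[[col]] - truth[[col]]) <= 0.1))
    }
  }
})

test_that("STS detection flags, but never corrects, a count mismatch", {
  sim <- simulate_sts(mini_profile(), seed = 4, n_cycles = 5)
  th <- lowpass(abs(sim$trial$sensors$thigh_L$angular_velocity[, "a2"]), fsp)
  expect_warning(cyc <- detect_sts_cycles(th, fs, expected_cycles = 4),
                 "expected 4")
  expect_true(cyc$mismatch)
  expect_equal(nrow(cyc$cycles), 5)  # the detected count is kept
})

test_that("an odd lobe count drops the unpaired lobe with a warning", {
  n <- 900
  x <- gauss_bump(n, 3, amp = 80, sigma = 0.3) +
    gauss_bump(n, 6, amp = 80, sigma = 0.3) +
    gauss_bump(n, 9, amp = 80, sigma = 0.3)
  expect_warning(cyc <- detect_sts_cycles(x, fs), "unpaired")
  expect_true(cyc$warning)
  expect_equal(nrow(cyc$cycles), 1)
})
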