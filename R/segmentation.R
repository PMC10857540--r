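# Event detection: gait HS/TO from shank (or foot) resultant acceleration,
# five-phase TUG segmentation from thorax angular velocity + foot impacts,
# and sit-stand-sit cycle detection from thigh angular velocity.
#
# All detectors are scale-free: peak thresholds adapt as
# median + k * MAD of the series, lobe onsets/offsets are 10%-of-peak
# crossings, and candidate ties go to the earliest sample. Events are
# reported in seconds from trial start (sample indices are 0-based, so
# time = index / fs).

# Local maxima of x strictly above `min_height`, greedily thinned so no two
# kept peaks are closer than `min_dist` samples (higher peak wins; earliest
# wins on ties).
find_peaks <- function(x, min_height = -Inf, min_dist = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > min_height]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

adaptive_threshold <- function(x, k = 3) {
  median(x) + k * mad(x)
}

# Expand each peak to its 10%-of-peak onset/offset crossings (sub-sample,
# by linear interpolation); merge overlapping lobes (taller peak wins).
# The peak threshold is relative to the dominant excursion (scale-free);
# a median+MAD threshold would be inflated here because transition lobes,
# unlike gait impacts, can occupy most of the trial.
find_lobes <- function(x, fs, frac = 0.10, min_sep_s = 0.5,
                       rel_height = 0.25) {
  thr <- rel_height * max(x)
  pk <- find_peaks(x, min_height = thr, min_dist = round(min_sep_s * fs))
  if (!length(pk)) {
    return(tibble(onset = numeric(0), peak = numeric(0), offset = numeric(0),
                  height = numeric(0)))
  }
  n <- length(x)
  rows <- map(pk, function(i) {
    lev <- frac * x[i]
    on <- i; while (on > 1 && x[on - 1] >= lev) on <- on - 1L
    off <- i; while (off < n && x[off + 1] >= lev) off <- off + 1L
    # sub-sample crossing times (0-based seconds)
    t_on <- if (on > 1) {
      f <- (lev - x[on - 1]) / (x[on] - x[on - 1])
      (on - 2 + f) / fs
    } else (on - 1) / fs
    t_off <- if (off < n) {
      f <- (x[off] - lev) / (x[off] - x[off + 1])
      (off - 1 + f) / fs
    } else (off - 1) / fs
    c(onset = t_on, peak = (i - 1) / fs, offset = t_off,
      height = x[i], i_on = on, i_off = off)
  })
  lb <- as_tibble(do.call(rbind, rows))
  # merge lobes whose 10% regions overlap
  keep <- rep(TRUE, nrow(lb))
  for (i in seq_len(nrow(lb))[-1]) {
    if (lb$i_on[i] <= lb$i_off[i - 1]) {
      if (lb$height[i] > lb$height[i - 1]) keep[i - 1] <- FALSE else keep[i] <- FALSE
    }
  }
  select(lb[keep, ], "onset", "peak", "offset", "height")
}

#' Detect heel-strike and toe-off events from a resultant acceleration
#'
#' Heel strikes (HS) are the dominant impact transients of the (already
#' low-passed) resultant linear acceleration of one shank or foot sensor;
#' each toe-off (TO) is the highest minor transient in a stride-scaled
#' window before the following HS. Thresholds are adaptive
#' (median + k x MAD), so event times are invariant to amplitude scaling.
#'
#' @param res Filtered resultant acceleration series of one foot/shank.
#' @param fs_hz Sampling rate.
#' @param cadence_prior_spm Optional cadence prior in steps/min; sets the
#'   minimum inter-HS distance to 0.4 x the implied stride time (default
#'   prior stride 1.1 s).
#' @param k_mad Threshold sensitivity (default 3).
#'
#' @return A `gait_events` object: list with `hs`, `to` (times in s),
#'   `warning` flag (TRUE if no events found), and the detection `params`.
#' @export
detect_gait_events <- function(res, fs_hz, cadence_prior_spm = NULL, k_mad = 3) {
  prior_stride <- if (is.null(cadence_prior_spm)) 1.1 else 120 / cadence_prior_spm
  out <- function(hs, to, warning) {
    structure(list(hs = hs, to = to, warning = warning,
                   params = list(k_mad = k_mad, prior_stride_s = prior_stride)),
              class = "gait_events")
  }
  thr <- adaptive_threshold(res, k_mad)
  cand <- find_peaks(res, min_height = thr, min_dist = max(1, round(0.1 * fs_hz)))
  if (!length(cand)) {
    warn("No gait events detected above the adaptive threshold.")
    return(out(numeric(0), numeric(0), TRUE))
  }
  heights <- res[cand]
  # heel strikes are the dominant transients; toe-offs and residual noise
  # peaks sit well below half the dominant impact height
  hs_level <- 0.5 * max(heights)
  hs_idx <- cand[heights >= hs_level]
  # enforce the minimum inter-HS distance, higher peak wins
  hs_idx <- find_peaks(replace(numeric(length(res)), hs_idx, res[hs_idx]),
                       min_height = 0, min_dist = round(0.4 * prior_stride * fs_hz))
  if (!length(hs_idx)) {
    warn("No heel strikes detected.")
    return(out(numeric(0), numeric(0), TRUE))
  }
  med_stride <- if (length(hs_idx) >= 2) median(diff(hs_idx)) / fs_hz else prior_stride
  to_idx <- integer(0)
  next_hs <- c(hs_idx[-1], hs_idx[length(hs_idx)] + round(med_stride * fs_hz))
  minor <- setdiff(cand, hs_idx)
  for (j in seq_along(hs_idx)) {
    w0 <- next_hs[j] - round(0.55 * med_stride * fs_hz)
    w1 <- next_hs[j] - round(0.10 * med_stride * fs_hz)
    inw <- minor[minor >= w0 & minor <= w1]
    if (length(inw)) to_idx <- c(to_idx, inw[which.max(res[inw])])
  }
  out((hs_idx - 1) / fs_hz, (sort(to_idx) - 1) / fs_hz, FALSE)
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d HS, %d TO%s\n", length(x$hs), length(x$to),
              if (x$warning) " [warning]" else ""))
  invisible(x)
}

#' Count steps from detected gait events
#'
#' Total heel strikes across the supplied per-foot event sets.
#'
#' @param ... One or more `gait_events` objects (typically left and right).
#' @return Integer step count.
#' @export
count_steps <- function(...) {
  evs <- list(...)
  sum(map_int(evs, function(e) length(e$hs)))
}

#' Segment a timed-up-and-go trial into its five phases
#'
#' Boundaries: t1 = onset of the first thorax pitch (axis 2)
#' angular-velocity lobe (sit-to-stand start); t2/t4 = first foot impact
#' after the preceding lobe's offset (walk initiations); t3/t5 = onsets of
#' the two thorax yaw (axis 3) lobes (turn, turn-and-sit); t6 = offset of
#' the last pitch lobe (task end). Lobe onsets/offsets are 10%-of-peak
#' crossings; all inputs must be low-passed already.
#'
#' @param thorax_angvel n x 3 filtered thorax angular-velocity matrix.
#' @param feet_res List of filtered resultant foot accelerations
#'   (one per foot).
#' @param fs_hz Sampling rate.
#'
#' @return A `tug_events` object: boundary times `t` (t1..t6, s), `valid`
#'   flag, `diagnostics` (named reasons for any missing boundary) and
#'   `phase_durations` (5 durations, s) when valid.
#' @export
segment_tug <- function(thorax_angvel, feet_res, fs_hz) {
  pitch <- abs(thorax_angvel[, 2])
  yaw <- abs(thorax_angvel[, 3])
  diag <- character(0)
  t <- rep(NA_real_, 6); names(t) <- paste0("t", 1:6)

  pl <- find_lobes(pitch, fs_hz, min_sep_s = 1)
  if (nrow(pl) >= 2) {
    t[1] <- pl$onset[1]
    t[6] <- pl$offset[nrow(pl)]
  } else diag <- c(diag, pitch_lobes = sprintf("expected >= 2 pitch lobes, found %d", nrow(pl)))

  yl <- find_lobes(yaw, fs_hz, min_sep_s = 1)
  if (nrow(yl) >= 2) {
    yl2 <- head(arrange(yl, desc(.data$height)), 2) |> arrange(.data$onset)
    t[3] <- yl2$onset[1]
    t[5] <- yl2$onset[2]
  } else diag <- c(diag, yaw_lobes = sprintf("expected 2 yaw lobes, found %d", nrow(yl)))

  # walk initiations are anchored on heel-strike impacts, detected with the
  # same dominant-transient rule as the gait detector
  foot_peaks <- sort(unlist(map(feet_res, function(r) {
    suppressWarnings(detect_gait_events(r, fs_hz)$hs)
  })))
  first_after <- function(tt) {
    p <- foot_peaks[foot_peaks > tt]
    if (length(p)) p[1] else NA_real_
  }
  if (!is.na(t[1]) && nrow(pl) >= 1) t[2] <- first_after(pl$offset[1])
  if (!is.na(t[3]) && nrow(yl) >= 2) {
    yl2 <- head(arrange(yl, desc(.data$height)), 2) |> arrange(.data$onset)
    t[4] <- first_after(yl2$offset[1])
  }
  if (is.na(t[2])) diag <- c(diag, t2 = "no foot impact after sit-to-stand lobe")
  if (is.na(t[4])) diag <- c(diag, t4 = "no foot impact after turn lobe")

  valid <- !anyNA(t) && all(diff(t) > 0)
  if (!valid && !length(diag)) diag <- c(ordering = "boundaries not strictly increasing")
  structure(
    list(t = t, valid = valid, diagnostics = diag,
         phase_durations = if (valid) setNames(diff(t),
           c("sit_to_stand", "walk1", "turn", "walk2", "turn_and_sit")) else NULL),
    class = "tug_events"
  )
}

#' @export
print.tug_events <- function(x, ...) {
  cat("<tug_events>", if (x$valid) "valid" else "INVALID", "\n")
  print(round(x$t, 3))
  invisible(x)
}

#' Detect sit-stand-sit cycles from thigh angular velocity
#'
#' Finds the convex lobes of the (filtered, rectified/resultant) thigh
#' angular-velocity series and pairs them sequentially: each cycle is a
#' sit-to-stand lobe followed by a stand-to-sit lobe, delimited by
#' 10%-of-peak crossings.
#'
#' @param thigh_angvel Filtered non-negative series (e.g. the resultant
#'   angular velocity of one thigh sensor).
#' @param fs_hz Sampling rate.
#' @param expected_cycles Optional expected cycle count; a mismatch sets the
#'   `mismatch` flag (never silently corrected).
#'
#' @return An `sts_cycles` object: tibble `cycles` with columns `start`,
#'   `sit_to_stand_end`, `stand_to_sit_start`, `end` (s), plus `warning`
#'   and `mismatch` flags.
#' @export
detect_sts_cycles <- function(thigh_angvel, fs_hz, expected_cycles = NULL) {
  lb <- find_lobes(thigh_angvel, fs_hz, min_sep_s = 0.5)
  empty <- tibble(start = numeric(0), sit_to_stand_end = numeric(0),
                  stand_to_sit_start = numeric(0), end = numeric(0))
  warning_flag <- FALSE
  if (nrow(lb) == 0) {
    warn("No sit-to-stand lobes detected.")
    cycles <- empty; warning_flag <- TRUE
  } else if (nrow(lb) %% 2 == 1) {
    warn("Odd number of transition lobes; last unpaired lobe dropped.")
    warning_flag <- TRUE
    lb <- lb[-nrow(lb), ]
  }
  if (nrow(lb) >= 2) {
    odd <- seq(1, nrow(lb), by = 2); even <- odd + 1
    cycles <- tibble(start = lb$onset[odd],
                     sit_to_stand_end = lb$offset[odd],
                     stand_to_sit_start = lb$onset[even],
                     end = lb$offset[even])
  } else cycles <- empty
  mismatch <- !is.null(expected_cycles) && nrow(cycles) != expected_cycles
  if (mismatch) {
    warn(sprintf("Detected %d cycles but expected %d.", nrow(cycles), expected_cycles))
  }
  structure(list(cycles = cycles, warning = warning_flag, mismatch = mismatch),
            class = "sts_cycles")
}

#' @export
print.sts_cycles <- function(x, ...) {
  cat(sprintf("<sts_cycles> %d cycles%s%s\n", nrow(x$cycles),
              if (x$warning) " [warning]" else "",
              if (x$mismatch) " [count mismatch]" else ""))
  invisible(x)
}
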