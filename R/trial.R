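# Trial-recording container and its tidy converters.

new_channel_block <- function(n, noise_level) {
  blk <- function() {
    m <- matrix(rnorm(n * 3, 0, noise_level), n, 3)
    colnames(m) <- c("a1", "a2", "a3")
    m
  }
  list(angle = blk(), angular_velocity = blk(), linear_acceleration = blk())
}

# A trial recording: one subject x one task variant x 8 sensors at fs_hz.
# Channels start as additive white sensor noise; generators overlay the
# scripted movement motifs on top. Axis convention in the subject frame:
# a1 anterior(+), a2 rightward(+), a3 downward(+); accelerations are
# gravity-free movement components.
new_trial_recording <- function(subject_id, task, dual, fs_hz, n, noise_level) {
  sensors <- map(setNames(SENSOR_LABELS, SENSOR_LABELS),
                 function(s) new_channel_block(n, noise_level))
  structure(
    list(subject_id = subject_id, task = task, dual = isTRUE(dual),
         task_id = paste0(task, "_", if (isTRUE(dual)) "dual" else "single"),
         fs_hz = fs_hz, n = as.integer(n), sensors = sensors),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> %s %s: %d samples @ %g Hz, %d sensors\n",
              x$subject_id, x$task_id, x$n, x$fs_hz, length(x$sensors)))
  invisible(x)
}

#' Convert a trial recording to a long tibble
#'
#' One row per (time, sensor, channel, axis): columns `time_s`, `sensor`,
#' `channel`, `axis`, `value`. This is the same long layout used by
#' [write_trial()].
#'
#' @param x A `trial_recording`.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.trial_recording <- function(x, ...) {
  t <- (seq_len(x$n) - 1) / x$fs_hz
  rows <- imap(x$sensors, function(blk, sensor) {
    imap(blk, function(m, channel) {
      tibble(time_s = rep(t, 3),
             sensor = sensor, channel = channel,
             axis = rep(colnames(m), each = x$n),
             value = as.vector(m))
    }) |> list_rbind()
  }) |> list_rbind()
  arrange(rows, .data$sensor, .data$channel, .data$axis, .data$time_s)
}

# Extract one channel matrix (n x 3) from a trial.
trial_channel <- function(trial, sensor, channel) {
  if (!sensor %in% names(trial$sensors)) {
    abort(sprintf("Sensor '%s' not present in trial %s/%s.",
                  sensor, trial$subject_id, trial$task_id))
  }
  trial$sensors[[sensor]][[channel]]
}

# Filtered n x 3 channel matrix.
filtered_channel <- function(trial, sensor, channel, fspec) {
  m <- trial_channel(trial, sensor, channel)
  out <- lowpass_mat(m, fspec)
  colnames(out) <- colnames(m)
  out
}

# Filtered resultant of a 3-axis channel.
filtered_resultant <- function(trial, sensor, channel, fspec) {
  m <- filtered_channel(trial, sensor, channel, fspec)
  resultant(m[, 1], m[, 2], m[, 3])
}

#' Plot trial channels
#'
#' @param object A `trial_recording`.
#' @param sensors Sensor labels to show (default thorax).
#' @param channel Channel to show.
#' @param ... Unused.
#' @return A ggplot object (time series faceted by sensor, coloured by axis).
#' @export
autoplot.trial_recording <- function(object, sensors = "thorax",
                                     channel = "linear_acceleration", ...) {
  t <- (seq_len(object$n) - 1) / object$fs_hz
  df <- map(setNames(sensors, sensors), function(s) {
    m <- trial_channel(object, s, channel)
    tibble(time_s = rep(t, 3), axis = rep(colnames(m), each = object$n),
           value = as.vector(m))
  }) |> list_rbind(names_to = "sensor")
  ggplot(df, aes(.data$time_s, .data$value, colour = .data$axis)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(~sensor, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = channel,
         title = sprintf("%s %s", object$subject_id, object$task_id)) +
    theme_minimal()
}
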