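# On-disk formats: long-format trial CSV, annotation JSON sidecars, cohort
# manifest JSON, clinical CSV, feature-table CSV + schema JSON.

#' Write / read a trial recording as long-format CSV
#'
#' One row per sample and channel: columns `time_s`, `sensor`, `channel`,
#' `axis`, `value`. `write_trial()` followed by `read_trial()` is the
#' identity on valid recordings (full numeric precision). Subject, task and
#' condition are encoded in the file name
#' `<subject>_<task>_<single|dual>.csv`.
#'
#' @param trial A `trial_recording`.
#' @param path File path (for `read_trial`, must follow the naming scheme).
#' @return `write_trial` returns `path` invisibly; `read_trial` returns a
#'   `trial_recording`.
#' @export
write_trial <- function(trial, path) {
  readr::write_csv(as_tibble(trial), path)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_s", "sensor", "channel", "axis", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("Trial file %s missing column(s): %s.",
                  basename(path), paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(df$sensor), SENSOR_LABELS)
  if (length(bad)) {
    abort(sprintf("Unknown sensor label(s) in %s: %s.",
                  basename(path), paste(bad, collapse = ", ")))
  }
  stem <- sub("\\.csv$", "", basename(path))
  # task labels contain underscores (BAL_EO, ...), so match them explicitly
  # instead of splitting on "_"
  m <- regmatches(stem, regexec("^(.+)_(single|dual)$", stem))[[1]]
  task <- if (length(m) == 3) {
    TASK_LABELS[endsWith(m[2], paste0("_", TASK_LABELS))]
  } else character()
  subject <- if (length(task) == 1) sub(paste0("_", task, "$"), "", m[2]) else ""
  if (length(task) != 1 || !nzchar(subject)) {
    abort(sprintf("File name '%s' does not match <subject>_<task>_<single|dual>.csv.",
                  basename(path)))
  }
  times <- sort(unique(df$time_s))
  fs <- 1 / median(diff(times))
  n <- length(times)
  trial <- new_trial_recording(subject, task, m[3] == "dual", round(fs, 6), n,
                               noise_level = 0)
  for (s in unique(df$sensor)) {
    for (ch in unique(df$channel[df$sensor == s])) {
      sub <- df[df$sensor == s & df$channel == ch, ]
      mat <- matrix(0, n, 3, dimnames = list(NULL, c("a1", "a2", "a3")))
      for (ax in c("a1", "a2", "a3")) {
        rows <- sub[sub$axis == ax, ]
        mat[, ax] <- rows$value[order(rows$time_s)]
      }
      trial$sensors[[s]][[ch]] <- mat
    }
  }
  trial
}

annotation_to_list <- function(ann) {
  ev <- ann$true_events
  if (!is.null(ev$cycles)) ev$cycles <- as.data.frame(ev$cycles)
  list(subject_id = ann$subject_id, task_id = ann$task_id,
       duration_s = ann$duration_s, true_events = ev,
       true_params = ann$true_params)
}

#' Write a cohort to a directory
#'
#' Writes one long-format CSV per trial, one annotation JSON sidecar per
#' trial, the clinical table CSV, and a `manifest.json` indexing all files
#' with the cohort seed and profile table.
#'
#' @param cohort A `fall_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest (a list), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (key in names(cohort$trials)) {
    f <- file.path(dir, paste0(key, ".csv"))
    write_trial(cohort$trials[[key]], f)
    jsonlite::write_json(annotation_to_list(cohort$annotations[[key]]),
                         file.path(dir, paste0(key, ".annotation.json")),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, basename(f))
  }
  readr::write_csv(cohort$clinical_table, file.path(dir, "clinical.csv"))
  manifest <- list(
    seed = cohort$spec$seed,
    n_fallers = cohort$spec$n_fallers, n_nonfallers = cohort$spec$n_nonfallers,
    fs_hz = cohort$spec$fs_hz, noise_level = cohort$spec$noise_level,
    effect_profile = cohort$spec$effect_profile,
    trial_files = files, clinical_file = "clinical.csv",
    profiles = as.data.frame(cohort$profiles))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write / read a feature table as CSV with a JSON schema sidecar
#'
#' The schema records column names, units and required sensors per feature.
#'
#' @param table Feature table from [assemble_feature_table()].
#' @param path CSV path; the schema is written beside it as
#'   `<path>.schema.json`.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` the tibble with the catalogue re-attached.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  cat_tbl <- attr(table, "catalogue") %||% feature_catalogue()
  schema <- list(columns = map(seq_len(nrow(cat_tbl)), function(i) {
    list(name = cat_tbl$name[i], unit = cat_tbl$unit[i],
         task = cat_tbl$task_id[i], sensors = cat_tbl$sensors[[i]])
  }), provenance = attr(table, "provenance"))
  jsonlite::write_json(schema, paste0(path, ".schema.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  attr(out, "catalogue") <- feature_catalogue()
  sf <- paste0(path, ".schema.json")
  if (file.exists(sf)) {
    schema <- jsonlite::read_json(sf, simplifyVector = FALSE)
    if (!is.null(schema$provenance)) {
      attr(out, "provenance") <- schema$provenance
    }
  }
  out
}
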