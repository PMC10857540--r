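# End-to-end pipeline: simulate -> preprocess/segment/extract -> model.

#' Pipeline configuration
#'
#' Bundles the cohort, filter and model settings plus the requested stages
#' into one object that round-trips losslessly through YAML
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param cohort A [cohort_spec()].
#' @param filter A [filter_spec()] (defaults to 5 Hz zero-phase at the
#'   cohort rate).
#' @param model A [model_spec()].
#' @param ablations Character subset of `c("no_motion", "no_dual")` to run
#'   after the full model.
#' @param search Run the sensor-configuration search? (logical; or a list
#'   with `max_tests`).
#' @param out_dir Optional output directory; when set, [run_pipeline()]
#'   writes the feature table, evaluation JSON and resolved config there.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_spec(), filter = NULL,
                            model = model_spec(), ablations = character(0),
                            search = FALSE, out_dir = NULL) {
  filter <- filter %||% filter_spec(fs_hz = cohort$fs_hz)
  stopifnot(inherits(cohort, "cohort_spec"), inherits(filter, "filter_spec"),
            inherits(model, "model_spec"))
  structure(list(cohort = cohort, filter = filter, model = model,
                 ablations = ablations, search = search, out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- list(cohort = unclass(config$cohort),
              filter = unclass(config$filter),
              model = unclass(config$model),
              ablations = as.list(config$ablations),
              search = config$search, out_dir = config$out_dir)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  pipeline_config(
    cohort = cohort_spec(n_fallers = lst$cohort$n_fallers,
                         n_nonfallers = lst$cohort$n_nonfallers,
                         fs_hz = lst$cohort$fs_hz, seed = lst$cohort$seed,
                         effect_profile = do.call(effect_profile, lst$cohort$effect_profile),
                         noise_level = lst$cohort$noise_level),
    filter = filter_spec(cutoff_hz = lst$filter$cutoff_hz, order = lst$filter$order,
                         fs_hz = lst$filter$fs_hz, zero_phase = lst$filter$zero_phase),
    model = model_spec(classifier = lst$model$classifier,
                       normalize = lst$model$normalize,
                       hyperparams = lst$model$hyperparams,
                       seed = lst$model$seed,
                       selection_mode = lst$model$selection_mode,
                       max_features = lst$model$max_features),
    ablations = unlist(lst$ablations) %||% character(0),
    search = lst$search %||% FALSE,
    out_dir = lst$out_dir
  )
}

#' Run the full pipeline
#'
#' Simulates the cohort, extracts the 92-feature table, evaluates the
#' configured model with forward selection under LOSO, optionally runs the
#' requested ablations and configuration search, and (if `out_dir` is set)
#' writes the feature table, evaluation JSON and resolved config. Stages
#' fail fast with the failing stage named. The whole run is a pure function
#' of the config (including its seeds).
#'
#' @param config A [pipeline_config()].
#' @return A list: `features` (tibble), `evaluation` (`fall_eval`),
#'   `ablations` (named list of `fall_eval`), `search` (tibble or NULL),
#'   `timings` (named seconds).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    list(value = val, secs = proc.time()[["elapsed"]] - t0)
  }
  sim <- stage("simulate", generate_cohort(config$cohort))
  feat <- stage("extract", assemble_feature_table(sim$value, config$filter))
  fit <- stage("model", forward_select(feat$value, config$model))
  abl <- stage("ablate", {
    out <- map(setNames(config$ablations, config$ablations),
               function(m) run_ablation(feat$value, m, config$model))
    out
  })
  srch <- stage("search", {
    if (isTRUE(config$search) || is.list(config$search)) {
      mt <- if (is.list(config$search)) config$search$max_tests %||% 3 else 3
      search_configurations(feat$value, max_tests = mt, spec = config$model)
    } else NULL
  })
  timings <- c(simulate = sim$secs, extract = feat$secs, model = fit$secs,
               ablate = abl$secs, search = srch$secs)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(feat$value, file.path(config$out_dir, "features.csv"))
    jsonlite::write_json(
      list(glance = as.data.frame(glance(fit$value)),
           per_subject = as.data.frame(tidy(fit$value)),
           selected_features = fit$value$selected_features,
           trajectory = if (!is.null(fit$value$trajectory))
             as.data.frame(fit$value$trajectory),
           seed = config$model$seed),
      file.path(config$out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    write_pipeline_config(config, file.path(config$out_dir, "config.yaml"))
  }
  list(features = feat$value, evaluation = fit$value, ablations = abl$value,
       search = srch$value, timings = timings)
}
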