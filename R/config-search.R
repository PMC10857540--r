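# Sensor-configuration x test-battery search: which reduced hardware setups
# and short batteries retain the predictive power of the full protocol.

#' Sensor configuration
#'
#' A named subset of the 8 sensor placements. Bilateral pairs ("upper
#' legs" = both thighs, "lower legs or feet" = shanks/feet) are selected as
#' one anatomical slot but count their physical sensors toward the arity.
#'
#' @param name Configuration label.
#' @param placements Character subset of the 8 placement labels.
#' @param arity `"single"`, `"double"` or `"triple"` (physical sensor
#'   grouping used for reporting).
#' @return A `sensor_config` object.
#' @export
sensor_config <- function(name, placements, arity) {
  if (!length(placements) || !all(placements %in% SENSOR_LABELS)) {
    abort(sprintf("Invalid placements for config '%s'.", name))
  }
  arity <- match.arg(arity, c("single", "double", "triple"))
  structure(list(name = name, placements = placements, arity = arity),
            class = "sensor_config")
}

#' Standard sensor configurations
#'
#' The single/double/triple configurations searched by default: thorax,
#' pelvis; thorax + pelvis, upper legs, lower legs or feet; upper legs +
#' thorax, lower legs or feet + thorax.
#'
#' @return Named list of [sensor_config()] objects.
#' @export
sensor_configs <- function() {
  lower <- c("shank_L", "shank_R", "foot_L", "foot_R")
  list(
    thorax = sensor_config("Thorax", "thorax", "single"),
    pelvis = sensor_config("Pelvic", "pelvis", "single"),
    thorax_pelvis = sensor_config("Thorax and Pelvic", c("thorax", "pelvis"), "double"),
    upper_legs = sensor_config("Upper Legs", c("thigh_L", "thigh_R"), "double"),
    lower_legs = sensor_config("Lower Legs or Feet", lower, "double"),
    upper_legs_thorax = sensor_config("Upper Legs and Thorax",
                                      c("thigh_L", "thigh_R", "thorax"), "triple"),
    lower_legs_thorax = sensor_config("Lower Legs or Feet and Thorax",
                                      c(lower, "thorax"), "triple")
  )
}

#' Features available under a sensor configuration and test subset
#'
#' A motion feature is available iff its required sensors are all in the
#' configuration and its task variant is in the chosen tests (single- and
#' dual-task variants count as distinct tests). The 8 clinical features are
#' always available.
#'
#' @param catalogue The [feature_catalogue()] (or an edited copy).
#' @param config A [sensor_config()] (or a character vector of placements).
#' @param tests Character vector of task variants (e.g. `"BAL_EO_dual"`,
#'   `"TUG_single"`); see `task_variants`.
#' @return Character vector of available feature names, in catalogue order.
#' @export
available_features <- function(catalogue, config, tests) {
  placements <- if (inherits(config, "sensor_config")) config$placements else config
  ok <- map_lgl(seq_len(nrow(catalogue)), function(i) {
    if (catalogue$block[i] == "clinical") return(TRUE)
    all(catalogue$sensors[[i]] %in% placements) && catalogue$task_id[i] %in% tests
  })
  catalogue$name[ok]
}

#' Search sensor configurations crossed with test batteries
#'
#' For every (configuration, test subset of size <= `max_tests`) pair, runs
#' [forward_select()] on the features available under that pair and records
#' the best model. The report is sorted by accuracy, then specificity, then
#' sensitivity. Exhaustive (no pruning); with the default 7 configurations
#' and all subsets of the 10 task variants up to size 3 this evaluates
#' 7 x 175 selection runs, so prefer a fast classifier spec for wide
#' searches.
#'
#' @inheritParams loso_predict
#' @param configs List of [sensor_config()]s (default [sensor_configs()]).
#' @param tests Task variants to draw subsets from (default all 10).
#' @param max_tests Maximum battery size (default 3).
#'
#' @return A tibble: `config`, `arity`, `tests`, `n_tests`,
#'   `selected_features`, `accuracy`, `sensitivity`, `specificity`.
#' @export
search_configurations <- function(table, configs = sensor_configs(),
                                  tests = task_variants(), max_tests = 3,
                                  spec = model_spec()) {
  cat_tbl <- attr(table, "catalogue") %||% feature_catalogue()
  subsets <- unlist(
    map(seq_len(min(max_tests, length(tests))),
        function(k) utils::combn(tests, k, simplify = FALSE)),
    recursive = FALSE)
  rows <- map(configs, function(cfg) {
    map(subsets, function(ts) {
      feats <- available_features(cat_tbl, cfg, ts)
      fit <- forward_select(table, spec, candidates = intersect(feats, names(table)))
      tibble(config = cfg$name, arity = cfg$arity,
             tests = paste(ts, collapse = "+"), n_tests = length(ts),
             selected_features = paste(fit$selected_features, collapse = ", "),
             accuracy = fit$accuracy, sensitivity = fit$sensitivity,
             specificity = fit$specificity)
    }) |> list_rbind()
  }) |> list_rbind()
  arrange(rows, desc(.data$accuracy), desc(.data$specificity), desc(.data$sensitivity))
}
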