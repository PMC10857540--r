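# Shared fixtures, cached across test files (helpers are sourced once per
# test run; expensive cohorts are built at most once).

fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

# Minimal subject profile accepted by the simulators.
mini_profile <- function(group = "nonfaller", subject_id = "S01", latent = 1) {
  list(subject_id = subject_id, group = group, latent_mobility = latent)
}

# All effect multipliers = 1: fallers and non-fallers are exchangeable.
null_effect <- function() {
  effect_profile(sway_std_faller = 1, gait_speed_faller = 1,
                 transition_time_faller = 1, dual_task_cost_faller = 1,
                 dual_task_cost_nonfaller = 1)
}

# 3 + 3 cohort reused by the feature / io / search tests.
small_cohort <- function() {
  fixture("small_cohort", function() {
    generate_cohort(cohort_spec(n_fallers = 3, n_nonfallers = 3, seed = 42))
  })
}

small_table <- function() {
  fixture("small_table", function() assemble_feature_table(small_cohort()))
}

# The default 11 + 10 study-scale cohort (seed 1), used by the acceptance
# criteria.
full_cohort <- function() {
  fixture("full_cohort", function() generate_cohort(cohort_spec(seed = 1)))
}

full_table <- function() {
  fixture("full_table", function() assemble_feature_table(full_cohort()))
}

# Plain feature table for modeling tests: p noise features, optionally one
# column that perfectly separates the classes.
toy_table <- function(n = 12, p = 5, seed = 1, leak = FALSE) {
  set.seed(seed)
  y <- rep(0:1, each = ceiling(n / 2))[seq_len(n)]
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  if (leak) X[, 1] <- y * 4 + rnorm(n, 0, 0.01)
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%02d", seq_len(n))),
    tibble::as_tibble(X),
    tibble::tibble(label = y)
  )
}

# LOSO accuracy/sensitivity of a fixed feature set (selection-free oracle).
loso_metrics <- function(tbl, feats, spec) {
  compute_metrics(loso_predict(tbl, feats, spec))
}

fast_logistic <- function(seed = 1, max_features = 5) {
  model_spec("logistic", seed = seed, max_features = max_features)
}
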