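# Metrics, LOSO evaluation, and forward selection against brute-force oracles.

brute_metrics <- function(truth, pred) {
  tp <- 0; fn <- 0; tn <- 0; fp <- 0
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1
  }
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

test_that("compute_metrics matches a brute-force confusion loop on 1000 fixtures", {
  set.seed(123)
  for (r in 1:1000) {
    n <- sample(2:30, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, 0.5)
    m <- compute_metrics(data.frame(truth = truth, pred = pred))
    o <- brute_metrics(truth, pred)
    expect_identical(c(accuracy = m$accuracy, sensitivity = m$sensitivity,
                       specificity = m$specificity), o)
    # metric identity: accuracy = weighted mean of sens/spec
    np <- sum(truth == 1); nn <- n - np
    if (np > 0 && nn > 0) {
      expect_equal(m$accuracy, (m$sensitivity * np + m$specificity * nn) / n)
    }
  }
})

test_that("the 11/10 confusion matrix TP=9 FN=2 TN=10 FP=0 gives (0.905, 0.818, 1.000)", {
  truth <- c(rep(1, 11), rep(0, 10))
  pred <- c(rep(1, 9), rep(0, 2), rep(0, 10))
  m <- compute_metrics(data.frame(truth = truth, pred = pred))
  expect_equal(round(m$accuracy, 3), 0.905)
  expect_equal(round(m$sensitivity, 3), 0.818)
  expect_equal(round(m$specificity, 3), 1.000)
})

test_that("model_spec resolves aliases and enforces standardization", {
  expect_equal(model_spec("tree_ensemble")$classifier, "rf")
  expect_equal(model_spec("max_margin")$classifier, "svm")
  expect_equal(model_spec("lr")$classifier, "logistic")
  expect_true(model_spec("svm")$normalize)
  expect_false(model_spec("rf")$normalize)
  expect_error(model_spec("svm", normalize = FALSE), "required")
  expect_error(model_spec("boosting"), "Unknown classifier")
})

test_that("loso_predict is deterministic, one row per subject, and validates", {
  tbl <- toy_table(n = 14, leak = TRUE)
  for (clf in c("rf", "svm", "logistic")) {
    sp <- model_spec(clf, seed = 3)
    p1 <- loso_predict(tbl, c("f1", "f2"), sp)
    p2 <- loso_predict(tbl, c("f1", "f2"), sp)
    expect_identical(p1, p2)
    expect_equal(nrow(p1), 14)
    expect_equal(p1$truth, tbl$label)
  }
  expect_error(loso_predict(tbl, character(0)), "non-empty")
  expect_error(loso_predict(tbl, "nope"), "not in table")
  one_class <- dplyr::mutate(tbl, label = 1L)
  expect_error(loso_predict(one_class, "f1"), "both classes")
})

test_that("a perfectly separating feature gives LOSO accuracy 1 for every classifier", {
  tbl <- toy_table(n = 12, leak = TRUE)
  for (clf in c("rf", "svm", "logistic")) {
    m <- loso_metrics(tbl, "f1", model_spec(clf, seed = 2))
    expect_equal(m$accuracy, 1)
  }
})

test_that("forward selection matches exhaustive 1- and 2-subset enumeration", {
  # replicate the documented tie-break: accuracy, then sensitivity, then the
  # earlier candidate in catalogue order
  best_of <- function(tbl, sets, spec) {
    stats <- lapply(sets, function(s) loso_metrics(tbl, s, spec))
    acc <- vapply(stats, function(m) m$accuracy, 0)
    sens <- vapply(stats, function(m) m$sensitivity, 0)
    ord <- order(-acc, -sens, seq_along(sets))
    list(set = sets[[ord[1]]], acc = acc[ord[1]])
  }
  feats <- paste0("f", 1:5)
  for (seed in 1:6) {
    tbl <- toy_table(n = 12, p = 5, seed = 100 + seed)
    sp <- fast_logistic(seed = seed)
    fit <- forward_select(tbl, sp, candidates = feats)
    singles <- best_of(tbl, as.list(feats), sp)
    expect_equal(fit$selected_features[1], singles$set)
    expect_equal(fit$trajectory$accuracy[1], singles$acc)
    if (length(fit$selected_features) >= 2) {
      pairs <- lapply(setdiff(feats, singles$set),
                      function(f) c(singles$set, f))
      p2 <- best_of(tbl, pairs, sp)
      expect_equal(fit$selected_features[2], setdiff(p2$set, singles$set))
      expect_equal(fit$trajectory$accuracy[2], p2$acc)
      expect_gt(p2$acc, singles$acc)  # strict improvement or it stops
    } else if (singles$acc < 1) {
      # stopped after one feature: no pair containing it strictly improves
      pair_accs <- vapply(setdiff(feats, singles$set), function(f) {
        loso_metrics(tbl, c(singles$set, f), sp)$accuracy
      }, 0)
      expect_lte(max(pair_accs), singles$acc)
    }
    expect_lte(length(fit$selected_features), sp$max_features)
  }
})

test_that("a separating feature is chosen first and selection stops at accuracy 1", {
  for (seed in 1:5) {
    tbl <- toy_table(n = 12, p = 5, seed = seed, leak = TRUE)
    fit <- forward_select(tbl, fast_logistic(seed = seed))
    expect_equal(fit$selected_features, "f1")
    expect_equal(fit$accuracy, 1)
  }
})

test_that("duplicated candidates break ties to the earlier catalogue index", {
  tbl <- toy_table(n = 12, p = 2, seed = 9, leak = TRUE)
  tbl$f2 <- tbl$f1  # identical twin, later in candidate order
  fit <- forward_select(tbl, fast_logistic(), candidates = c("f1", "f2"))
  expect_equal(fit$selected_features[1], "f1")
  fit_rev <- forward_select(tbl, fast_logistic(), candidates = c("f2", "f1"))
  expect_equal(fit_rev$selected_features[1], "f2")
})

test_that("nested selection produces per-fold feature sets and honest predictions", {
  tbl <- toy_table(n = 10, p = 3, seed = 5, leak = TRUE)
  sp <- model_spec("logistic", seed = 1, selection_mode = "nested",
                   max_features = 2)
  fit <- forward_select(tbl, sp)
  expect_length(fit$fold_details, 10)
  expect_null(fit$trajectory)
  expect_equal(fit$accuracy, 1)  # the leak survives every training fold
})

test_that("ablations restrict the candidate pool to 8 / 50 features", {
  tbl <- small_table()
  sp <- fast_logistic(max_features = 2)
  ab_clin <- run_ablation(tbl, "no_motion", sp)
  expect_length(ab_clin$candidates, 8)
  expect_true(all(ab_clin$candidates %in%
                    feature_catalogue()$name[feature_catalogue()$block == "clinical"]))
  ab_nd <- run_ablation(tbl, "no_dual", sp)
  expect_length(ab_nd$candidates, 50)
  expect_false(any(grepl("^Dual_", ab_nd$candidates)))
  ab_full <- run_ablation(tbl, "full", sp)
  expect_length(ab_full$candidates, 92)
})

test_that("tidy/glance summarise a fall_eval consistently", {
  tbl <- toy_table(n = 10, p = 3, seed = 2, leak = TRUE)
  fit <- forward_select(tbl, fast_logistic())
  td <- tidy(fit)
  expect_named(td, c("subject_id", "truth", "pred", "correct"))
  gl <- glance(fit)
  expect_equal(gl$accuracy, mean(td$correct))
  expect_equal(gl$n_subjects, 10)
  expect_equal(gl$n_features, length(fit$selected_features))
})
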