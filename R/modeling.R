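# Classification of high- vs low-fall-risk subjects: leave-one-subject-out
# (LOSO) evaluation, heuristic forward feature selection, and the two
# feature-set ablations (clinical-only and no-dual-task).

CLASSIFIER_ALIASES <- c(rf = "rf", tree_ensemble = "rf",
                        svm = "svm", max_margin = "svm",
                        logistic = "logistic", lr = "logistic")

#' Model specification
#'
#' Classifier choice and evaluation settings. Feature standardization is
#' estimated on training rows only and is mandatory for the SVM and
#' logistic models; the random forest accepts either (default
#' unnormalized -- tree splits are invariant to monotone rescaling).
#'
#' @param classifier `"rf"`/`"tree_ensemble"`, `"svm"`/`"max_margin"`, or
#'   `"logistic"`/`"lr"`.
#' @param normalize Standardize features (training-fold statistics)?
#'   `NULL` picks the classifier default (TRUE for svm/logistic, FALSE for
#'   rf). Must not be FALSE for svm/logistic.
#' @param hyperparams Named list of overrides: `cost` and `kernel` (svm,
#'   defaults 1 and `"linear"`), `lambda` (logistic ridge penalty, default
#'   1/n(train)), `ntree` (rf, default 200 -- out-of-bag error is long
#'   stable at this size for cohorts of a few dozen subjects).
#' @param seed Integer seed controlling stochastic classifiers; fold seeds
#'   are derived from it.
#' @param selection_mode `"pooled"` scores candidate feature sets by their
#'   LOSO accuracy over all subjects (one global selection trajectory);
#'   `"nested"` reruns selection inside every training fold and aggregates
#'   hold-out predictions only. Pooled scores are optimistically biased;
#'   nested gives honest generalization estimates.
#' @param max_features Selection stops after this many features (default 5;
#'   top models in this setting carry 2-5 features).
#'
#' @return A `model_spec` object.
#' @export
model_spec <- function(classifier = "rf", normalize = NULL, hyperparams = list(),
                       seed = 1, selection_mode = c("pooled", "nested"),
                       max_features = 5) {
  if (!classifier %in% names(CLASSIFIER_ALIASES)) {
    abort(sprintf("Unknown classifier '%s'.", classifier))
  }
  clf <- CLASSIFIER_ALIASES[[classifier]]
  if (is.null(normalize)) normalize <- clf != "rf"
  if (!normalize && clf %in% c("svm", "logistic")) {
    abort("Standardization is required for svm and logistic models.")
  }
  structure(
    list(classifier = clf, normalize = isTRUE(normalize),
         hyperparams = hyperparams, seed = as.integer(seed),
         selection_mode = match.arg(selection_mode),
         max_features = as.integer(max_features)),
    class = "model_spec"
  )
}

# Fit on (xtr, ytr), predict labels for xte. x's are numeric matrices,
# y integer 0/1. Returns integer predictions.
fit_predict <- function(xtr, ytr, xte, spec, fold_seed) {
  # Columns constant in the training fold carry no information and the tree
  # backend's split search does not terminate on an all-constant predictor
  # set, so drop them up front. With nothing left, fall back to the training
  # majority class (ties -> the negative class), deterministically.
  keep <- apply(xtr, 2, function(col) any(col != col[1]))
  if (!any(keep)) {
    maj <- if (sum(ytr == 1) > sum(ytr == 0)) 1L else 0L
    return(rep(maj, nrow(xte)))
  }
  xtr <- xtr[, keep, drop = FALSE]
  xte <- xte[, keep, drop = FALSE]
  if (spec$normalize) {
    mu <- colMeans(xtr)
    sg <- apply(xtr, 2, sd); sg[sg == 0 | is.na(sg)] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sg, "/")
  }
  yf <- factor(ytr, levels = c(0, 1))
  hp <- spec$hyperparams
  pred <- switch(spec$classifier,
    svm = {
      fit <- e1071::svm(xtr, yf, kernel = hp$kernel %||% "linear",
                        cost = hp$cost %||% 1, scale = FALSE)
      predict(fit, xte)
    },
    logistic = {
      # ridge logistic; glmnet needs >= 2 columns, pad with a zero column
      pad <- function(m) if (ncol(m) < 2) cbind(m, `..pad` = 0) else m
      # glmnet warns about small per-class counts on every LOSO fold of a
      # small cohort; that is inherent to the protocol, so muffle just that
      # advisory rather than flooding callers with thousands of copies.
      fit <- withCallingHandlers(
        glmnet::glmnet(pad(xtr), yf, family = "binomial", alpha = 0,
                       lambda = hp$lambda %||% (1 / nrow(xtr)),
                       standardize = FALSE),
        warning = function(w) {
          if (grepl("dangerous ground", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
      predict(fit, pad(xte), type = "class")[, 1]
    },
    rf = {
      set.seed(fold_seed)
      fit <- randomForest::randomForest(xtr, yf, ntree = hp$ntree %||% 200)
      predict(fit, xte)
    })
  as.integer(as.character(pred))
}

# LOSO predictions on a plain matrix; the hot path of forward selection.
loso_matrix <- function(X, y, spec) {
  n <- nrow(X)
  pred <- integer(n)
  for (i in seq_len(n)) {
    pred[i] <- fit_predict(X[-i, , drop = FALSE], y[-i],
                           X[i, , drop = FALSE], spec, spec$seed + i)
  }
  pred
}

check_loso_pre <- function(y) {
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    abort("Each class needs >= 2 subjects so every training fold contains both classes.")
  }
}

#' Leave-one-subject-out predictions
#'
#' For each subject, fits the classifier on the remaining n - 1 subjects
#' (standardization parameters estimated on those training rows only) and
#' predicts the held-out subject. Fixed seed gives identical predictions.
#'
#' @param table Feature table from [assemble_feature_table()] (needs
#'   `subject_id`, feature columns, `label`).
#' @param features Character vector of feature columns to use (non-empty).
#' @param spec A [model_spec()].
#'
#' @return Tibble with one row per subject: `subject_id`, `truth`, `pred`.
#' @export
loso_predict <- function(table, features, spec = model_spec()) {
  if (!length(features)) abort("`features` must be non-empty.")
  miss <- setdiff(features, names(table))
  if (length(miss)) {
    abort(sprintf("Feature(s) not in table: %s.", paste(head(miss, 3), collapse = ", ")))
  }
  y <- as.integer(table$label)
  check_loso_pre(y)
  X <- as.matrix(table[, features, drop = FALSE])
  tibble(subject_id = table$subject_id, truth = y, pred = loso_matrix(X, y, spec))
}

#' Classification metrics from per-subject predictions
#'
#' Fallers (label 1) are the positive class: sensitivity = TP / (TP + FN)
#' on fallers, specificity = TN / (TN + FP) on non-fallers, accuracy =
#' (TP + TN) / n. A metric whose class is absent is reported as `NA`, never
#' as 0.
#'
#' @param per_subject Tibble/data frame with integer columns `truth` and
#'   `pred` (0/1).
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `n`.
#' @export
compute_metrics <- function(per_subject) {
  truth <- as.integer(per_subject$truth); pred <- as.integer(per_subject$pred)
  stopifnot(all(truth %in% 0:1), all(pred %in% 0:1))
  tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0); fp <- sum(truth == 0 & pred == 1)
  n <- length(truth)
  tibble(
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    n = n
  )
}

# Greedy forward selection on matrices. Candidates are evaluated in
# catalogue order; ties break to higher accuracy, then higher sensitivity,
# then the earlier (lower-index) candidate. Stops when no candidate
# strictly improves pooled LOSO accuracy, at max_features, or at perfect
# accuracy.
greedy_select <- function(X, y, candidates, spec) {
  selected <- character(0)
  best_pred <- NULL
  cur_acc <- -Inf; cur_sens <- -Inf
  traj <- list()
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining) || length(selected) >= spec$max_features) break
    step_best <- NULL
    for (f in remaining) {
      pred <- loso_matrix(X[, c(selected, f), drop = FALSE], y, spec)
      acc <- mean(pred == y)
      sens <- if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_
      better <- is.null(step_best) || acc > step_best$acc ||
        (acc == step_best$acc && isTRUE(sens > step_best$sens))
      if (better) step_best <- list(f = f, acc = acc, sens = sens, pred = pred)
    }
    if (step_best$acc <= cur_acc) break
    selected <- c(selected, step_best$f)
    cur_acc <- step_best$acc; cur_sens <- step_best$sens
    best_pred <- step_best$pred
    traj[[length(traj) + 1]] <- tibble(step = length(selected),
                                       feature = step_best$f,
                                       accuracy = cur_acc,
                                       sensitivity = cur_sens)
    if (cur_acc == 1) break
  }
  list(selected = selected, pred = best_pred,
       trajectory = if (length(traj)) list_rbind(traj) else
         tibble(step = integer(0), feature = character(0),
                accuracy = numeric(0), sensitivity = numeric(0)))
}

#' Heuristic forward feature selection under LOSO
#'
#' Step 1 evaluates every candidate feature alone and keeps the best; each
#' later step evaluates the current set plus each remaining feature and
#' keeps the best extension. Selection stops when no candidate strictly
#' improves accuracy, at `max_features`, or at perfect accuracy. In
#' `"pooled"` mode (default) a candidate set is scored by its LOSO accuracy
#' over all subjects, giving one global feature set and trajectory; in
#' `"nested"` mode selection is rerun inside every training fold and only
#' hold-out predictions are aggregated.
#'
#' @inheritParams loso_predict
#' @param candidates Candidate feature columns, in catalogue order (default:
#'   every column of `table` except `subject_id` and `label`). Ties break to
#'   the earlier candidate.
#'
#' @return A `fall_eval` object: per-subject predictions, accuracy /
#'   sensitivity / specificity, `selected_features`, the selection
#'   `trajectory` (pooled mode), and the spec used. See [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
forward_select <- function(table, spec = model_spec(), candidates = NULL) {
  candidates <- candidates %||% setdiff(names(table), c("subject_id", "label"))
  if (!length(candidates)) abort("Need at least one candidate feature.")
  miss <- setdiff(candidates, names(table))
  if (length(miss)) {
    abort(sprintf("Candidate(s) not in table: %s.", paste(head(miss, 3), collapse = ", ")))
  }
  y <- as.integer(table$label)
  check_loso_pre(y)
  X <- as.matrix(table[, candidates, drop = FALSE])
  colnames(X) <- candidates

  if (spec$selection_mode == "pooled") {
    g <- greedy_select(X, y, candidates, spec)
    per_subject <- tibble(subject_id = table$subject_id, truth = y, pred = g$pred)
    res <- list(per_subject = per_subject,
                selected_features = g$selected, trajectory = g$trajectory,
                fold_details = NULL)
  } else {
    n <- nrow(X)
    pred <- integer(n)
    fold_sets <- vector("list", n)
    for (i in seq_len(n)) {
      gi <- greedy_select(X[-i, , drop = FALSE], y[-i], candidates, spec)
      fold_sets[[i]] <- gi$selected
      pred[i] <- fit_predict(X[-i, gi$selected, drop = FALSE], y[-i],
                             X[i, gi$selected, drop = FALSE], spec, spec$seed + i)
    }
    per_subject <- tibble(subject_id = table$subject_id, truth = y, pred = pred)
    sel <- sort(table(unlist(fold_sets)), decreasing = TRUE)
    res <- list(per_subject = per_subject,
                selected_features = names(sel), trajectory = NULL,
                fold_details = fold_sets)
  }
  m <- compute_metrics(res$per_subject)
  structure(
    c(res, list(accuracy = m$accuracy, sensitivity = m$sensitivity,
                specificity = m$specificity, spec = spec,
                candidates = candidates)),
    class = "fall_eval"
  )
}

#' Feature-set ablations
#'
#' Reruns forward selection with a restricted candidate pool: `"no_motion"`
#' keeps only the 8 clinical features; `"no_dual"` drops the 42 dual-task
#' recomputations (leaving 50 candidates); `"full"` uses all 92. The
#' pipeline is otherwise identical.
#'
#' @inheritParams loso_predict
#' @param mode `"full"`, `"no_motion"` or `"no_dual"`.
#' @return A `fall_eval` (see [forward_select()]).
#' @export
run_ablation <- function(table, mode = c("full", "no_motion", "no_dual"),
                         spec = model_spec()) {
  mode <- match.arg(mode)
  cat_tbl <- attr(table, "catalogue") %||% feature_catalogue()
  cand <- switch(mode,
    full = cat_tbl$name,
    no_motion = cat_tbl$name[cat_tbl$block == "clinical"],
    no_dual = cat_tbl$name[!grepl("^Dual_", cat_tbl$name)])
  forward_select(table, spec, candidates = intersect(cand, names(table)))
}

#' @export
print.fall_eval <- function(x, ...) {
  cat(sprintf("<fall_eval> %s, %s mode: accuracy %.2f, sensitivity %.2f, specificity %.2f\n",
              x$spec$classifier, x$spec$selection_mode,
              x$accuracy, x$sensitivity, x$specificity))
  cat("selected:", paste(head(x$selected_features, 6), collapse = ", "),
      if (length(x$selected_features) > 6) "..." else "", "\n")
  invisible(x)
}

#' Tidy per-subject predictions of a fitted evaluation
#'
#' @param x A `fall_eval`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `truth`, `pred`, `correct`.
#' @export
tidy.fall_eval <- function(x, ...) {
  mutate(x$per_subject, correct = .data$truth == .data$pred)
}

#' One-row summary of a fitted evaluation
#'
#' @param x A `fall_eval`.
#' @param ... Unused.
#' @return One-row tibble: classifier, selection mode, metrics, number of
#'   selected features and subjects.
#' @export
glance.fall_eval <- function(x, ...) {
  tibble(classifier = x$spec$classifier, selection_mode = x$spec$selection_mode,
         accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity,
         n_features = length(x$selected_features),
         n_subjects = nrow(x$per_subject))
}

#' Plot the forward-selection trajectory
#'
#' Accuracy as each feature is added (pooled mode only).
#'
#' @param object A `fall_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fall_eval <- function(object, ...) {
  if (is.null(object$trajectory) || !nrow(object$trajectory)) {
    abort("No selection trajectory (nested mode or empty selection).")
  }
  ggplot(object$trajectory, aes(.data$step, .data$accuracy)) +
    geom_line() + geom_point() +
    geom_text(aes(label = .data$feature), angle = 90, hjust = 1.05, size = 2.6) +
    scale_x_continuous(breaks = object$trajectory$step) +
    coord_cartesian(ylim = c(0, 1.05)) +
    labs(x = "selection step", y = "pooled LOSO accuracy",
         title = sprintf("Forward selection (%s)", object$spec$classifier)) +
    theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
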