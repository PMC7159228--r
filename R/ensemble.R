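#' Balanced undersampling trial splits
#'
#' Builds the repeated balanced training sets the ensemble is trained on.
#' Each trial independently draws, without replacement, as many
#' majority-class compounds as there are minority-class compounds
#' (undersampling; with the default cohorts, 155 of the 164 negatives),
#' then splits each class 90/10 into training and held-out test compounds.
#' Test size is `ceiling(test_fraction * class size)`. Every trial is fully
#' reproducible from `(seed, trial index)`.
#'
#' @param positives,negatives character vectors of compound ids.
#' @param n_trials number of balanced trials (the reference protocol
#'   uses 500).
#' @param test_fraction held-out fraction per class (default 0.1).
#' @param seed master seed.
#' @return list of `trial_split` objects with elements `trial`, `seed`,
#'   `train_pos`, `train_neg`, `test_pos`, `test_neg`.
#' @export
make_balanced_trials <- function(positives, negatives, n_trials = 500,
                                 test_fraction = 0.1, seed = 1) {
  positives <- as.character(positives); negatives <- as.character(negatives)
  if (length(positives) == 0 || length(negatives) == 0)
    stop("both classes must be non-empty")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (length(negatives) < length(positives))
    message("make_balanced_trials: fewer negatives than positives; ",
            "undersampling positives instead")
  n_bal <- min(length(positives), length(negatives))
  n_test <- ceiling(test_fraction * n_bal)
  if (n_test >= n_bal) stop("test_fraction leaves no training compounds")
  lapply(seq_len(n_trials), function(t) {
    st <- derive_seed(seed, t)
    with_seed(st, {
      pos <- if (length(positives) > n_bal) sample(positives, n_bal)
             else positives
      neg <- if (length(negatives) > n_bal) sample(negatives, n_bal)
             else negatives
      test_pos <- sample(pos, n_test)
      test_neg <- sample(neg, n_test)
      structure(list(trial = t, seed = st,
                     train_pos = setdiff(pos, test_pos),
                     train_neg = setdiff(neg, test_neg),
                     test_pos = test_pos, test_neg = test_neg),
                class = "trial_split")
    })
  })
}

#' Rank features by recursive elimination with a linear SVM
#'
#' Fits the classifier on the surviving features, scores each feature by
#' its importance (linear kernel: squared weight; RBF kernel: training
#' hinge-loss increase under seeded column permutation), drops the
#' lowest-scoring block down to the next schedule size, and repeats. The
#' returned ranking is best-to-worst: survivors of the last step ordered by
#' final importance, then eliminated blocks in reverse elimination order
#' (within a block, by importance at the step that dropped them).
#'
#' @param x preprocessed training matrix (samples x features).
#' @param y labels (`"pos"`/`"neg"` or any two levels; positive =
#'   lexicographically larger unless `positive_level` given).
#' @param cost SVM cost parameter.
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param schedule strictly decreasing feature counts, starting at
#'   `ncol(x)`; default halves repeatedly down to 10. Values above
#'   `ncol(x)` are truncated with a warning.
#' @param seed used only by the RBF permutation importances.
#' @param positive_level passed to [svm_fit()].
#' @return character vector of all feature names, best first.
#' @export
rfe_rank <- function(x, y, cost = 1, kernel = c("linear", "rbf"),
                     schedule = NULL, seed = 1, positive_level = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(colnames(x))) stop("features must be named")
  if (is.null(schedule)) {
    schedule <- p
    while (schedule[length(schedule)] > 10)
      schedule <- c(schedule, max(10L, ceiling(schedule[length(schedule)] / 2)))
  } else {
    if (any(schedule > p)) {
      warning("rfe_rank: schedule values above ", p, " truncated")
      schedule <- schedule[schedule <= p]
      if (length(schedule) == 0 || schedule[1] < p)
        schedule <- c(p, schedule)
    }
    if (any(diff(schedule) >= 0)) stop("schedule must be strictly decreasing")
  }
  surviving <- colnames(x)
  eliminated <- character(0)
  for (k in seq_along(schedule)) {
    fit <- svm_fit(x[, surviving, drop = FALSE], y, cost = cost,
                   kernel = kernel, positive_level = positive_level)
    imp <- feature_importance(fit, x[, surviving, drop = FALSE], y, seed)
    ord <- order(-imp, surviving)  # ties broken by name for determinism
    surviving <- surviving[ord]
    if (k < length(schedule)) {
      n_drop <- length(surviving) - schedule[k + 1]
      dropped <- surviving[seq(length(surviving) - n_drop + 1,
                               length(surviving))]
      eliminated <- c(dropped, eliminated)
      surviving <- surviving[seq_len(schedule[k + 1])]
    }
  }
  c(surviving, eliminated)
}

feature_importance <- function(fit, x, y, seed) {
  if (fit$kernel == "linear") return(unname(fit$w^2))
  # permutation importance: growth of the training hinge loss when one
  # feature column is shuffled (one seeded permutation per feature)
  yy <- ifelse(as.character(y) == fit$positive_level, 1, -1)
  f0 <- predict(fit, x, type = "decision")
  base <- mean(pmax(0, 1 - yy * f0))
  vapply(seq_len(ncol(x)), function(j) {
    xp <- x
    xp[, j] <- with_seed(derive_seed(seed, j), sample(xp[, j]))
    mean(pmax(0, 1 - yy * predict(fit, xp, type = "decision"))) - base
  }, numeric(1))
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param truth labels; `positive` marks the positive level (default
#'   `"pos"`).
#' @param prob scores or probabilities, larger = more positive.
#' @param positive positive label value.
#' @return AUC in \[0, 1\]; `NA` if either class is absent.
#' @export
roc_auc <- function(truth, prob, positive = "pos") {
  is_pos <- as.character(truth) == positive
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Decision threshold maximizing Youden's J (sensitivity + specificity - 1)
# over the trial ROC. Candidates are 0 and the unique scores; a compound is
# called positive when prob > threshold. Among maximizers the highest
# candidate wins and the returned threshold is the midpoint to the next
# distinct score, which centers it between the classes.
youden_threshold <- function(truth, prob, positive = "pos") {
  is_pos <- as.character(truth) == positive
  u <- sort(unique(c(0, prob)))
  j <- vapply(u, function(t) {
    pred <- prob > t
    sens <- if (sum(is_pos)) mean(pred[is_pos]) else NA_real_
    spec <- if (sum(!is_pos)) mean(!pred[!is_pos]) else NA_real_
    sens + spec - 1
  }, numeric(1))
  best <- max(j)
  t0 <- max(u[j >= best - 1e-12])
  above <- prob[prob > t0]
  if (length(above)) (t0 + min(above)) / 2 else (t0 + 1) / 2
}

#' Confusion-matrix metrics at a probability threshold
#'
#' A compound is predicted positive when its probability strictly exceeds
#' the threshold. PPV with zero predicted positives is reported as `NA`,
#' not 0.
#'
#' @param truth labels; `positive` marks the positive level.
#' @param prob probabilities in \[0, 1\].
#' @param threshold decision threshold.
#' @param positive positive label value (default `"pos"`).
#' @return named list: `sensitivity`, `specificity`, `fpr`, `fnr`,
#'   `accuracy`, `ppv`.
#' @export
confusion_metrics <- function(truth, prob, threshold, positive = "pos") {
  if (length(truth) == 0) stop("empty input")
  if (length(truth) != length(prob)) stop("truth/prob length mismatch")
  is_pos <- as.character(truth) == positive
  pred <- prob > threshold
  tp <- sum(pred & is_pos); fn <- sum(!pred & is_pos)
  tn <- sum(!pred & !is_pos); fp <- sum(pred & !is_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       fpr = if (is.na(spec)) NA_real_ else 1 - spec,
       fnr = if (is.na(sens)) NA_real_ else 1 - sens,
       accuracy = (tp + tn) / length(truth),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Fit and evaluate one balanced trial
#'
#' Preprocessing (degenerate-feature removal, median imputation,
#' standardization) is fitted on the trial's training compounds only and
#' applied to its held-out compounds. Features are ranked by [rfe_rank()]
#' on the training data, the `top` best are retained, the SVM is fitted at
#' `cost`, and held-out probabilities give the ROC/AUC. The trial's
#' decision probability is the Youden-J-optimal ROC threshold; confusion
#' metrics are computed there. A held-out set that ends up single-class
#' leaves AUC undefined: the trial is flagged and excluded from averages.
#'
#' @param split a `trial_split`.
#' @param features raw descriptor matrix (rownames = compound ids).
#' @param labels named vector of `"pos"`/`"neg"` per compound id.
#' @param params list with `cost`, `top`, and optionally `kernel`
#'   (default `"linear"`).
#' @param ranking optional precomputed ranking (as from [rfe_rank()] on
#'   this trial's scaled training data) to avoid recomputation in grids.
#' @return list of class `trial_result`: `params`, `selected_features`,
#'   `metrics`, `decision_probability`, `flagged`, `trial`.
#' @export
fit_trial <- function(split, features, labels, params, ranking = NULL) {
  kernel <- params$kernel %||% "linear"
  train_ids <- c(split$train_pos, split$train_neg)
  test_ids <- c(split$test_pos, split$test_neg)
  prep <- preprocess_descriptors(features[train_ids, , drop = FALSE])
  xtr <- prep$x
  ytr <- labels[train_ids]
  if (is.null(ranking))
    ranking <- rfe_rank(xtr, ytr, cost = params$cost, kernel = kernel,
                        seed = split$seed, positive_level = "pos")
  top <- min(params$top, length(ranking))
  sel <- ranking[seq_len(top)]
  fit <- svm_fit(xtr[, sel, drop = FALSE], ytr, cost = params$cost,
                 kernel = kernel, positive_level = "pos")
  xte <- apply_scaling(prep$scaling, features[test_ids, , drop = FALSE])
  prob <- predict(fit, xte[, sel, drop = FALSE])
  yte <- labels[test_ids]
  auc <- roc_auc(yte, prob)
  if (is.na(auc)) {
    return(structure(list(params = params, selected_features = sel,
                          metrics = list(auc = NA_real_), flagged = TRUE,
                          decision_probability = NA_real_,
                          trial = split$trial), class = "trial_result"))
  }
  thr <- youden_threshold(yte, prob)
  m <- confusion_metrics(yte, prob, thr)
  structure(list(params = params, selected_features = sel,
                 metrics = c(list(auc = auc), m), flagged = FALSE,
                 decision_probability = thr, trial = split$trial),
            class = "trial_result")
}

#' Run all trials at fixed parameters
#'
#' @inheritParams fit_trial
#' @param trials list of `trial_split` from [make_balanced_trials()].
#' @return list of `trial_result`.
#' @export
run_trials <- function(trials, features, labels, params) {
  lapply(trials, fit_trial, features = features, labels = labels,
         params = params)
}

metric_names <- c("auc", "sensitivity", "specificity", "fpr", "fnr",
                  "accuracy", "ppv")

average_trials <- function(results) {
  ok <- !vapply(results, `[[`, logical(1), "flagged")
  if (!any(ok))
    return(c(setNames(rep(NA_real_, length(metric_names)), metric_names),
             decision_probability = NA_real_, n_trials_used = 0))
  mm <- vapply(results[ok], function(r)
    vapply(metric_names, function(nm)
      as.numeric(r$metrics[[nm]] %||% NA_real_), numeric(1)),
    numeric(length(metric_names)))
  thr <- vapply(results[ok], `[[`, numeric(1), "decision_probability")
  c(rowMeans(mm, na.rm = TRUE),
    decision_probability = mean(thr), n_trials_used = sum(ok))
}

#' Grid search over (cost, top) with trial-averaged performance
#'
#' Every `(cost, top)` combination is evaluated on every balanced trial
#' (splits are fixed once and reused across the grid), each metric is
#' arithmetically averaged over the trials, and the combination maximizing
#' the averaged AUC is selected — ties broken by smaller `top`, then
#' smaller `cost` (parsimony). Feature rankings are computed once per
#' (trial, cost) and shared across `top` values, which does not change any
#' result because elimination below `top` never affects the top of the
#' ranking.
#'
#' @inheritParams fit_trial
#' @param trials list of `trial_split`.
#' @param cost_grid positive costs (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param top_grid feature counts (defaults scale to the matrix width).
#' @param kernel `"linear"` or `"rbf"`.
#' @param verbose print per-cell progress.
#' @return object of class `dili_grid`: `grid` (one row per cell with
#'   averaged metrics), `best_params`, `best_trials` (the `trial_result`s
#'   at the best cell), `n_trials`.
#' @export
grid_search <- function(trials, features, labels,
                        cost_grid = c(0.01, 0.1, 1, 10, 100),
                        top_grid = NULL, kernel = "linear",
                        verbose = FALSE) {
  if (length(cost_grid) == 0 || (!is.null(top_grid) && length(top_grid) == 0))
    stop("grids must be non-empty")
  p <- ncol(features)
  if (is.null(top_grid))
    top_grid <- unique(pmin(c(5, 10, 15, 20, 30, 50, 100, 200, 400, p), p))
  if (any(top_grid > p)) {
    warning("grid_search: dropping top values above ", p, " features")
    top_grid <- top_grid[top_grid <= p]
  }
  cost_grid <- sort(unique(cost_grid)); top_grid <- sort(unique(top_grid))

  cells <- expand.grid(cost = cost_grid, top = top_grid,
                       KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(cells))
  for (i in seq_along(results)) results[[i]] <- vector("list", length(trials))

  for (ti in seq_along(trials)) {
    split <- trials[[ti]]
    train_ids <- c(split$train_pos, split$train_neg)
    prep <- preprocess_descriptors(features[train_ids, , drop = FALSE])
    for (cost in cost_grid) {
      ranking <- rfe_rank(prep$x, labels[train_ids], cost = cost,
                          kernel = kernel, seed = split$seed,
                          positive_level = "pos")
      for (top in top_grid) {
        ci <- which(cells$cost == cost & cells$top == top)
        results[[ci]][[ti]] <- fit_trial(
          split, features, labels,
          params = list(cost = cost, top = top, kernel = kernel),
          ranking = ranking)
      }
    }
    if (verbose && ti %% 10 == 0)
      message("grid_search: trial ", ti, "/", length(trials))
  }

  avg <- t(vapply(results, average_trials, numeric(length(metric_names) + 2)))
  grid <- cbind(cells, as.data.frame(avg))
  usable <- !is.na(grid$auc)
  if (!any(usable)) stop("every grid cell had only degenerate trials")
  if (any(!usable))
    message("grid_search: ", sum(!usable), " cell(s) had no usable trial")
  ord <- order(-grid$auc, grid$top, grid$cost, na.last = TRUE)
  best_i <- ord[1]
  best_params <- list(cost = grid$cost[best_i], top = grid$top[best_i],
                      kernel = kernel)
  structure(list(grid = grid, best_params = best_params,
                 best_trials = results[[best_i]],
                 n_trials = length(trials)),
            class = "dili_grid")
}

#' @export
print.dili_grid <- function(x, ...) {
  cat("dili_grid:", nrow(x$grid), "cells x", x$n_trials, "trials\n")
  cat("best: cost =", x$best_params$cost, "top =", x$best_params$top,
      "| averaged AUC =",
      signif(x$grid$auc[x$grid$cost == x$best_params$cost &
                          x$grid$top == x$best_params$top], 3), "\n")
  invisible(x)
}
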