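#' Feature selection frequency across trials
#'
#' Counts, for each descriptor, the number of trials (at one fixed
#' parameter combination) whose selected top set contains it, and records
#' its mean within-trial rank for tie-breaking. This is the frequency
#' distribution the consensus feature set is read off.
#'
#' @param trial_results list of `trial_result` sharing the same `params`.
#' @return data.frame of class `frequency_table` with columns `feature`,
#'   `count`, `mean_rank`, sorted by decreasing count; attribute
#'   `n_trials`.
#' @export
feature_frequency <- function(trial_results) {
  if (length(trial_results) == 0) stop("no trial results")
  key <- vapply(trial_results, function(r)
    paste(r$params$cost, r$params$top, r$params$kernel %||% "linear"),
    character(1))
  if (length(unique(key)) != 1)
    stop("all trial results must share the same (cost, top) parameters")
  feats <- unlist(lapply(trial_results, `[[`, "selected_features"))
  ranks <- unlist(lapply(trial_results, function(r)
    seq_along(r$selected_features)))
  count <- tapply(ranks, feats, length)
  mean_rank <- tapply(ranks, feats, mean)
  out <- data.frame(feature = names(count),
                    count = as.integer(count),
                    mean_rank = as.numeric(mean_rank),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$mean_rank, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_trials") <- length(trial_results)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Consensus feature set: top-k by selection frequency
#'
#' Ties on count are broken by better (smaller) mean within-trial rank,
#' then lexicographic feature name, so the selection is deterministic.
#'
#' @param freq a `frequency_table`.
#' @param k number of consensus features (the reference model uses 15).
#' @return ordered character vector of length `k`.
#' @export
select_consensus_features <- function(freq, k) {
  if (k > nrow(freq))
    stop("k = ", k, " exceeds the ", nrow(freq), " features ever selected")
  freq$feature[seq_len(k)]
}

#' Fit the final deployable model on the full labeled pool
#'
#' Refits preprocessing and the SVM on all positive and all negative
#' compounds (no undersampling; the class imbalance left after cohort
#' construction is absorbed by inverse-class-frequency weights on `cost`),
#' restricted to the consensus features. The decision threshold defaults to
#' the mean per-trial Youden threshold at the best parameters — the
#' ensemble's averaged probability separating positives from negatives.
#'
#' @param features raw descriptor matrix (rownames = compound ids).
#' @param labels named `"pos"`/`"neg"` vector; only named compounds are
#'   used.
#' @param consensus_features ordered feature names from
#'   [select_consensus_features()].
#' @param cost SVM cost at the best grid cell.
#' @param threshold decision probability; if `NULL`, computed from
#'   `trial_results`.
#' @param trial_results optional `trial_result` list used to derive the
#'   threshold (mean over non-flagged trials).
#' @param kernel `"linear"` or `"rbf"`.
#' @param provenance free-form list recorded on the model (seed, grid,
#'   label source).
#' @return object of class `dili_model`.
#' @export
fit_final_model <- function(features, labels, consensus_features, cost = 1,
                            threshold = NULL, trial_results = NULL,
                            kernel = "linear", provenance = list()) {
  if (is.null(threshold)) {
    if (is.null(trial_results))
      stop("supply either `threshold` or `trial_results`")
    thr <- vapply(trial_results, `[[`, numeric(1), "decision_probability")
    threshold <- mean(thr[!vapply(trial_results, `[[`, logical(1),
                                  "flagged")])
  }
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  ids <- names(labels)
  missing_feats <- setdiff(consensus_features, colnames(features))
  if (length(missing_feats) > 0)
    stop("consensus features absent from matrix: ",
         paste(missing_feats, collapse = ", "))
  prep <- preprocess_descriptors(
    features[ids, consensus_features, drop = FALSE])
  y <- labels[ids]
  n_pos <- sum(y == "pos"); n_neg <- sum(y == "neg")
  cw <- c(pos = length(y) / (2 * n_pos), neg = length(y) / (2 * n_neg))
  fit <- svm_fit(prep$x, y, cost = cost, kernel = kernel,
                 class_weights = cw, positive_level = "pos")
  structure(list(consensus_features = prep$scaling$features,
                 scaling = prep$scaling, svm = fit,
                 threshold = threshold, cost = cost, kernel = kernel,
                 provenance = c(provenance,
                                list(n_pos = n_pos, n_neg = n_neg,
                                     class_weights = as.list(cw)))),
            class = "dili_model")
}

#' Predict DILI liability probabilities for new compounds
#'
#' @param object a `dili_model`.
#' @param newdata raw descriptor matrix containing the model's consensus
#'   features (rownames = compound ids).
#' @param threshold override the model's stored decision threshold.
#' @param ... unused.
#' @return data.frame `compound_id`, `probability`, `label`
#'   (`"pos"` when probability > threshold).
#' @export
predict.dili_model <- function(object, newdata, threshold = NULL, ...) {
  threshold <- threshold %||% object$threshold
  xs <- apply_scaling(object$scaling, newdata)
  prob <- predict(object$svm, xs)
  data.frame(compound_id = rownames(newdata) %||%
               paste0("compound", seq_len(nrow(newdata))),
             probability = prob,
             label = ifelse(prob > threshold, "pos", "neg"),
             stringsAsFactors = FALSE)
}

#' @export
print.dili_model <- function(x, ...) {
  cat("dili_model:", length(x$consensus_features), "consensus features,",
      x$kernel, "kernel, cost =", x$cost, "\n")
  cat("  decision threshold:", signif(x$threshold, 3), "\n")
  cat("  trained on", x$provenance$n_pos, "positives /",
      x$provenance$n_neg, "negatives\n")
  invisible(x)
}

#' Persist / restore a final model as a plain-text directory
#'
#' Writes `model.json` (classifier parameters, threshold, provenance),
#' `scaling.json` and `features.txt`. The round trip preserves predictions
#' exactly (full-precision JSON numbers).
#'
#' @param model a `dili_model`.
#' @param dir output directory (created if needed).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  svm <- model$svm
  svm_out <- list(kernel = svm$kernel, cost = svm$cost, b = svm$b,
                  platt = as.list(svm$platt),
                  positive_level = svm$positive_level, levels = svm$levels,
                  features = svm$features)
  if (svm$kernel == "linear") {
    svm_out$w <- as.list(svm$w)
  } else {
    svm_out$gamma <- svm$gamma
    svm_out$sv_coef <- svm$sv_coef
    svm_out$sv_x <- apply(svm$sv_x, 1, as.list)
  }
  jsonlite::write_json(list(threshold = model$threshold, cost = model$cost,
                            kernel = model$kernel,
                            provenance = model$provenance, svm = svm_out),
                       file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write_scaling(model$scaling, file.path(dir, "scaling.json"))
  writeLines(model$consensus_features, file.path(dir, "features.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  raw <- jsonlite::read_json(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  sv <- raw$svm
  fit <- list(kernel = sv$kernel, cost = sv$cost, b = sv$b,
              platt = c(A = sv$platt$A, B = sv$platt$B),
              positive_level = sv$positive_level, levels = sv$levels,
              features = sv$features)
  if (sv$kernel == "linear") {
    fit$w <- setNames(as.numeric(sv$w), names(sv$w))
  } else {
    fit$gamma <- sv$gamma
    fit$sv_coef <- as.numeric(sv$sv_coef)
    fit$sv_x <- matrix(unlist(lapply(sv$sv_x, as.numeric)),
                       nrow = length(sv$sv_x), byrow = TRUE,
                       dimnames = list(NULL, sv$features))
  }
  class(fit) <- "dili_svm"
  structure(list(consensus_features = readLines(file.path(dir,
                                                          "features.txt")),
                 scaling = read_scaling(file.path(dir, "scaling.json")),
                 svm = fit, threshold = raw$threshold, cost = raw$cost,
                 kernel = raw$kernel, provenance = raw$provenance),
            class = "dili_model")
}
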