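# Cost-sensitive random-forest classification under stratified 10-fold CV.
# Class imbalance is handled by a misclassification-cost matrix: training
# uses per-class instance weights proportional to the cost of misclassifying
# that class, and hard labels come from the expected-cost-minimizing
# threshold t* = cost_fp / (cost_fp + cost_fn) on the positive-class score.

#' Misclassification cost matrix
#'
#' Default costs encode that missing a nodal metastasis (false negative,
#' cost 0.59) is worse than a false alarm (false positive, cost 0.41);
#' correct predictions cost nothing.
#'
#' @param cost_fn Cost of a false negative (default 0.59).
#' @param cost_fp Cost of a false positive (default 0.41).
#' @return A list of class `cost_matrix` with the costs and the implied
#'   decision threshold `threshold = cost_fp / (cost_fp + cost_fn)`.
#' @export
cost_matrix <- function(cost_fn = 0.59, cost_fp = 0.41) {
  if (cost_fn < 0 || cost_fp < 0) abort("Costs must be nonnegative.")
  if (cost_fn + cost_fp <= 0) abort("At least one cost must be positive.")
  structure(list(cost_fn = cost_fn, cost_fp = cost_fp,
                 threshold = cost_fp / (cost_fn + cost_fp)),
            class = "cost_matrix")
}

#' ROC curve and AUC by the Mann-Whitney construction
#'
#' The AUC equals the probability that a randomly chosen positive case
#' outscores a randomly chosen negative one, with ties counting one half;
#' the trapezoidal area under the empirical ROC over all score thresholds
#' equals the same quantity.
#'
#' @param scores Numeric positive-class scores.
#' @param labels Binary 0/1 labels (both classes present).
#' @return List with `auc` and `roc`, a tibble of `(threshold, fpr, tpr)`
#'   points (monotone non-decreasing, from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))  # tie groups share one ROC point
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- tibble(threshold = c(Inf, s[last]),
                fpr = c(0, fp[last] / n_neg),
                tpr = c(0, tp[last] / n_pos))
  list(auc = auc, roc = roc)
}

#' Cost-sensitive cross-validated evaluation
#'
#' Stratified k-fold CV of a cost-sensitive random forest on the given
#' feature subset: every case is scored exactly once out-of-fold. Training
#' weights are `cost_fn` for positive and `cost_fp` for negative cases and
#' hard labels use the cost-optimal threshold (score strictly greater than
#' `t*`); with equal costs the model reduces exactly to the unweighted
#' forest with the 0.5 threshold. Fold partitions are seeded independently
#' of any selection seed.
#'
#' @param data Tibble with `case_id` (optional), 0/1 `label` and feature
#'   columns.
#' @param features Character vector of feature columns to use (e.g. a
#'   signature); default all.
#' @param cost A [cost_matrix()].
#' @param folds Number of CV folds (default 10).
#' @param num_trees Trees per forest (default 500).
#' @param seed Integer seed.
#' @return An object of class `ln_cv_eval`: list with `cases` (per-case
#'   out-of-fold tibble: label, score, fold, predicted), `confusion`
#'   (tp/fp/tn/fn with the node-positive class as positive), `accuracy`,
#'   `auc`, `roc`, `cost`, `threshold`, `n`.
#' @export
cost_sensitive_cv <- function(data, features = feature_columns(data),
                              cost = cost_matrix(), folds = 10L,
                              num_trees = 500L, seed = 1L) {
  missing_f <- setdiff(features, names(data))
  if (length(missing_f))
    abort(paste0("Features absent from `data`: ",
                 paste(head(missing_f, 5), collapse = ", "), "."))
  fold_id <- stratified_folds(data$label, folds, derive_seed(seed, 977L))
  scores <- numeric(nrow(data))
  equal_costs <- isTRUE(all.equal(cost$cost_fn, cost$cost_fp))
  for (k in seq_len(folds)) {
    train <- data[fold_id != k, , drop = FALSE]
    w <- if (equal_costs) NULL else
      ifelse(train$label == 1, cost$cost_fn, cost$cost_fp)
    fit <- fit_rf(train, features, num_trees, derive_seed(seed, 3000L + k),
                  case_weights = w)
    scores[fold_id == k] <- rf_scores(fit, data[fold_id == k, , drop = FALSE],
                                      features)
  }
  predicted <- as.integer(scores > cost$threshold)
  ra <- roc_auc(scores, data$label)
  confusion <- c(tp = sum(predicted == 1 & data$label == 1),
                 fp = sum(predicted == 1 & data$label == 0),
                 tn = sum(predicted == 0 & data$label == 0),
                 fn = sum(predicted == 0 & data$label == 1))
  structure(list(
    cases = tibble(case_id = if ("case_id" %in% names(data)) data$case_id else
                     as.character(seq_len(nrow(data))),
                   label = as.integer(data$label), score = scores,
                   fold = fold_id, predicted = predicted),
    confusion = confusion,
    accuracy = unname((confusion["tp"] + confusion["tn"]) / nrow(data)),
    auc = ra$auc, roc = ra$roc, cost = cost, threshold = cost$threshold,
    n = nrow(data)), class = "ln_cv_eval")
}

#' @export
print.ln_cv_eval <- function(x, ...) {
  cat(sprintf("<ln_cv_eval> n = %d, AUC = %.3f, accuracy = %.3f\n",
              x$n, x$auc, x$accuracy))
  cat(sprintf("  confusion (positive = node-positive): TP %d  FP %d  TN %d  FN %d\n",
              x$confusion["tp"], x$confusion["fp"], x$confusion["tn"],
              x$confusion["fn"]))
  invisible(x)
}

#' @method tidy ln_cv_eval
#' @export
tidy.ln_cv_eval <- function(x, ...) x$cases

#' @method glance ln_cv_eval
#' @export
glance.ln_cv_eval <- function(x, ...) {
  s <- summarize_eval(x)
  s[, c("tp", "fp", "tn", "fn", "accuracy", "accuracy_lo", "accuracy_hi",
        "auc", "auc_lo", "auc_hi")]
}

#' Performance summary of a cross-validated evaluation
#'
#' Emits a one-row report in the style of a published results table: confusion
#' counts with within-class percentages, accuracy with a 95% Wilson interval
#' and AUC with a 95% DeLong interval. Counts are reported in both
#' orientations: `tp/fn` count node-positive cases (sensitivity row) and
#' `neg_tp/neg_fn` count node-negative cases treated as the "positive" class,
#' the counting convention some reports use for the majority class.
#'
#' @param x An `ln_cv_eval`, or a named confusion vector/list with elements
#'   `tp`, `fp`, `tn`, `fn` (percent bookkeeping only; no AUC without
#'   scores).
#' @param conf Confidence level (default 0.95).
#' @return A one-row tibble.
#' @export
summarize_eval <- function(x, conf = 0.95) {
  if (inherits(x, "ln_cv_eval")) {
    cm <- as.list(x$confusion)
    ci_auc <- tryCatch(
      as.numeric(pROC::ci.auc(pROC::roc(x$cases$label, x$cases$score,
                                        quiet = TRUE, direction = "<"),
                              conf.level = conf, method = "delong")),
      error = function(e) c(NA_real_, x$auc, NA_real_))
    auc <- x$auc
  } else {
    cm <- as.list(x)
    ci_auc <- c(NA_real_, NA_real_, NA_real_)
    auc <- NA_real_
  }
  n <- cm$tp + cm$fp + cm$tn + cm$fn
  acc <- (cm$tp + cm$tn) / n
  ci_acc <- wilson_ci(cm$tp + cm$tn, n, conf)
  tibble(
    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
    tp_pct = 100 * cm$tp / (cm$tp + cm$fn),
    fn_pct = 100 * cm$fn / (cm$tp + cm$fn),
    tn_pct = 100 * cm$tn / (cm$tn + cm$fp),
    fp_pct = 100 * cm$fp / (cm$tn + cm$fp),
    sensitivity = cm$tp / (cm$tp + cm$fn),
    specificity = cm$tn / (cm$tn + cm$fp),
    neg_tp = cm$tn, neg_fp = cm$fn, neg_tn = cm$tp, neg_fn = cm$fp,
    accuracy = acc, accuracy_lo = ci_acc[["lower"]],
    accuracy_hi = ci_acc[["upper"]],
    auc = auc, auc_lo = ci_auc[1], auc_hi = ci_auc[3]
  )
}

#' ROC plot of a cross-validated evaluation
#'
#' @param object An `ln_cv_eval`.
#' @param ... Unused.
#' @return A ggplot of the pooled out-of-fold ROC curve with the AUC in the
#'   subtitle.
#' @method autoplot ln_cv_eval
#' @export
autoplot.ln_cv_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  title = "Pooled out-of-fold ROC",
                  subtitle = sprintf("AUC = %.3f (n = %d)", object$auc,
                                     object$n)) +
    ggplot2::theme_minimal()
}
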