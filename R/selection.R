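# Wrapper feature selection: best-first search over feature subsets, scored
# by the inner 5-fold cross-validated AUC of a random forest, nested inside
# an outer CV loop whose test folds are never touched by the search. The
# signature keeps features selected in at least 20% of the outer folds.

#' Wrapper selection configuration
#'
#' @param outer_folds Outer CV folds (default 10).
#' @param inner_folds Inner CV folds used to score subsets (default 5).
#' @param frequency_threshold Minimum selection frequency across outer folds
#'   for a feature to enter the signature (default 0.20).
#' @param max_stale Best-first stop rule: consecutive node expansions without
#'   improvement of the global best score (default 5).
#' @param num_trees Trees per random forest evaluated (ranger default 500;
#'   simulation studies may lower this).
#' @param seed Integer seed driving folds and forests.
#' @return A list of class `wrapper_config`.
#' @export
wrapper_config <- function(outer_folds = 10L, inner_folds = 5L,
                           frequency_threshold = 0.20, max_stale = 5L,
                           num_trees = 500L, seed = 1L) {
  if (frequency_threshold <= 0 || frequency_threshold > 1)
    abort("`frequency_threshold` must lie in (0, 1].")
  if (outer_folds < 2L || inner_folds < 2L) abort("Fold counts must be >= 2.")
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 frequency_threshold = frequency_threshold,
                 max_stale = as.integer(max_stale),
                 num_trees = as.integer(num_trees),
                 seed = as.integer(seed)),
            class = "wrapper_config")
}

feature_columns <- function(data) {
  setdiff(names(data), c("case_id", "label"))
}

fit_rf <- function(train, features, num_trees, seed, case_weights = NULL) {
  x <- as.data.frame(train[features])
  y <- factor(train$label, levels = c(0, 1))
  ranger::ranger(x = x, y = y, num.trees = num_trees, probability = TRUE,
                 seed = seed, num.threads = 1L,
                 case.weights = case_weights)
}

rf_scores <- function(fit, data, features) {
  p <- predict(fit, data = as.data.frame(data[features]),
               num.threads = 1L)$predictions
  p[, "1"]
}

#' Inner cross-validated AUC of a feature subset
#'
#' Mean out-of-fold AUC over `inner_folds` stratified folds of a random
#' forest trained on the given features. Deterministic for a fixed seed.
#'
#' @param data Tibble with a 0/1 `label` column and feature columns.
#' @param features Character vector of feature names (nonempty).
#' @param config A [wrapper_config()].
#' @param seed Seed for the fold split and forests (defaults to the config
#'   seed).
#' @return A single AUC value.
#' @export
inner_cv_auc <- function(data, features, config = wrapper_config(),
                         seed = config$seed) {
  if (length(features) == 0L) abort("`features` must be nonempty.")
  folds <- stratified_folds(data$label, config$inner_folds, seed)
  aucs <- vapply(seq_len(config$inner_folds), function(k) {
    train <- data[folds != k, , drop = FALSE]
    test <- data[folds == k, , drop = FALSE]
    fit <- fit_rf(train, features, config$num_trees, derive_seed(seed, k))
    roc_auc(rf_scores(fit, test, features), test$label)$auc
  }, numeric(1))
  mean(aucs)
}

#' Best-first search over feature subsets
#'
#' Forward best-first graph search: starting from the empty set, subsets are
#' expanded by single-feature additions; the open node with the highest inner
#' CV AUC is expanded next (which permits backtracking to earlier branches).
#' The search stops after `max_stale` consecutive expansions that fail to
#' improve the global best score, and returns the highest-scoring subset,
#' breaking ties in favour of smaller subsets and then lexicographic feature
#' order. Subset scores are cached, so each subset is evaluated once.
#'
#' @param data Training split: tibble with `label` and feature columns.
#' @param config A [wrapper_config()].
#' @param features Candidate pool (default: all feature columns).
#' @param seed Seed for subset evaluation (defaults to the config seed).
#' @return Character vector of selected features, with attributes `score`
#'   (its inner CV AUC) and `n_evaluated` (number of distinct subsets
#'   scored).
#' @export
best_first_search <- function(data, config = wrapper_config(),
                              features = feature_columns(data),
                              seed = config$seed) {
  if (length(features) < 2L) abort("Need at least 2 candidate features.")
  features <- sort(features)
  eps <- 1e-6
  cache <- new.env(parent = emptyenv())
  evaluate <- function(subset) {
    key <- paste(subset, collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- inner_cv_auc(data, subset, config, seed)
    cache[[key]] <- val
    val
  }

  open_sets <- list(character(0))
  open_scores <- -Inf
  expanded <- character(0)
  best_set <- character(0)
  best_score <- -Inf
  stale <- 0L
  n_eval <- 0L

  better_tie <- function(set_a, score_a, set_b, score_b) {
    # is (a) preferable to (b)?
    if (score_a > score_b + eps) return(TRUE)
    if (score_b > score_a + eps) return(FALSE)
    if (length(set_a) != length(set_b)) return(length(set_a) < length(set_b))
    paste(set_a, collapse = ",") < paste(set_b, collapse = ",")
  }

  while (length(open_sets) > 0L && stale < config$max_stale) {
    pick <- 1L
    for (i in seq_along(open_sets))
      if (better_tie(open_sets[[i]], open_scores[i],
                     open_sets[[pick]], open_scores[pick])) pick <- i
    node <- open_sets[[pick]]
    open_sets <- open_sets[-pick]
    open_scores <- open_scores[-pick]
    key <- paste(node, collapse = "\r")
    if (key %in% expanded) next
    expanded <- c(expanded, key)

    improved <- FALSE
    for (f in setdiff(features, node)) {
      child <- sort(c(node, f))
      ckey <- paste(child, collapse = "\r")
      if (!is.null(cache[[ckey]])) next
      sc <- evaluate(child)
      n_eval <- n_eval + 1L
      open_sets <- c(open_sets, list(child))
      open_scores <- c(open_scores, sc)
      if (better_tie(child, sc, best_set, best_score)) {
        if (sc > best_score + eps) improved <- TRUE
        best_set <- child
        best_score <- sc
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(best_set, score = best_score, n_evaluated = n_eval)
}

#' Nested-CV wrapper selection with a stability rule
#'
#' Runs [best_first_search()] on the training split of each outer fold (the
#' outer test folds are never seen by the search), records the per-fold
#' subsets, and returns the signature of features selected in at least
#' `frequency_threshold` of the outer folds.
#'
#' @param data Full cohort feature table (tibble with `case_id`, `label` and
#'   feature columns).
#' @param config A [wrapper_config()].
#' @param features Candidate pool (default: all feature columns).
#' @return An object of class `ln_signature`: list with `features`,
#'   `frequency` (tibble of per-feature selection frequencies),
#'   `fold_subsets` (audit trail), `fold_test_ids` (leakage audit),
#'   `config`.
#' @export
nested_selection <- function(data, config = wrapper_config(),
                             features = feature_columns(data)) {
  folds <- stratified_folds(data$label, config$outer_folds,
                            derive_seed(config$seed, 523L))
  ids <- if ("case_id" %in% names(data)) data$case_id else
    as.character(seq_len(nrow(data)))
  fold_subsets <- vector("list", config$outer_folds)
  fold_test_ids <- vector("list", config$outer_folds)
  for (k in seq_len(config$outer_folds)) {
    train <- data[folds != k, , drop = FALSE]
    fold_test_ids[[k]] <- ids[folds == k]
    stopifnot(length(intersect(ids[folds != k], fold_test_ids[[k]])) == 0L)
    fold_subsets[[k]] <- as.character(
      best_first_search(train, config, features, seed = derive_seed(config$seed, k)))
  }
  freq <- selection_frequencies(fold_subsets, features)
  selected <- freq$feature[freq$frequency >= config$frequency_threshold]
  if (length(selected) == 0L)
    abort("No feature reached the selection-frequency threshold; lower `frequency_threshold`.")
  structure(list(features = selected, frequency = freq,
                 fold_subsets = fold_subsets, fold_test_ids = fold_test_ids,
                 config = config),
            class = "ln_signature")
}

#' Selection frequencies from a per-fold audit trail
#'
#' @param fold_subsets List of per-fold selected feature vectors.
#' @param features Full candidate pool.
#' @return Tibble with `feature` and `frequency`, sorted by decreasing
#'   frequency then name.
#' @export
selection_frequencies <- function(fold_subsets, features) {
  counts <- table(factor(unlist(fold_subsets), levels = sort(features)))
  out <- tibble(feature = names(counts),
                frequency = as.numeric(counts) / length(fold_subsets))
  dplyr::arrange(out, dplyr::desc(.data$frequency), .data$feature)
}

#' @export
print.ln_signature <- function(x, ...) {
  cat(sprintf("<ln_signature> %d feature(s), threshold %.2f over %d outer folds\n",
              length(x$features), x$config$frequency_threshold,
              x$config$outer_folds))
  sel <- x$frequency[x$frequency$feature %in% x$features, ]
  for (i in seq_len(nrow(sel)))
    cat(sprintf("  %-28s %.0f%%\n", sel$feature[i], 100 * sel$frequency[i]))
  invisible(x)
}

#' @method tidy ln_signature
#' @export
tidy.ln_signature <- function(x, ...) {
  dplyr::mutate(x$frequency, selected = .data$feature %in% x$features)
}

#' @method glance ln_signature
#' @export
glance.ln_signature <- function(x, ...) {
  tibble(n_selected = length(x$features),
         n_candidates = nrow(x$frequency),
         frequency_threshold = x$config$frequency_threshold,
         outer_folds = x$config$outer_folds)
}

#' Selection-frequency plot of a signature
#'
#' @param object An `ln_signature`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-feature selection frequencies with the
#'   stability threshold marked.
#' @method autoplot ln_signature
#' @export
autoplot.ln_signature <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$frequency > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$frequency),
    y = .data$frequency, fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$config$frequency_threshold,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Selection frequency across outer folds",
                  fill = "In signature") +
    ggplot2::theme_minimal()
}
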