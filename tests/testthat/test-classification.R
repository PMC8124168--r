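# ROC/AUC, cost-sensitive cross-validation and the summary report.

test_that("AUC matches the exhaustive pair-counting oracle, including ties", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0, 0, 1, 1))$auc, 0.0)
  set.seed(17)
  for (rep in 1:5) {
    scores <- round(runif(30), 2)  # rounding forces ties
    labels <- rbinom(30, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(roc_auc(scores, labels)$auc, brute_auc(scores, labels),
                 info = sprintf("rep %d", rep))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "Both classes")
})

test_that("AUC agrees with the independent pROC implementation", {
  set.seed(23)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.3)
  got <- roc_auc(scores, labels)$auc
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("ROC curves are monotone and AUC is invariant to monotone transforms", {
  set.seed(29)
  scores <- runif(50)
  labels <- rbinom(50, 1, 0.5)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  ra <- roc_auc(scores, labels)
  expect_true(all(diff(ra$roc$fpr) >= 0))
  expect_true(all(diff(ra$roc$tpr) >= 0))
  expect_equal(utils::tail(ra$roc$fpr, 1), 1)
  expect_equal(utils::tail(ra$roc$tpr, 1), 1)
  # trapezoid under the curve equals the Mann-Whitney value
  trap <- sum(diff(ra$roc$fpr) *
                (utils::head(ra$roc$tpr, -1) + utils::tail(ra$roc$tpr, -1)) / 2)
  expect_equal(trap, ra$auc, tolerance = 1e-12)
  for (f in list(function(x) 3 * x - 1, function(x) exp(2 * x), qlogis))
    expect_equal(roc_auc(f(scores), labels)$auc, ra$auc, tolerance = 1e-12)
})

test_that("perfectly separable features give a perfect evaluation", {
  tab <- simulate_feature_table(n_cases = 60, n_noise = 2, effect = 0, seed = 2)
  tab$feat_sep <- tab$label * 10 + rnorm(60, sd = 0.01)
  ev <- cost_sensitive_cv(tab, "feat_sep", folds = 5, num_trees = 100, seed = 3)
  expect_equal(ev$auc, 1.0)
  expect_equal(unname(ev$confusion["fn"] + ev$confusion["fp"]), 0L)
  expect_equal(ev$accuracy, 1.0)
})

test_that("label-independent features score near chance on a large cohort", {
  tab <- simulate_feature_table(n_cases = 500, n_noise = 4, effect = 0, seed = 5)
  ev <- cost_sensitive_cv(tab, folds = 5, num_trees = 100, seed = 7)
  expect_gt(ev$auc, 0.5 - 0.07)
  expect_lt(ev$auc, 0.5 + 0.07)
  # every case scored exactly once out-of-fold
  expect_equal(sum(ev$confusion), 500)
  expect_equal(sort(unique(ev$cases$fold)), 1:5)
})

test_that("raising the false-negative cost does not increase false negatives", {
  tab <- simulate_feature_table(n_cases = 200, n_noise = 3, effect = 1, seed = 11)
  fns <- vapply(c(0.41, 0.59, 0.75, 0.92), function(cfn) {
    ev <- cost_sensitive_cv(tab, c("feat_signal", "feat_noise_01"),
                            cost = cost_matrix(cost_fn = cfn,
                                               cost_fp = 1 - cfn),
                            folds = 5, num_trees = 200, seed = 13)
    unname(ev$confusion["fn"])
  }, numeric(1))
  expect_true(all(diff(fns) <= 0))
})

test_that("equal costs reduce to the unweighted 0.5-threshold classifier", {
  tab <- simulate_feature_table(n_cases = 100, n_noise = 3, effect = 1, seed = 19)
  ev_half <- cost_sensitive_cv(tab, cost = cost_matrix(0.5, 0.5),
                               folds = 5, num_trees = 100, seed = 23)
  ev_one <- cost_sensitive_cv(tab, cost = cost_matrix(1, 1),
                              folds = 5, num_trees = 100, seed = 23)
  expect_identical(ev_half$cases$score, ev_one$cases$score)
  expect_identical(ev_half$cases$predicted, ev_one$cases$predicted)
  expect_equal(ev_half$threshold, 0.5)
  # and the scores coincide with a manually trained unweighted forest CV
  folds <- stratified_folds(tab$label, 5, derive_seed(23, 977L))
  feats <- setdiff(names(tab), c("case_id", "label"))
  manual <- numeric(nrow(tab))
  for (k in 1:5) {
    fit <- lnradiomics:::fit_rf(tab[folds != k, ], feats,
                                100L, derive_seed(23, 3000L + k))
    manual[folds == k] <- lnradiomics:::rf_scores(fit, tab[folds == k, ], feats)
  }
  expect_identical(ev_half$cases$score, manual)
})

test_that("the published bookkeeping reproduces from raw confusion counts", {
  s <- summarize_eval(c(tp = 62, fp = 7, tn = 20, fn = 10))
  expect_equal(s$accuracy, 82 / 99)
  expect_equal(round(s$accuracy, 3), 0.828)
  expect_equal(s$tp_pct, 100 * 62 / 72)
  expect_equal(s$tn_pct, 100 * 20 / 27)
  expect_equal(s$sensitivity, 62 / 72)
  expect_equal(s$specificity, 20 / 27)
  # flipped orientation bookkeeping
  expect_equal(s$neg_tp, 20)
  expect_equal(s$neg_fn, 7)
})

test_that("a fully correct toy evaluation has a degenerate Wilson interval", {
  s <- summarize_eval(c(tp = 4, fp = 0, tn = 6, fn = 0))
  expect_equal(s$accuracy, 1.0)
  expect_equal(s$accuracy_hi, 1.0)
  expect_lt(s$accuracy_lo, 1.0)
})

test_that("summary, tidy and autoplot expose a complete evaluation", {
  tab <- simulate_feature_table(n_cases = 80, n_noise = 3, effect = 1.5, seed = 29)
  ev <- cost_sensitive_cv(tab, folds = 5, num_trees = 100, seed = 31)
  s <- summarize_eval(ev)
  expect_equal(s$tp + s$fp + s$tn + s$fn, 80)
  expect_true(s$auc_lo <= ev$auc && ev$auc <= s$auc_hi)
  expect_equal(s$accuracy, ev$accuracy)
  td <- tidy(ev)
  expect_equal(nrow(td), 80)
  expect_true(all(td$score >= 0 & td$score <= 1))
  expect_s3_class(autoplot(ev), "ggplot")
})
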