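# End-to-end orchestration: per-case hull preprocessing, the four feature
# blocks, and the single feature-table contract shared by the selection and
# classification stages. Feature columns are grouped by name prefix:
# semantic fields, the hull volume ratio, fo_*, glcm3_*, lbp_*.

expected_group_counts <- c(semantic = 14L, ratio = 1L, first_order = 12L,
                           glcm3 = 182L, toplbp = 48L)

#' Group tag of each feature column
#'
#' @param feature_names Character vector of feature-table column names.
#' @return Character vector of group tags (`semantic`, `ratio`,
#'   `first_order`, `glcm3`, `toplbp`) aligned with `feature_names`;
#'   non-feature columns (`case_id`, `label`) get `NA`.
#' @export
feature_groups <- function(feature_names) {
  dplyr::case_when(
    feature_names %in% semantic_feature_names() ~ "semantic",
    feature_names == "volume_ratio" ~ "ratio",
    startsWith(feature_names, "fo_") ~ "first_order",
    startsWith(feature_names, "glcm3_") ~ "glcm3",
    startsWith(feature_names, "lbp_") ~ "toplbp",
    TRUE ~ NA_character_
  )
}

#' Validate the feature-table schema
#'
#' Checks the per-group column counts (14 semantic + 1 volume ratio + 12
#' first-order + 182 GLCM3 + 48 TOP-LBP = 257 features), the presence of
#' `case_id` and a binary `label`, and the absence of missing values.
#'
#' @param table A feature table as produced by [extract_features()].
#' @return The table, invisibly; errors describe any violation.
#' @export
check_feature_table <- function(table) {
  if (!all(c("case_id", "label") %in% names(table)))
    abort("Feature table must have `case_id` and `label` columns.")
  if (!all(table$label %in% c(0, 1)))
    abort("`label` must be binary 0/1.")
  groups <- feature_groups(names(table))
  counts <- table(factor(groups, levels = names(expected_group_counts)))
  bad <- names(expected_group_counts)[counts != expected_group_counts]
  if (length(bad))
    abort(paste0("Wrong feature count for group(s): ",
                 paste(sprintf("%s (%d, expected %d)", bad,
                               counts[bad], expected_group_counts[bad]),
                       collapse = ", "), "."))
  unknown <- names(table)[is.na(groups) & !names(table) %in% c("case_id", "label")]
  if (length(unknown))
    abort(paste0("Unrecognized feature column(s): ",
                 paste(head(unknown, 5), collapse = ", "), "."))
  feat <- dplyr::select(table, -dplyr::all_of(c("case_id", "label")))
  if (anyNA(feat)) abort("Feature table contains missing values.")
  invisible(table)
}

#' Extract the full 257-feature table from a cohort
#'
#' For every case: iterative convex-hull preprocessing of the mask, then the
#' hull volume ratio, the 12 first-order features, the 182 GLCM3 features
#' (on the re-quantized volume) and the 48 TOP-LBP features, all computed on
#' the hull ROI, merged with the 14 encoded semantic features and the label.
#' Per-case failures are collected and reported together after the run.
#'
#' @param cohort Cohort tibble as produced by [simulate_cohort()] (list
#'   columns `volume`, `mask`, raw semantic fields, `label`).
#' @param bits Working GLCM3 quantization bit depth (default 6).
#' @param lbp An [lbp_config()].
#' @param fo_window First-order "energy around maximum" half-width in bins.
#' @param verbose Print one line per case.
#' @return A tibble with `case_id`, 257 feature columns and `label`, passing
#'   [check_feature_table()].
#' @export
extract_features <- function(cohort, bits = 6L, lbp = lbp_config(),
                             fo_window = 2L, verbose = FALSE) {
  sem <- encode_semantic(cohort)
  failures <- character(0)
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$case_id[i]
    t0 <- Sys.time()
    row <- tryCatch({
      vol <- cohort$volume[[i]]
      msk <- cohort$mask[[i]]
      hull <- iterative_hull(msk)
      roi <- hull$hull_mask
      quant <- c(volume_ratio = hull$volume_ratio,
                 first_order_block(vol, roi, window = fo_window),
                 glcm3_block(vol, roi, bits = bits),
                 toplbp_block(vol, roi, lbp))
      dplyr::bind_cols(tibble(case_id = id), sem[i, ],
                       as_tibble(as.list(quant)),
                       tibble(label = as.integer(cohort$label[i])))
    }, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", id, conditionMessage(e)))
      NULL
    })
    if (verbose)
      message(sprintf("extracted %s in %.2fs", id,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    rows[[i]] <- row
  }
  if (length(failures))
    abort(paste0("Feature extraction failed for ", length(failures),
                 " case(s):\n  ", paste(head(failures, 5), collapse = "\n  ")))
  out <- dplyr::bind_rows(rows)
  check_feature_table(out)
  out
}

#' Per-group ablation of the classifier
#'
#' Re-runs the cost-sensitive cross-validated classifier restricted to each
#' named feature group, and optionally to a selected signature, producing a
#' results-table-shaped comparison (one summary row per group).
#'
#' @param table Feature table (must pass [check_feature_table()]).
#' @param groups Character vector of group tags to ablate (default the four
#'   groups: semantic, first_order, glcm3, toplbp).
#' @param signature Optional `ln_signature` (or character vector of feature
#'   names) evaluated as an additional `"signature"` row.
#' @param cost A [cost_matrix()].
#' @param folds,num_trees,seed Passed to [cost_sensitive_cv()].
#' @return A tibble with one row per group: the [summarize_eval()] columns
#'   plus `features_used`, keyed by `group`.
#' @export
run_group_ablation <- function(table, groups = c("semantic", "first_order",
                                                 "glcm3", "toplbp"),
                               signature = NULL, cost = cost_matrix(),
                               folds = 10L, num_trees = 500L, seed = 1L) {
  check_feature_table(table)
  tags <- feature_groups(names(table))
  known <- setdiff(unique(tags), NA)
  bad <- setdiff(groups, known)
  if (length(bad))
    abort(paste0("Unknown feature group(s): ", paste(bad, collapse = ", "), "."))
  sets <- lapply(groups, function(g) names(table)[!is.na(tags) & tags == g])
  names(sets) <- groups
  if (!is.null(signature)) {
    feats <- if (inherits(signature, "ln_signature")) signature$features else signature
    sets <- c(list(signature = feats), sets)
  }
  purrr::map2_dfr(names(sets), sets, function(nm, fs) {
    if (length(fs) == 0L) abort(sprintf("Feature group `%s` is empty.", nm))
    ev <- cost_sensitive_cv(table, fs, cost = cost, folds = folds,
                            num_trees = num_trees, seed = seed)
    dplyr::bind_cols(tibble(group = nm, features_used = length(fs)),
                     summarize_eval(ev))
  })
}
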