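# On-disk interchange: per-case volumes and masks as NIfTI (.nii.gz), the
# semantic table plus labels as one CSV keyed by case_id, a JSON cohort
# manifest, and CSV/JSON for feature tables, signatures and reports.

#' Write a synthetic cohort to a directory
#'
#' Writes `<case_id>_volume.nii.gz` and `<case_id>_mask.nii.gz` per case, a
#' `semantic.csv` with one row per case (raw semantic fields + label), and a
#' `manifest.json` describing the cohort.
#'
#' @param cohort Cohort tibble from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$case_id[i]
    RNifti::writeNifti(cohort$volume[[i]],
                       file.path(dir, paste0(id, "_volume.nii.gz")))
    RNifti::writeNifti(cohort$mask[[i]] + 0L,
                       file.path(dir, paste0(id, "_mask.nii.gz")))
  }
  sem <- dplyr::select(cohort, -dplyr::all_of(c("volume", "mask")))
  readr::write_csv(sem, file.path(dir, "semantic.csv"))
  manifest <- list(n_cases = nrow(cohort),
                   case_ids = cohort$case_id,
                   grid_shape = dim(cohort$volume[[1]]),
                   n_positive = sum(cohort$label == 1))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A cohort tibble with list-columns `volume` (integer arrays) and
#'   `mask` (logical arrays) plus the semantic fields and `label`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  sem <- readr::read_csv(file.path(dir, "semantic.csv"),
                         show_col_types = FALSE)
  vols <- lapply(manifest$case_ids, function(id) {
    v <- RNifti::readNifti(file.path(dir, paste0(id, "_volume.nii.gz")))
    a <- array(as.integer(v), dim(v))
    a
  })
  masks <- lapply(manifest$case_ids, function(id) {
    m <- RNifti::readNifti(file.path(dir, paste0(id, "_mask.nii.gz")))
    array(as.integer(m) != 0L, dim(m))
  })
  out <- dplyr::bind_cols(
    tibble(case_id = manifest$case_ids),
    tibble(volume = vols, mask = masks),
    dplyr::select(sem, -dplyr::all_of("case_id")))
  dplyr::relocate(out, dplyr::all_of(c("case_id", "label")))
}

#' Read and write feature tables as CSV
#'
#' The CSV keeps `case_id` first and `label` last; groups are recovered from
#' column names on read and the schema is validated.
#'
#' @param table Feature table.
#' @param path CSV path.
#' @return `write_feature_table()`: the path, invisibly;
#'   `read_feature_table()`: the validated tibble.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_feature_table(out)
  out
}

#' Write a signature (with audit trail) to JSON
#'
#' @param signature An `ln_signature`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(
    list(features = signature$features,
         frequency = signature$frequency,
         fold_subsets = signature$fold_subsets,
         fold_test_ids = signature$fold_test_ids,
         config = unclass(signature$config)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature written by [write_signature()]
#'
#' @param path JSON path.
#' @return An `ln_signature`.
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = x$features,
                 frequency = as_tibble(x$frequency),
                 fold_subsets = x$fold_subsets,
                 fold_test_ids = x$fold_test_ids,
                 config = structure(x$config, class = "wrapper_config")),
            class = "ln_signature")
}
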