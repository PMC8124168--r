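# Clinical, lesion-MRI and histological covariates ("semantic" features) and
# the binary axillary lymph-node label. Fields are validated against a strict
# vocabulary and integer-coded for the tree learner (no one-hot expansion:
# random forests handle label-coded qualitative features directly).

semantic_vocab <- list(
  localization = c("retro-areolar", "upper-external", "lower-external",
                   "upper-internal", "lower-internal"),
  margins = c("regular", "irregular", "lobulated", "spiculated"),
  familiarity = c("none", "1", ">1"),
  histotype = c("IDC", "ILC", "medullary"),
  tumor_class = c("Luminal A", "Luminal B", "HER2", "TN")
)

#' Names of the 14 default semantic features
#' @return Character vector of length 14.
#' @export
semantic_feature_names <- function() {
  c("age", "menopause", "hormone_therapy", "familiarity",
    "localization", "margins", "max_diameter", "curve_type",
    "histotype", "grading", "tumor_class",
    "er_positive", "pgr_positive", "her2_positive")
}

#' Receptor status flags from immunohistochemistry values
#'
#' Applies the diagnostic cut-offs: estrogen and progesterone receptor
#' positive when expression is strictly greater than 10%; HER2 positive when
#' the score is strictly greater than 2+; Ki67 high when strictly greater
#' than 14%.
#'
#' @param er_percent,pgr_percent,ki67_percent Percentages in `[0, 100]`.
#' @param her2_score Integer score 0..3.
#' @return A tibble with logical columns `er_positive`, `pgr_positive`,
#'   `her2_positive`, `ki67_high`.
#' @export
derive_receptor_status <- function(er_percent, pgr_percent, her2_score,
                                   ki67_percent) {
  for (v in list(er_percent, pgr_percent, ki67_percent))
    if (any(v < 0 | v > 100)) abort("Percentages must lie in [0, 100].")
  if (any(her2_score < 0 | her2_score > 3)) abort("`her2_score` must be 0..3.")
  tibble(er_positive = er_percent > 10,
         pgr_positive = pgr_percent > 10,
         her2_positive = her2_score > 2,
         ki67_high = ki67_percent > 14)
}

#' Molecular tumor class from receptor flags
#'
#' Deterministic mapping with documented precedence: triple negative (ER-,
#' PgR-, HER2-) first; then HER2-overexpressed (ER-, HER2+); ER+ tumors are
#' Luminal A when HER2- with low Ki67 and Luminal B otherwise (HER2 -/+ with
#' high Ki67, or HER2+ regardless of Ki67). The rare ER-/PgR+/HER2- pattern
#' is coded Luminal B.
#'
#' @param er_positive,pgr_positive,her2_positive,ki67_high Logical vectors.
#' @return Character vector of classes in
#'   `c("Luminal A", "Luminal B", "HER2", "TN")`.
#' @export
derive_tumor_class <- function(er_positive, pgr_positive, her2_positive,
                               ki67_high) {
  dplyr::case_when(
    !er_positive & !pgr_positive & !her2_positive ~ "TN",
    !er_positive & her2_positive ~ "HER2",
    er_positive & !her2_positive & !ki67_high ~ "Luminal A",
    er_positive ~ "Luminal B",
    TRUE ~ "Luminal B"
  )
}

validate_semantic <- function(records) {
  records <- as_tibble(records)
  required <- c(semantic_feature_names(), "er_percent", "pgr_percent",
                "her2_score", "ki67_percent")
  required <- setdiff(required, c("er_positive", "pgr_positive", "her2_positive"))
  missing <- setdiff(required, names(records))
  if (length(missing))
    abort(paste0("Missing required semantic fields: ",
                 paste(missing, collapse = ", "), "."))
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows))
      problems <<- c(problems, sprintf("row %d: %s", rows, msg))
  }
  note(which(records$age <= 0), "age must be positive")
  note(which(records$max_diameter <= 0), "max_diameter must be positive")
  note(which(!records$menopause %in% c(0, 1)), "menopause must be 0/1")
  note(which(!records$hormone_therapy %in% c(0, 1)), "hormone_therapy must be 0/1")
  note(which(!records$curve_type %in% 1:3), "curve_type must be 1, 2 or 3")
  note(which(!records$grading %in% 1:3), "grading must be 1, 2 or 3")
  for (f in names(semantic_vocab))
    note(which(!records[[f]] %in% semantic_vocab[[f]]),
         sprintf("unknown %s category", f))
  for (f in c("er_percent", "pgr_percent", "ki67_percent"))
    note(which(records[[f]] < 0 | records[[f]] > 100),
         sprintf("%s must be in [0, 100]", f))
  note(which(!records$her2_score %in% 0:3), "her2_score must be 0..3")
  if (length(problems))
    abort(paste0("Semantic validation failed:\n  ",
                 paste(head(problems, 10), collapse = "\n  ")))
  records
}

#' Encode semantic records into the model feature block
#'
#' Validates each record against the strict category vocabulary and emits the
#' 14 default semantic features: age, menopause, hormone therapy, familiarity
#' (0/1/2 relatives), localization, margins, maximum diameter (mm), kinetic
#' curve type (I/II/III), histotype, grading, molecular tumor class, and the
#' ER/PgR/HER2 positivity flags derived from the immunohistochemistry
#' cut-offs (Ki67 is absorbed into the tumor class). Ordinal fields are
#' integer-coded and nominal fields label-coded. If a provided `tumor_class`
#' contradicts the class derived from the receptor flags, a warning is issued
#' and the provided value wins.
#'
#' @param records Data frame with one row per case (see
#'   [semantic_feature_names()] plus the raw `er_percent`, `pgr_percent`,
#'   `her2_score`, `ki67_percent` fields).
#' @return A tibble with exactly 14 numeric semantic feature columns.
#' @export
encode_semantic <- function(records) {
  records <- validate_semantic(records)
  flags <- derive_receptor_status(records$er_percent, records$pgr_percent,
                                  records$her2_score, records$ki67_percent)
  derived <- derive_tumor_class(flags$er_positive, flags$pgr_positive,
                                flags$her2_positive, flags$ki67_high)
  mismatch <- derived != records$tumor_class
  if (any(mismatch))
    warn(sprintf(
      "%d case(s) have a provided tumor_class differing from the derived one; keeping the provided value.",
      sum(mismatch)))
  tibble(
    age = as.numeric(records$age),
    menopause = as.numeric(records$menopause),
    hormone_therapy = as.numeric(records$hormone_therapy),
    familiarity = as.numeric(match(records$familiarity, semantic_vocab$familiarity) - 1L),
    localization = as.numeric(match(records$localization, semantic_vocab$localization)),
    margins = as.numeric(match(records$margins, semantic_vocab$margins)),
    max_diameter = as.numeric(records$max_diameter),
    curve_type = as.numeric(records$curve_type),
    histotype = as.numeric(match(records$histotype, semantic_vocab$histotype)),
    grading = as.numeric(records$grading),
    tumor_class = as.numeric(match(records$tumor_class, semantic_vocab$tumor_class)),
    er_positive = as.numeric(flags$er_positive),
    pgr_positive = as.numeric(flags$pgr_positive),
    her2_positive = as.numeric(flags$her2_positive)
  )
}

#' Decode an encoded semantic block back to category labels
#'
#' Inverse of the categorical codings of [encode_semantic()] (the derived
#' receptor flags are not invertible to raw percentages and are returned as
#' logicals).
#'
#' @param encoded Tibble produced by [encode_semantic()].
#' @return Tibble with category labels restored.
#' @export
decode_semantic <- function(encoded) {
  tibble(
    age = encoded$age,
    menopause = as.integer(encoded$menopause),
    hormone_therapy = as.integer(encoded$hormone_therapy),
    familiarity = semantic_vocab$familiarity[encoded$familiarity + 1L],
    localization = semantic_vocab$localization[encoded$localization],
    margins = semantic_vocab$margins[encoded$margins],
    max_diameter = encoded$max_diameter,
    curve_type = as.integer(encoded$curve_type),
    histotype = semantic_vocab$histotype[encoded$histotype],
    grading = as.integer(encoded$grading),
    tumor_class = semantic_vocab$tumor_class[encoded$tumor_class],
    er_positive = encoded$er_positive > 0,
    pgr_positive = encoded$pgr_positive > 0,
    her2_positive = encoded$her2_positive > 0
  )
}
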