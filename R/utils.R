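# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific random seed
#'
#' Deterministically maps a base seed and a stream offset to a new seed in
#' `[0, 2^31 - 1)`, so that independent pipeline stages (simulation, selection,
#' classification) consume independent but reproducible streams.
#'
#' @param seed Integer base seed.
#' @param offset Integer stream offset (e.g. a case index or stage number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  # splitmix-style integer scramble, kept inside 31 bits for R's set.seed()
  x <- (as.double(seed) * 2654435761 + as.double(offset) * 40503 + 12345) %% 2147483647
  as.integer(x)
}

assert_volume <- function(volume) {
  if (!is.array(volume) || length(dim(volume)) != 3L)
    abort("`volume` must be a 3D array of intensities.")
  if (any(volume < 0, na.rm = TRUE))
    abort("`volume` intensities must be nonnegative.")
  invisible(volume)
}

assert_mask <- function(mask, volume = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    abort("`mask` must be a 3D logical array.")
  m <- if (is.logical(mask)) mask else mask != 0
  if (!any(m)) abort("`mask` must contain at least one voxel.")
  if (!is.null(volume) && !identical(dim(mask), dim(volume)))
    abort("`mask` and `volume` must share the same grid shape.")
  m
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each case to one of `k` folds so that class proportions are as
#' balanced as possible across folds. Errors if any fold would end up with a
#' single class, which would make out-of-fold AUC undefined.
#'
#' @param labels Binary (0/1) label vector.
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Integer vector of fold ids in `1:k`, one per case.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    abort("Both classes must be present to build stratified folds.")
  if (min(table(labels)) < k)
    abort(sprintf(
      "Stratification failure: minority class has %d cases, fewer than %d folds.",
      min(table(labels)), k))
  folds <- integer(length(labels))
  set.seed(derive_seed(seed, 101L))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Quantize intensities to n_levels grey levels (0 .. n_levels-1) by equal-width
# binning over the in-mask range. Constant regions map to level 0.
quantize_levels <- function(values, n_levels) {
  vmin <- min(values)
  vmax <- max(values)
  if (vmax <= vmin) return(rep.int(0L, length(values)))
  g <- floor((values - vmin) / (vmax - vmin) * n_levels)
  as.integer(pmin(g, n_levels - 1L))
}

#' Re-quantize a volume to a working bit depth over the ROI intensity range
#'
#' Grey-level co-occurrence statistics need a tractable number of levels; the
#' raw acquisition bit depth would give a sparse, astronomically large matrix.
#' Intensities are linearly min-max rescaled over the in-mask range to
#' `2^bits` levels (default 6 bits = 64 levels, the customary radiomics
#' resolution). Out-of-mask voxels are set to level 0 but are never paired.
#'
#' @param volume 3D intensity array.
#' @param mask 3D logical array on the same grid.
#' @param bits Working bit depth (1..8 supported).
#' @return Integer 3D array of levels in `0 .. 2^bits - 1`.
#' @export
quantize_volume <- function(volume, mask, bits = 6L) {
  assert_volume(volume)
  m <- assert_mask(mask, volume)
  if (bits < 1L || bits > 8L) abort("`bits` must be between 1 and 8.")
  n_levels <- as.integer(2^bits)
  q <- array(0L, dim(volume))
  q[m] <- quantize_levels(volume[m], n_levels)
  q
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}
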