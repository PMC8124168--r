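# First-order (histogram) features: the intensity distribution of the ROI,
# summarized by 12 scalars up to fourth-order moments plus histogram-shape
# descriptors. The same 12-measure battery is reused on LBP code histograms.

#' Intensity histogram of a masked region
#'
#' Tallies in-mask voxel intensities. By default one bin per grey level over
#' `[0, 2^bit_depth - 1]` (so moments on bin centers equal moments on raw
#' values); a coarser equal-width binning can be requested with `n_bins`.
#'
#' @param volume 3D array of nonnegative integer intensities.
#' @param mask 3D logical array on the same grid.
#' @param bit_depth Bits per voxel of the stored volume (defines the grey
#'   range). Defaults to the smallest of 8/16 bits covering the data.
#' @param n_bins Number of equal-width bins; `NULL` (default) = one bin per
#'   grey level.
#' @return An object of class `intensity_histogram`: list with `counts`,
#'   `mids` (bin-center grey levels), `edges` and `n_voxels`.
#' @export
roi_histogram <- function(volume, mask, bit_depth = NULL, n_bins = NULL) {
  assert_volume(volume)
  m <- assert_mask(mask, volume)
  vals <- as.numeric(volume[m])
  if (is.null(bit_depth)) bit_depth <- if (max(vals) <= 255) 8L else 16L
  gmax <- 2^bit_depth - 1
  if (max(vals) > gmax) abort("Intensities exceed the stated bit depth.")
  if (is.null(n_bins)) {
    counts <- tabulate(as.integer(vals) + 1L, nbins = as.integer(gmax) + 1L)
    mids <- 0:gmax
    edges <- seq(-0.5, gmax + 0.5, by = 1)
  } else {
    edges <- seq(0, gmax + 1, length.out = n_bins + 1L)
    bin <- pmin(findInterval(vals, edges), n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    mids <- (head(edges, -1) + tail(edges, -1)) / 2
  }
  new_intensity_histogram(counts, mids, edges)
}

new_intensity_histogram <- function(counts, mids, edges = NULL) {
  structure(list(counts = as.numeric(counts), mids = as.numeric(mids),
                 edges = edges, n_voxels = sum(counts)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins, %d voxels, occupied range [%g, %g]\n",
              length(x$counts), x$n_voxels,
              min(x$mids[x$counts > 0]), max(x$mids[x$counts > 0])))
  invisible(x)
}

# Strict relative maxima of a counts vector: interior bins greater than both
# neighbors; edge bins greater than their single neighbor. Plateaus (equal
# neighbors) do not count.
relative_maxima <- function(counts) {
  b <- length(counts)
  if (b == 1L) return(if (counts[1] > 0) 1L else integer(0))
  left <- c(-Inf, counts[-b])
  right <- c(counts[-1], -Inf)
  which(counts > left & counts > right)
}

#' The 12 first-order measures of an intensity histogram
#'
#' Computes, over the normalized histogram probabilities `p_b` at bin centers
#' `x_b`: mean, standard deviation, skewness and kurtosis (population
#' moments, kurtosis non-excess); width (occupied grey-level range); entropy
#' (`-sum p log2 p`, 0 log 0 = 0); energy (`sum p^2`); the absolute-maximum
#' probability and its grey level; the energy in a window of `window` bins
#' around the absolute maximum; the number of strict relative maxima; and the
#' energy in the union of windows around all relative maxima.
#'
#' @param histogram An `intensity_histogram` (or any list with `counts` and
#'   `mids`).
#' @param window Half-width, in bins, of the "energy around a maximum"
#'   windows (default 2).
#' @param prefix Name prefix for the returned features (default `"fo_"`).
#' @return A named numeric vector of exactly 12 features.
#' @export
first_order <- function(histogram, window = 2L, prefix = "fo_") {
  counts <- histogram$counts
  mids <- histogram$mids
  n <- sum(counts)
  if (n < 1) abort("Histogram is empty.")
  p <- counts / n
  mu <- sum(p * mids)
  v <- sum(p * (mids - mu)^2)
  s <- sqrt(v)
  skew <- if (s > 0) sum(p * (mids - mu)^3) / s^3 else 0
  kurt <- if (s > 0) sum(p * (mids - mu)^4) / s^4 else 0
  occ <- which(counts > 0)
  width <- mids[max(occ)] - mids[min(occ)]
  entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
  energy <- sum(p^2)
  imax <- which.max(counts)  # first bin on ties
  wmax <- seq(max(1L, imax - window), min(length(p), imax + window))
  relmax <- relative_maxima(counts)
  wrel <- unique(unlist(lapply(relmax, function(i)
    seq(max(1L, i - window), min(length(p), i + window)))))
  out <- c(mean = mu, sd = s, skewness = skew, kurtosis = kurt,
           width = width, entropy = entropy, energy = energy,
           max_value = p[imax], max_grey = mids[imax],
           energy_abs_max = sum(p[wmax]^2),
           n_rel_max = length(relmax),
           energy_rel_max = if (length(wrel)) sum(p[wrel]^2) else 0)
  names(out) <- paste0(prefix, names(out))
  out
}

#' First-order feature block for one case
#'
#' Convenience wrapper: histogram of the in-ROI intensities followed by
#' [first_order()].
#'
#' @inheritParams roi_histogram
#' @inheritParams first_order
#' @return Named numeric vector of 12 `fo_`-prefixed features.
#' @export
first_order_block <- function(volume, mask, bit_depth = NULL, n_bins = NULL,
                              window = 2L) {
  first_order(roi_histogram(volume, mask, bit_depth, n_bins), window = window)
}
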