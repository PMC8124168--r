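# Local binary patterns on three orthogonal planes (TOP-LBP). Each of the
# three central planes through the ROI centroid is coded with a planar LBP
# (P neighbors on a radius-r circle, bilinear interpolation); histograms of
# the in-mask codes are concatenated across planes for four coding variants
# (plain, uniform U, rotation-invariant RI, U+RI) and each concatenated
# histogram is summarized by the 12 first-order measures, giving 48 features
# at P = 8.

#' LBP configuration
#'
#' @param P Number of circle neighbors (default 8).
#' @param r Circle radius in pixels (default 1).
#' @return A list of class `lbp_config`.
#' @export
lbp_config <- function(P = 8L, r = 1) {
  if (P < 4L) abort("`P` must be at least 4.")
  if (r < 1) abort("`r` must be at least 1.")
  structure(list(P = as.integer(P), r = r), class = "lbp_config")
}

# --- code tables ------------------------------------------------------------
# For P <= 16 the full code space 0 .. 2^P - 1 is enumerated once and the
# variant mappings are table lookups.

lbp_code_bits <- function(P) {
  codes <- 0:(2^P - 1)
  vapply(0:(P - 1), function(j) bitwAnd(bitwShiftR(codes, j), 1L), integer(2^P))
}

lbp_transitions <- function(P) {
  bits <- lbp_code_bits(P)
  rot <- bits[, c(2:P, 1), drop = FALSE]
  rowSums(bits != rot)
}

# Rotation-invariant canonical code: minimum over the P circular bit rotations.
lbp_ri_map <- function(P) {
  codes <- 0:(2^P - 1)
  mn <- codes
  x <- codes
  mask_all <- 2^P - 1
  for (k in seq_len(P - 1)) {
    x <- bitwOr(bitwShiftR(x, 1L), bitwShiftL(bitwAnd(x, 1L), P - 1L))
    x <- bitwAnd(x, mask_all)
    mn <- pmin(mn, x)
  }
  mn
}

#' LBP variant code tables
#'
#' Enumerates the full planar LBP code space for `P` neighbors and returns,
#' for each variant, the map from raw code to variant bin index (0-based)
#' and the number of bins: plain `2^P`; U collapses all codes with more than
#' two circular 0-1 transitions into one non-uniform bin (59 bins at P = 8);
#' RI maps each code to its minimal circular rotation (36 bins at P = 8);
#' U+RI keeps the 9 uniform rotation classes plus one non-uniform bin (10
#' bins at P = 8).
#'
#' @param P Number of neighbors (4..16).
#' @return List with per-variant elements `map` (integer vector over raw
#'   codes) and `n_bins`.
#' @export
lbp_variant_tables <- function(P = 8L) {
  if (P > 16L) abort("Code tables support P <= 16.")
  codes <- 0:(2^P - 1)
  trans <- lbp_transitions(P)
  uniform <- trans <= 2L
  ri <- lbp_ri_map(P)
  ones <- rowSums(lbp_code_bits(P))

  u_bins <- sort(codes[uniform])
  u_map <- integer(2^P)
  u_map[uniform] <- match(codes[uniform], u_bins) - 1L
  u_map[!uniform] <- length(u_bins)  # single non-uniform bin, last

  ri_bins <- sort(unique(ri))
  ri_map <- match(ri, ri_bins) - 1L

  uri_map <- integer(2^P)
  uri_map[uniform] <- ones[uniform]      # 0..P ones -> P+1 classes
  uri_map[!uniform] <- P + 1L            # non-uniform bin, last

  list(
    plain = list(map = codes, n_bins = 2^P),
    U = list(map = u_map, n_bins = length(u_bins) + 1L),
    RI = list(map = ri_map, n_bins = length(ri_bins)),
    U_RI = list(map = uri_map, n_bins = P + 2L)
  )
}

# Bilinear sample of `slice` at (rows + dr, cols + dc) for the coded region.
bilinear_shift <- function(slice, rows, cols, dr, dc, tol = 1e-9) {
  r0 <- floor(dr + tol); fr <- dr - r0
  c0 <- floor(dc + tol); fc <- dc - c0
  if (abs(fr) < tol) fr <- 0
  if (abs(fc) < tol) fc <- 0
  v <- (1 - fr) * (1 - fc) * slice[rows + r0, cols + c0, drop = FALSE]
  if (fc > 0) v <- v + (1 - fr) * fc * slice[rows + r0, cols + c0 + 1, drop = FALSE]
  if (fr > 0) v <- v + fr * (1 - fc) * slice[rows + r0 + 1, cols + c0, drop = FALSE]
  if (fr > 0 && fc > 0) v <- v + fr * fc * slice[rows + r0 + 1, cols + c0 + 1, drop = FALSE]
  v
}

#' Planar LBP coding of a 2D slice
#'
#' For each interior pixel, samples `P` neighbors at angles `2*pi*j/P` on a
#' radius-`r` circle (bilinear interpolation for off-grid samples), sets bit
#' `j` to 1 when the neighbor intensity strictly exceeds the center (ties
#' code 0), and reads the bits in counter-clockwise order starting at angle
#' 0. A border of width `ceiling(r)` is left uncoded (`NA`).
#'
#' @param slice Numeric matrix.
#' @param config An [lbp_config()].
#' @return Integer matrix of raw LBP codes with `NA` on the uncoded border.
#'   If the slice is smaller than the neighborhood, an all-`NA` grid is
#'   returned with a warning.
#' @export
lbp2d <- function(slice, config = lbp_config()) {
  P <- config$P; r <- config$r
  rb <- ceiling(r)
  nr <- nrow(slice); nc <- ncol(slice)
  out <- matrix(NA_integer_, nr, nc)
  if (nr < 2 * rb + 1 || nc < 2 * rb + 1) {
    warn("Slice smaller than the LBP neighborhood; returning an uncoded grid.")
    return(out)
  }
  rows <- (rb + 1):(nr - rb)
  cols <- (rb + 1):(nc - rb)
  center <- slice[rows, cols, drop = FALSE]
  code <- matrix(0L, length(rows), length(cols))
  for (j in 0:(P - 1)) {
    ang <- 2 * pi * j / P
    dc <- r * cos(ang)
    dr <- r * sin(ang)
    nb <- bilinear_shift(slice, rows, cols, dr, dc)
    code <- code + (nb > center) * 2L^j
  }
  out[rows, cols] <- code
  out
}

# Centroid (rounded) of a mask, as an index triple.
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pmin(pmax(round(colMeans(idx)), 1L), dim(mask))
}

#' TOP-LBP histograms of a masked volume
#'
#' Extracts the three orthogonal planes through the ROI centroid (axial
#' `z = k0`, coronal `y = j0`, sagittal `x = i0`), codes each with [lbp2d()],
#' restricts to coded pixels whose location is in-mask, and concatenates the
#' per-plane histograms (raw counts) in fixed axial, coronal, sagittal order
#' for each coding variant.
#'
#' @param volume 3D intensity array.
#' @param mask 3D logical ROI.
#' @param config An [lbp_config()].
#' @return An object of class `toplbp_histograms`: list with one named counts
#'   vector per variant (`plain`, `U`, `RI`, `U_RI`) plus `plane_totals`.
#' @export
toplbp_histograms <- function(volume, mask, config = lbp_config()) {
  assert_volume(volume)
  m <- assert_mask(mask, volume)
  tabs <- lbp_variant_tables(config$P)
  ctr <- mask_centroid(m)
  planes <- list(
    axial    = list(sl = volume[, , ctr[3]], ms = m[, , ctr[3]]),
    coronal  = list(sl = volume[, ctr[2], ], ms = m[, ctr[2], ]),
    sagittal = list(sl = volume[ctr[1], , ], ms = m[ctr[1], , ])
  )
  hists <- lapply(names(tabs), function(v) numeric(0))
  names(hists) <- names(tabs)
  plane_totals <- integer(0)
  for (pn in names(planes)) {
    sl <- planes[[pn]]$sl
    ms <- planes[[pn]]$ms
    coded <- withCallingHandlers(
      lbp2d(sl, config),
      rlang_warning = function(w) invokeRestart("muffleWarning"),
      warning = function(w) invokeRestart("muffleWarning"))
    keep <- !is.na(coded) & ms
    if (!any(keep))
      warn(sprintf("Degenerate %s plane: no in-mask coded pixels.", pn))
    raw <- coded[keep]
    plane_totals[pn] <- length(raw)
    for (v in names(tabs)) {
      mapped <- tabs[[v]]$map[raw + 1L]
      h <- tabulate(mapped + 1L, nbins = tabs[[v]]$n_bins)
      names(h) <- paste0(pn, "_", seq_len(tabs[[v]]$n_bins) - 1L)
      hists[[v]] <- c(hists[[v]], h)
    }
  }
  structure(c(hists, list(plane_totals = plane_totals, P = config$P)),
            class = "toplbp_histograms")
}

toplbp_variant_suffix <- c(plain = "", U = "_U", RI = "_RI", U_RI = "_U_RI")

#' TOP-LBP feature block for one case
#'
#' Applies the 12 first-order measures to each variant's histogram with the
#' variant's code bin as the grey-level axis: the three per-plane histograms
#' are aligned code-wise and summed, so a constant volume (one code
#' everywhere) occupies a single bin regardless of plane layout. This yields
#' 12 x 4 = 48 named features; the `width` measure is reported as `range`,
#' its customary name for LBP histograms.
#'
#' @inheritParams toplbp_histograms
#' @return Named numeric vector of exactly 48 features, prefixed `lbp_` with
#'   variant suffixes `""`, `"_U"`, `"_RI"`, `"_U_RI"`.
#' @export
toplbp_block <- function(volume, mask, config = lbp_config()) {
  hs <- toplbp_histograms(volume, mask, config)
  tabs <- lbp_variant_tables(config$P)
  out <- numeric(0)
  for (v in names(toplbp_variant_suffix)) {
    b <- tabs[[v]]$n_bins
    counts <- numeric(b)  # pool the three plane segments code-wise
    for (pl in c("axial", "coronal", "sagittal")) {
      seg <- hs[[v]][startsWith(names(hs[[v]]), paste0(pl, "_"))]
      if (length(seg)) counts <- counts + as.numeric(seg)
    }
    h <- new_intensity_histogram(counts, seq_along(counts) - 1)
    f <- first_order(h, prefix = "")
    names(f)[names(f) == "width"] <- "range"
    names(f) <- paste0("lbp_", names(f), toplbp_variant_suffix[[v]])
    out <- c(out, f)
  }
  out
}
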