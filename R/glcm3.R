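# 3D grey-level co-occurrence texture. For a displacement d, the GLCM3 counts
# ordered voxel pairs (p, p + d) with both endpoints inside the ROI; 26 unit
# displacements (all of {-1,0,1}^3 minus the origin) are retained separately,
# and 7 measures are computed from each matrix, giving 26 x 7 = 182 features.

#' The 26 unit displacement vectors
#'
#' All of `{-1,0,1}^3` except the zero vector, in a fixed deterministic order
#' (dx fastest). Opposite vectors are distinct entries: the matrices they
#' generate are transposes of one another.
#'
#' @return An integer matrix with 26 rows and columns `dx`, `dy`, `dz`.
#' @export
displacement_set <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  rownames(g) <- apply(g, 1, function(d) sprintf("(%d.%d.%d)", d[1], d[2], d[3]))
  g
}

#' 3D grey-level co-occurrence matrix for one displacement
#'
#' Counts ordered pairs of in-mask voxels separated by displacement `d` on a
#' quantized volume with levels `0 .. n_levels - 1`. The matrix is
#' directional (not symmetrized); `glcm3(d)` is the transpose of
#' `glcm3(-d)`.
#'
#' @param qvol Integer 3D array of quantized grey levels (see
#'   [quantize_volume()]).
#' @param mask 3D logical array on the same grid.
#' @param d Length-3 integer displacement, e.g. `c(1, 0, 0)`.
#' @param n_levels Number of grey levels N (defaults to `max(qvol) + 1`).
#' @return An object of class `glcm3`: list with `counts` (N x N matrix,
#'   rows = source level gi, cols = target level gj), `displacement`,
#'   `n_pairs`.
#' @export
glcm3 <- function(qvol, mask, d, n_levels = NULL) {
  m <- assert_mask(mask, qvol)
  if (length(d) != 3L || all(d == 0)) abort("`d` must be a nonzero length-3 displacement.")
  n_levels <- as.integer(n_levels %||% (max(qvol[m]) + 1L))
  dims <- dim(qvol)
  src <- lapply(1:3, function(ax) {
    seq.int(max(1L, 1L - d[ax]), min(dims[ax], dims[ax] - d[ax]))
  })
  counts <- matrix(0, n_levels, n_levels)
  if (all(lengths(src) > 0)) {
    dst <- lapply(1:3, function(ax) src[[ax]] + d[ax])
    a <- qvol[src[[1]], src[[2]], src[[3]], drop = FALSE]
    b <- qvol[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    ok <- m[src[[1]], src[[2]], src[[3]], drop = FALSE] &
          m[dst[[1]], dst[[2]], dst[[3]], drop = FALSE]
    if (any(ok)) {
      code <- a[ok] * n_levels + b[ok] + 1L
      tab <- tabulate(code, nbins = n_levels^2)
      counts <- matrix(tab, n_levels, n_levels, byrow = TRUE)
    }
  }
  structure(list(counts = counts, displacement = as.integer(d),
                 n_pairs = sum(counts), n_levels = n_levels),
            class = "glcm3")
}

#' @export
print.glcm3 <- function(x, ...) {
  cat(sprintf("<glcm3> N = %d, displacement (%d,%d,%d), %d pairs\n",
              x$n_levels, x$displacement[1], x$displacement[2],
              x$displacement[3], x$n_pairs))
  invisible(x)
}

glcm3_measure_names <- c("autocorrelation", "homogeneity", "entropy", "energy",
                         "covariance", "inertia", "abs_contrast")

#' The 7 co-occurrence measures of a GLCM3
#'
#' On the normalized co-occurrence probabilities `P(i, j)` with grey levels
#' `i, j` in `0 .. N-1`: autocorrelation `sum i j P`, homogeneity (inverse
#' difference) `sum P / (1 + |i - j|)`, entropy `-sum P log2 P`, energy
#' `sum P^2`, covariance `sum (i - mu_r)(j - mu_c) P` with marginal means
#' `mu_r`, `mu_c`, inertia (contrast) `sum (i - j)^2 P`, and absolute
#' contrast `sum |i - j| P`.
#'
#' @param g A `glcm3` object.
#' @return Named numeric vector of 7 measures. If the matrix holds zero
#'   pairs, all measures are emitted as the sentinel 0 with a warning.
#' @export
glcm3_measures <- function(g) {
  if (g$n_pairs == 0) {
    warn("GLCM3 has zero valid pairs for this displacement; emitting 0 sentinels.")
    return(setNames(rep(0, 7L), glcm3_measure_names))
  }
  P <- g$counts / g$n_pairs
  N <- g$n_levels
  lev <- 0:(N - 1)
  I <- matrix(lev, N, N)       # row index = gi
  J <- matrix(lev, N, N, byrow = TRUE)
  mu_r <- sum(lev * rowSums(P))
  mu_c <- sum(lev * colSums(P))
  setNames(c(
    sum(I * J * P),
    sum(P / (1 + abs(I - J))),
    -sum(ifelse(P > 0, P * log2(P), 0)),
    sum(P^2),
    sum((I - mu_r) * (J - mu_c) * P),
    sum((I - J)^2 * P),
    sum(abs(I - J) * P)
  ), glcm3_measure_names)
}

#' Full GLCM3 feature block for one case
#'
#' Quantizes the volume over the ROI to `2^bits` grey levels, builds the
#' GLCM3 for each of the 26 displacements and concatenates the 7 measures of
#' each, yielding 182 named features in fixed direction-major order. Names
#' follow `glcm3_<measure>_(dx.dy.dz)`.
#'
#' @param volume 3D intensity array.
#' @param mask 3D logical ROI (normally the convex-hull mask).
#' @param bits Working quantization bit depth (default 6, i.e. 64 levels).
#' @return Named numeric vector of exactly 182 features.
#' @export
glcm3_block <- function(volume, mask, bits = 6L) {
  q <- quantize_volume(volume, mask, bits)
  m <- assert_mask(mask, volume)
  disp <- displacement_set()
  n_levels <- as.integer(2^bits)
  out <- numeric(0)
  for (r in seq_len(nrow(disp))) {
    g <- glcm3(q, m, disp[r, ], n_levels = n_levels)
    meas <- glcm3_measures(g)
    names(meas) <- paste0("glcm3_", glcm3_measure_names, "_", rownames(disp)[r])
    out <- c(out, meas)
  }
  out
}
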