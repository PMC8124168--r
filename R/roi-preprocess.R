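# ROI pre-processing: segmentation masks exported from manual contouring have
# coarse, slice-wise boundaries. Before texture extraction the lesion mask is
# smoothed by iteratively replacing each 26-connected component by its 3D
# convex hull and merging hulls that touch or overlap, until the mask is a
# fixed point (every component convex). Components too small to span a 3D
# hull (fewer than 4 affinely independent voxel centers) are dropped as
# outliers. The ratio of the kept original volume to the hull volume is
# itself a shape feature.

neighbor_offsets <- function(connectivity = 26L) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
    "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
    "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
    "26" = g,
    abort("`connectivity` must be one of 6, 18, 26."))
}

#' Connected components of a binary voxel mask
#'
#' Partitions the true voxels of a 3D mask into connected components under
#' face (6), face+edge (18) or full face+edge+corner (26) adjacency. The
#' pipeline default is 26-connectivity, under which diagonally touching
#' voxels belong to one component.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param connectivity One of 6, 18, 26 (default 26).
#' @return A list of 3D logical arrays, one per component, partitioning the
#'   true voxels. Components are ordered by their first voxel in array order.
#' @export
connected_components <- function(mask, connectivity = 26L) {
  m <- assert_mask(mask)
  dims <- dim(m)
  vox <- which(m)
  rank <- array(0L, dims)
  rank[vox] <- seq_along(vox)
  idx <- arrayInd(vox, dims)
  offs <- neighbor_offsets(connectivity)
  # half set: each unordered adjacency once
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, -offs[r, ])  # idx + offset
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    to <- rank[nb[ok, , drop = FALSE]]
    from <- seq_along(vox)[ok]
    keep <- to > 0L
    if (any(keep)) edges <- rbind(edges, cbind(from[keep], to[keep]))
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # relabel components by first occurrence so ordering is deterministic
  memb <- match(memb, unique(memb))
  lapply(seq_len(max(memb)), function(k) {
    comp <- array(FALSE, dims)
    comp[vox[memb == k]] <- TRUE
    comp
  })
}

#' Convex hull of a single mask component
#'
#' Rasterized 3D convex hull of a connected component: every voxel whose
#' center lies inside or on the convex polytope of the component's voxel
#' centers (half-space tests with tolerance 1e-9). Components with fewer than
#' 4 affinely independent voxel centers admit no 3D hull and are flagged as
#' outliers by returning `NULL`.
#'
#' @param component 3D logical array holding one connected component.
#' @return A 3D logical hull mask, or `NULL` when the component is an
#'   outlier (degenerate point set).
#' @export
voxel_hull <- function(component) {
  m <- assert_mask(component)
  idx <- which(m, arr.ind = TRUE)
  h <- hull_mask_of_points(idx, dim(m))
  if (is.null(h)) return(NULL)
  h | m  # numerical safety: the component is inside its own hull by definition
}

#' Iterative convex-hull smoothing of a lesion mask
#'
#' Splits the mask into 26-connected components, drops degenerate outlier
#' components, replaces each remaining component by its rasterized convex
#' hull, then re-extracts 26-connected components of the union of hulls and
#' re-hulls any component formed by touching or overlapping hulls. Iterates
#' until every component is convex (its own hull adds no voxels). The result
#' is the definitive ROI used by all feature extractors.
#'
#' @param mask 3D logical (or 0/1) array; the raw segmentation label map.
#' @param max_iter Safety cap on hull-merge iterations.
#' @return An object of class `hull_result`: list with `hull_mask` (3D logical
#'   array), `n_iterations`, `dropped_outlier_voxels`, `kept_original_voxels`,
#'   `original_voxels`, and `volume_ratio` = kept original voxels / hull
#'   voxels.
#' @export
iterative_hull <- function(mask, max_iter = 100L) {
  m <- assert_mask(mask)
  comps <- connected_components(m, 26L)
  hulls <- lapply(comps, voxel_hull)
  outlier <- vapply(hulls, is.null, logical(1))
  if (all(outlier))
    abort("Degenerate ROI: every 26-connected component is an outlier (no 3D hull exists).")
  dropped <- sum(vapply(comps[outlier], sum, numeric(1)))
  kept_original <- m
  for (co in comps[outlier]) kept_original <- kept_original & !co

  current <- Reduce(`|`, hulls[!outlier])
  n_iter <- 1L
  repeat {
    comps2 <- connected_components(current, 26L)
    hulls2 <- lapply(comps2, voxel_hull)
    nxt <- Reduce(`|`, hulls2)
    if (sum(nxt) == sum(current)) break
    current <- nxt
    n_iter <- n_iter + 1L
    if (n_iter > max_iter) abort("iterative_hull failed to converge.")
  }

  structure(
    list(hull_mask = current,
         n_iterations = n_iter,
         dropped_outlier_voxels = as.integer(dropped),
         kept_original_voxels = as.integer(sum(kept_original)),
         original_voxels = as.integer(sum(m)),
         volume_ratio = hull_volume_ratio(kept_original, current)),
    class = "hull_result")
}

#' @export
print.hull_result <- function(x, ...) {
  cat("<hull_result>\n")
  cat(sprintf("  hull voxels:            %d\n", sum(x$hull_mask)))
  cat(sprintf("  kept original voxels:   %d (of %d; %d dropped as outliers)\n",
              x$kept_original_voxels, x$original_voxels, x$dropped_outlier_voxels))
  cat(sprintf("  iterations:             %d\n", x$n_iterations))
  cat(sprintf("  volume ratio:           %.4f\n", x$volume_ratio))
  invisible(x)
}

#' @method glance hull_result
#' @export
glance.hull_result <- function(x, ...) {
  tibble(hull_voxels = sum(x$hull_mask),
         kept_original_voxels = x$kept_original_voxels,
         original_voxels = x$original_voxels,
         dropped_outlier_voxels = x$dropped_outlier_voxels,
         n_iterations = x$n_iterations,
         volume_ratio = x$volume_ratio)
}

#' ROI volume to convex-hull volume ratio
#'
#' Fraction of the hull actually occupied by the (outlier-filtered) original
#' segmentation: 1 for a convex lesion, small for spiculated or multifocal
#' lesions whose hull fills in concavities.
#'
#' @param original 3D logical array; the original (kept) ROI voxels.
#' @param hull 3D logical array; the hull mask containing `original`.
#' @return A fraction in (0, 1].
#' @export
hull_volume_ratio <- function(original, hull) {
  o <- assert_mask(original)
  h <- assert_mask(hull)
  if (any(o & !h)) abort("`original` must be contained in `hull`.")
  sum(o) / sum(h)
}
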