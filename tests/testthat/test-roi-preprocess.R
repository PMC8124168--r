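# Convex-hull ROI preprocessing: connected components, voxel hulls,
# iterative merging and the volume-ratio feature.

test_that("26-connectivity joins corner-touching voxels that 6-connectivity separates", {
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- TRUE
  m[3, 3, 3] <- TRUE
  expect_length(connected_components(m, 26), 1L)
  expect_length(connected_components(m, 6), 2L)
  expect_length(connected_components(m, 18), 2L)
  m2 <- array(FALSE, c(4, 4, 4))
  m2[2, 2, 2] <- TRUE
  m2[3, 3, 2] <- TRUE  # edge-touching: 18 joins, 6 splits
  expect_length(connected_components(m2, 18), 1L)
  expect_length(connected_components(m2, 6), 2L)
})

test_that("connected components match a flood-fill oracle on random masks", {
  for (seed in 1:3) {
    m <- random_mask(c(10, 10, 10), p = 0.25, seed = seed)
    if (!any(m)) next
    for (conn in c(6, 18, 26)) {
      got <- connected_components(m, conn)
      want <- flood_fill_components(m, conn)
      expect_identical(partition_fingerprint(got), partition_fingerprint(want),
                       info = sprintf("seed %d conn %d", seed, conn))
    }
  }
})

test_that("voxel_hull reproduces convex shapes and fills corner frames", {
  box <- array(FALSE, c(7, 7, 7))
  box[2:6, 2:6, 2:6] <- TRUE
  expect_identical(voxel_hull(box), box)

  corners <- array(FALSE, c(7, 7, 7))
  for (x in c(2, 6)) for (y in c(2, 6)) for (z in c(2, 6))
    corners[x, y, z] <- TRUE
  expect_identical(voxel_hull(corners), box)
})

test_that("degenerate components (line, plane, points) are outliers", {
  line <- array(FALSE, c(12, 5, 5))
  line[2:11, 3, 3] <- TRUE
  expect_null(voxel_hull(line))

  plane <- array(FALSE, c(8, 8, 3))
  plane[2:6, 2:6, 2] <- TRUE
  expect_null(voxel_hull(plane))

  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_null(voxel_hull(single))
})

test_that("voxel_hull agrees with the exhaustive tetrahedron-membership oracle", {
  set.seed(42)
  for (rep in 1:3) {
    dims <- c(9, 9, 9)
    pts <- unique(cbind(sample(2:8, 10, TRUE), sample(2:8, 10, TRUE),
                        sample(2:8, 10, TRUE)))
    m <- array(FALSE, dims)
    m[pts] <- TRUE
    got <- lnradiomics:::hull_mask_of_points(which(m, arr.ind = TRUE), dims)
    if (is.null(got)) next  # degenerate draw; covered above
    want <- brute_hull_mask(which(m, arr.ind = TRUE), dims)
    expect_identical(got, want, info = sprintf("rep %d", rep))
  }
})

test_that("iterative_hull converges in one pass on a convex blob and is idempotent", {
  m <- make_ellipsoid_mask(c(20, 20, 20), c(10, 10, 10), c(6, 5, 4))
  res <- iterative_hull(m)
  expect_equal(res$n_iterations, 1L)
  expect_true(all(m[res$hull_mask == FALSE] == FALSE))  # mask inside hull
  # idempotence and convexity: re-running on the hull changes nothing
  res2 <- iterative_hull(res$hull_mask)
  expect_identical(res2$hull_mask, res$hull_mask)
  expect_identical(voxel_hull(res$hull_mask), res$hull_mask)
  # monotonicity
  expect_gte(sum(res$hull_mask), res$kept_original_voxels)
})

test_that("overlapping hulls merge into one; far-apart hulls stay separate", {
  dims <- c(20, 8, 10)
  # component A: a dumbbell (two cubes joined by a rod) whose hull fills the
  # whole slab; component B: a cube above the slab's middle, not touching A
  # itself but 26-adjacent to A's hull
  two <- array(FALSE, dims)
  two[2:4, 2:4, 2:4] <- TRUE
  two[14:16, 2:4, 2:4] <- TRUE
  two[2:16, 3, 3] <- TRUE
  two[8:10, 2:4, 5:7] <- TRUE
  comps <- connected_components(two, 26)
  expect_length(comps, 2L)  # construction check: genuinely split
  res <- iterative_hull(two)
  expect_gte(res$n_iterations, 2L)
  expect_length(connected_components(res$hull_mask, 26), 1L)
  # final mask equals the hull of the union of kept voxels (half-space oracle)
  want <- lnradiomics:::hull_mask_of_points(which(two, arr.ind = TRUE), dims)
  expect_identical(res$hull_mask, want)

  far <- array(FALSE, c(24, 10, 10))
  far[2:5, 2:5, 2:5] <- TRUE
  far[19:22, 6:9, 6:9] <- TRUE
  resf <- iterative_hull(far)
  expect_equal(resf$n_iterations, 1L)
  expect_length(connected_components(resf$hull_mask, 26), 2L)
})

test_that("outlier components are dropped and counted", {
  m <- make_ellipsoid_mask(c(20, 20, 20), c(10, 10, 10), c(5, 5, 5))
  m[2, 2, 2] <- TRUE   # isolated voxel: outlier
  m[18, 2, 2] <- TRUE  # another
  res <- iterative_hull(m)
  expect_equal(res$dropped_outlier_voxels, 2L)
  expect_false(res$hull_mask[2, 2, 2])
  # all-outlier mask errors
  solo <- array(FALSE, c(6, 6, 6)); solo[3, 3, 3] <- TRUE
  expect_error(iterative_hull(solo), "outlier")
})

test_that("volume ratio is exact counting and 1 for convex masks", {
  box <- array(FALSE, c(7, 7, 7)); box[2:6, 2:6, 2:6] <- TRUE
  corners <- array(FALSE, c(7, 7, 7))
  for (x in c(2, 6)) for (y in c(2, 6)) for (z in c(2, 6)) corners[x, y, z] <- TRUE
  expect_equal(hull_volume_ratio(corners, box), 8 / 125)
  expect_equal(iterative_hull(box)$volume_ratio, 1.0)
  expect_error(hull_volume_ratio(box, corners), "contained")

  lesion <- simulate_lesion(c(24, 24, 24), spicule_count = 8, seed = 9)
  res <- iterative_hull(lesion$mask)
  expect_equal(res$volume_ratio, sum(lesion$mask) / sum(res$hull_mask))
})
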