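# 3D grey-level co-occurrence matrices and their 7 measures.

test_that("the displacement set is the 26 nonzero unit vectors", {
  d <- displacement_set()
  expect_equal(nrow(d), 26L)
  expect_false(any(rowSums(abs(d)) == 0))
  expect_equal(nrow(unique(d)), 26L)
  keys <- apply(d, 1, paste, collapse = ",")
  expect_true(all(c("1,0,0", "-1,0,0") %in% keys))
})

test_that("a two-voxel pair counts once and reverses under -d", {
  vol <- array(0L, c(1, 1, 2))
  vol[1, 1, 1] <- 3L; vol[1, 1, 2] <- 5L
  msk <- array(TRUE, c(1, 1, 2))
  g <- glcm3(vol, msk, c(0, 0, 1), n_levels = 8)
  expect_equal(g$n_pairs, 1)
  expect_equal(g$counts[4, 6], 1)  # (gi=3, gj=5), 1-based indexing
  gr <- glcm3(vol, msk, c(0, 0, -1), n_levels = 8)
  expect_equal(gr$counts[6, 4], 1)
  expect_identical(g$counts, t(gr$counts))
})

test_that("a constant ROI concentrates all mass on one diagonal cell", {
  vol <- array(9L, c(4, 4, 4))
  msk <- array(TRUE, c(4, 4, 4))
  g <- glcm3(vol, msk, c(1, 0, 0), n_levels = 16)
  expect_equal(sum(g$counts), g$n_pairs)
  expect_equal(g$counts[10, 10], g$n_pairs)
  m <- glcm3_measures(g)
  expect_equal(unname(m["inertia"]), 0)
  expect_equal(unname(m["abs_contrast"]), 0)
  expect_equal(unname(m["entropy"]), 0)
  expect_equal(unname(m["energy"]), 1)
  expect_equal(unname(m["homogeneity"]), 1)
})

test_that("a single off-diagonal cell gives the closed-form measures", {
  g <- structure(list(counts = {
    cm <- matrix(0, 8, 8); cm[4, 6] <- 1; cm  # (gi=3, gj=5)
  }, displacement = c(0L, 0L, 1L), n_pairs = 1, n_levels = 8L),
  class = "glcm3")
  m <- glcm3_measures(g)
  expect_equal(unname(m["inertia"]), 4)       # (3-5)^2
  expect_equal(unname(m["abs_contrast"]), 2)  # |3-5|
  expect_equal(unname(m["covariance"]), 0)    # point distribution
  expect_equal(unname(m["autocorrelation"]), 15)
  expect_equal(unname(m["homogeneity"]), 1 / 3)
})

test_that("pair counts match the exhaustive double-loop oracle in all 26 directions", {
  set.seed(21)
  vol <- array(sample(0:7, 8^3, TRUE), c(8, 8, 8))
  msk <- random_mask(c(8, 8, 8), 0.6, seed = 22)
  disp <- displacement_set()
  for (r in seq_len(nrow(disp))) {
    got <- glcm3(vol, msk, disp[r, ], n_levels = 8)
    want <- brute_glcm(vol, msk, disp[r, ], 8)
    expect_equal(got$counts, want, info = rownames(disp)[r])
    expect_equal(got$n_pairs, sum(want))
  }
})

test_that("measures match the naive per-cell oracle on random matrices", {
  set.seed(5)
  for (rep in 1:5) {
    cm <- matrix(rpois(64, 1), 8, 8)
    if (sum(cm) == 0) cm[2, 3] <- 2
    g <- structure(list(counts = cm, displacement = c(1L, 0L, 0L),
                        n_pairs = sum(cm), n_levels = 8L), class = "glcm3")
    expect_equal(unclass(glcm3_measures(g)), brute_glcm_measures(cm),
                 tolerance = 1e-12)
  }
})

test_that("transpose symmetry: symmetric measures agree for d and -d", {
  lesion <- simulate_lesion(c(20, 20, 20), seed = 31)
  q <- quantize_volume(lesion$volume, lesion$mask, bits = 4)
  sym <- c("energy", "entropy", "inertia", "abs_contrast", "homogeneity",
           "autocorrelation")
  for (d in list(c(1, 0, 0), c(1, 1, 0), c(1, -1, 1))) {
    g1 <- glcm3(q, lesion$mask, d, n_levels = 16)
    g2 <- glcm3(q, lesion$mask, -d, n_levels = 16)
    expect_identical(g1$counts, t(g2$counts))
    m1 <- glcm3_measures(g1); m2 <- glcm3_measures(g2)
    expect_equal(m1[sym], m2[sym], tolerance = 1e-12)
  }
})

test_that("glcm3_block emits 182 features that track direction mirroring", {
  lesion <- simulate_lesion(c(18, 18, 18), seed = 41)
  blk <- glcm3_block(lesion$volume, lesion$mask, bits = 4)
  expect_length(blk, 182L)
  expect_equal(sum(startsWith(names(blk), "glcm3_energy_")), 26L)

  # constant ROI: all 26 energies are 1
  cvol <- array(7L, c(16, 16, 16))
  cmask <- make_ellipsoid_mask(c(16, 16, 16), c(8, 8, 8), c(5, 5, 5))
  cblk <- glcm3_block(cvol, cmask, bits = 4)
  expect_true(all(cblk[startsWith(names(cblk), "glcm3_energy_")] == 1))

  # mirroring the volume along x permutes features to the mirrored direction
  mvol <- lesion$volume[dim(lesion$volume)[1]:1, , ]
  mmask <- lesion$mask[dim(lesion$mask)[1]:1, , ]
  mblk <- glcm3_block(mvol, mmask, bits = 4)
  for (nm in c("glcm3_entropy_(1.0.0)", "glcm3_inertia_(1.1.0)",
               "glcm3_autocorrelation_(1.0.1)")) {
    mirrored <- sub("\\((-?\\d+)\\.", "(\\1m.", nm)  # placeholder
    d <- as.integer(strsplit(gsub("[()]", "", sub(".*_\\(", "(", nm)), "\\.")[[1]])
    nm2 <- sub("\\(.*\\)", sprintf("(%d.%d.%d)", -d[1], d[2], d[3]), nm)
    expect_equal(unname(mblk[nm]), unname(blk[nm2]), tolerance = 1e-10,
                 info = paste(nm, "->", nm2), ignore_attr = TRUE)
  }
})

test_that("zero-pair directions emit warned sentinels", {
  vol <- array(5L, c(3, 3, 3))
  msk <- array(FALSE, c(3, 3, 3)); msk[2, 2, 2] <- TRUE
  g <- glcm3(vol, msk, c(1, 0, 0), n_levels = 8)
  expect_equal(g$n_pairs, 0)
  expect_warning(m <- glcm3_measures(g), "zero valid pairs")
  expect_true(all(m == 0))
})
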