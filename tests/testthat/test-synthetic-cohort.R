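# Synthetic cohort generator: label bookkeeping, determinism, planted
# effects and disk round-trip.

test_that("the default imbalance yields 27 positives in a 99-case cohort", {
  spec <- cohort_spec(n_cases = 99, positive_fraction = 27 / 99,
                      grid_shape = c(16, 16, 16), seed = 7)
  coh <- simulate_cohort(spec)
  expect_equal(nrow(coh), 99L)
  expect_equal(sum(coh$label == 1), 27L)
  expect_equal(sum(coh$label == 0), 72L)
})

test_that("identical spec and seed reproduce the cohort; different seeds differ", {
  spec <- cohort_spec(n_cases = 6, positive_fraction = 0.33,
                      grid_shape = c(18, 18, 18), seed = 5)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$volume, b$volume)
  expect_identical(a$mask, b$mask)
  expect_identical(dplyr::select(a, -volume, -mask),
                   dplyr::select(b, -volume, -mask))

  spec2 <- cohort_spec(n_cases = 6, positive_fraction = 0.33,
                       grid_shape = c(18, 18, 18), seed = 6)
  c2 <- simulate_cohort(spec2)
  expect_false(identical(a$volume, c2$volume))
  expect_equal(sum(a$label), sum(c2$label))  # same counts, different draws
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n_cases = 3), "at least 4")
  expect_error(cohort_spec(positive_fraction = 0), "strictly between")
  expect_error(cohort_spec(positive_fraction = 1), "strictly between")
  expect_error(cohort_spec(grid_shape = c(8, 32, 32)), ">= 16")
  expect_error(cohort_spec(texture_effect = -1), "nonnegative")
})

test_that("lesions are connected, inside the grid margin, and seed-stable", {
  for (seed in c(2, 12)) {
    les <- simulate_lesion(c(24, 24, 24), spicule_count = 5, seed = seed)
    expect_length(connected_components(les$mask, 26), 1L)
    idx <- which(les$mask, arr.ind = TRUE)
    expect_true(all(idx >= 3) && all(idx <= 22))  # >= 2 empty voxels per side
  }
  a <- simulate_lesion(c(20, 20, 20), seed = 3)
  b <- simulate_lesion(c(20, 20, 20), seed = 3)
  expect_identical(a$mask, b$mask)
  expect_identical(a$volume, b$volume)
})

test_that("ellipsoids are near-convex while spiculated lesions are not", {
  core <- simulate_lesion(c(28, 28, 28), spicule_count = 0, seed = 8)
  smooth_ratio <- iterative_hull(core$mask)$volume_ratio
  expect_gte(smooth_ratio, 0.95)

  spic <- simulate_lesion(c(28, 28, 28), spicule_count = 8, seed = 8)
  spic_ratio <- iterative_hull(spic$mask)$volume_ratio
  expect_lt(spic_ratio, smooth_ratio)
})

test_that("semantic marginals reproduce the published frequencies", {
  set.seed(1)
  n <- 10000
  draws <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    sample_semantic(label = 0L, semantic_effect = 0, seed = i)[, c("histotype", "menopause")]))
  p_hist <- prop.table(table(draws$histotype))
  expect_equal(unname(p_hist[["IDC"]]), 83 / 99, tolerance = 0.02 / 0.84)
  expect_equal(unname(p_hist[["ILC"]]), 12 / 99, tolerance = 0.02 / 0.12)
  expect_equal(unname(p_hist[["medullary"]]), 4 / 99, tolerance = 0.02 / 0.04)
  expect_equal(mean(draws$menopause), 57 / 99, tolerance = 0.02 / 0.58)
})

test_that("semantic_effect = 0 leaves histotype independent of the label", {
  labs <- rep(c(0L, 1L), 500)
  hist0 <- vapply(seq_along(labs), function(i)
    sample_semantic(label = labs[i], semantic_effect = 0,
                    seed = 5000 + i)$histotype, character(1))
  tab <- table(hist0, labs)
  p <- suppressWarnings(stats::chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("frequency vectors must sum to one", {
  freq <- default_semantic_frequencies()
  freq$histotype <- c(IDC = 0.5, ILC = 0.3, medullary = 0.3)
  expect_error(sample_semantic(freq, seed = 1), "sum to 1")
})

test_that("texture_effect = 0 plants no class difference in texture statistics", {
  spec <- cohort_spec(n_cases = 200, positive_fraction = 0.5,
                      texture_effect = 0, grid_shape = c(16, 16, 16), seed = 11)
  coh <- simulate_cohort(spec)
  fo_sd <- vapply(seq_len(nrow(coh)), function(i)
    first_order_block(coh$volume[[i]], coh$mask[[i]])[["fo_sd"]], numeric(1))
  p <- stats::t.test(fo_sd[coh$label == 1], fo_sd[coh$label == 0])$p.value
  expect_gt(p, 0.01)
})

test_that("cohorts round-trip losslessly through NIfTI + CSV + JSON", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_cases = 4, positive_fraction = 0.5,
                      grid_shape = c(16, 16, 16), seed = 9)
  coh <- simulate_cohort(spec)
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$case_id, coh$case_id)
  expect_equal(back$label, coh$label)
  for (i in 1:4) {
    expect_equal(back$volume[[i]], coh$volume[[i]], ignore_attr = TRUE)
    expect_equal(back$mask[[i]], coh$mask[[i]], ignore_attr = TRUE)
  }
  expect_equal(as.data.frame(back[names(coh)][, -c(3, 4)]),
               as.data.frame(coh[, -c(3, 4)]))
})
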