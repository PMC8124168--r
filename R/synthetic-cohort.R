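# Seeded synthetic cohorts: textured ellipsoidal-to-spiculated lesions whose
# in-mask texture statistics differ by lymph-node class, plus semantic tables
# drawn from the published category frequencies and the 27-positive /
# 72-negative class imbalance. Intensities are in arbitrary units (the
# subtracted-phase units of the source images are not standardized).

#' Specification of a synthetic cohort
#'
#' @param n_cases Number of lesions (>= 4).
#' @param positive_fraction Fraction of node-positive cases in (0, 1);
#'   default 27/99, the published cohort imbalance.
#' @param texture_effect Nonnegative effect size controlling how strongly the
#'   in-lesion texture (noise variance and correlation length) differs
#'   between classes; 0 plants no signal.
#' @param semantic_effect Nonnegative effect size controlling the
#'   label-dependence of the histotype field; 0 plants no signal.
#' @param grid_shape Integer length-3 voxel grid (each >= 16).
#' @param bit_depth Bits per voxel of the generated volumes (default 8).
#' @param spicule_rate Mean number of radial spicules per lesion (Poisson).
#' @param seed Integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 99L, positive_fraction = 27 / 99,
                        texture_effect = 1, semantic_effect = 1,
                        grid_shape = c(32L, 32L, 32L), bit_depth = 8L,
                        spicule_rate = 3, seed = 1L) {
  if (n_cases < 4L) abort("`n_cases` must be at least 4.")
  if (positive_fraction <= 0 || positive_fraction >= 1)
    abort("`positive_fraction` must lie strictly between 0 and 1.")
  if (texture_effect < 0 || semantic_effect < 0)
    abort("Effect sizes must be nonnegative.")
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    abort("`grid_shape` must be 3 integers, each >= 16.")
  structure(list(n_cases = as.integer(n_cases),
                 positive_fraction = positive_fraction,
                 texture_effect = texture_effect,
                 semantic_effect = semantic_effect,
                 grid_shape = as.integer(grid_shape),
                 bit_depth = as.integer(bit_depth),
                 spicule_rate = spicule_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Class-conditional texture parameters. Intensities are arbitrary units on a
# 2^bit_depth - 1 scale; the positive class gets a longer correlation length
# and a larger in-lesion variance, scaled multiplicatively by the effect size.
class_texture_params <- function(label, texture_effect, bit_depth = 8L) {
  full <- 2^bit_depth - 1
  base <- list(level = 0.55 * full, sd = 0.085 * full, sigma = 1.2,
               bg_level = 0.08 * full, bg_sd = 0.025 * full)
  if (label == 1) {
    base$sd <- base$sd * (1 + 0.15 * texture_effect)
    base$sigma <- base$sigma * (1 + 0.30 * texture_effect)
  }
  base
}

# Separable Gaussian smoothing of a 3D array (replicate padding via edge
# clamping of the shifted sums).
gaussian_smooth3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  for (ax in 1:3) {
    dims <- dim(x)
    out <- array(0, dims)
    n <- dims[ax]
    for (t in -half:half) {
      src <- pmin(pmax(seq_len(n) + t, 1L), n)  # clamped shift
      out <- out + k[t + half + 1] * switch(ax,
        x[src, , , drop = FALSE],
        x[, src, , drop = FALSE],
        x[, , src, drop = FALSE])
    }
    x <- out
  }
  x
}

#' Simulate one textured lesion volume and mask
#'
#' The lesion is an axis-aligned ellipsoid plus a Poisson number of radial
#' spicules (thin cones), kept strictly inside the grid with a margin of at
#' least 2 voxels so unit-displacement pair lookups never leave the grid.
#' In-mask intensities follow base level + Gaussian-correlated noise with
#' class-specific correlation length and variance, quantized to the volume
#' bit depth; the background is low-level i.i.d. noise.
#'
#' @param grid_shape Integer length-3 grid (each >= 16).
#' @param params Texture parameter list (see the `texture_effect` machinery
#'   in [cohort_spec()]); defaults to the node-negative class.
#' @param spicule_count Number of spicules; `NULL` draws Poisson(`spicule_rate`).
#' @param spicule_rate Poisson mean used when `spicule_count` is `NULL`.
#' @param bit_depth Bits per voxel.
#' @param seed Integer seed.
#' @return List with integer 3D `volume` and logical 3D `mask`.
#' @export
simulate_lesion <- function(grid_shape = c(32L, 32L, 32L),
                            params = class_texture_params(0, 0),
                            spicule_count = NULL, spicule_rate = 3,
                            bit_depth = 8L, seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    abort("`grid_shape` must be 3 integers, each >= 16.")
  set.seed(derive_seed(seed, 7L))
  dims <- as.integer(grid_shape)
  margin <- 2.6  # keeps >= 2 empty voxels on every side of the mask
  ctr <- dims / 2 + runif(3, -1, 1)
  semi <- runif(3, dims / 7, dims / 4.8)
  if (is.null(spicule_count)) spicule_count <- rpois(1, spicule_rate)
  spic_len <- if (spicule_count > 0) runif(spicule_count, 2, 4.5) else numeric(0)
  max_reach <- max(semi) + if (length(spic_len)) max(spic_len) else 0
  allowed <- min(pmin(ctr, dims + 1 - ctr)) - margin
  if (max_reach > allowed) {  # rescale so lesion plus spicules keep the margin
    scl <- allowed / max_reach
    semi <- semi * scl
    spic_len <- spic_len * scl
  }
  if (any(semi < 1.2))
    abort("Lesion cannot fit inside the grid with the required margin.")

  ax <- seq_len(dims[1]); ay <- seq_len(dims[2]); az <- seq_len(dims[3])
  X <- array(ax, dims)
  Y <- array(rep(ay, each = dims[1]), dims)
  Z <- array(rep(az, each = dims[1] * dims[2]), dims)
  mask <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
    ((Z - ctr[3]) / semi[3])^2 <= 1

  # radial spicules: voxels within ~1.1 voxels of a surface-anchored segment
  for (s in seq_len(spicule_count)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    # anchor on the ellipsoid surface along u
    tt <- 1 / sqrt(sum((u / semi)^2))
    a <- ctr + 0.92 * tt * u
    b <- a + spic_len[s] * u
    lo <- pmax(floor(pmin(a, b)) - 2L, 1L)
    hi <- pmin(ceiling(pmax(a, b)) + 2L, dims)
    sub <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3]))
    ap <- sweep(sub, 2, a)
    ab <- b - a
    t0 <- pmin(pmax(drop(ap %*% ab) / sum(ab^2), 0), 1)
    d2 <- rowSums((ap - outer(t0, ab))^2)
    hit <- sub[d2 <= 1.1^2, , drop = FALSE]
    if (nrow(hit)) mask[hit] <- TRUE
  }

  full <- 2^bit_depth - 1
  noise <- gaussian_smooth3(array(rnorm(prod(dims)), dims), params$sigma)
  # standardize over the mask so the planted in-lesion mean and sd are exact
  # regardless of the correlation length
  noise <- (noise - mean(noise[mask])) / sd(noise[mask])
  vol <- params$bg_level + rnorm(prod(dims), 0, params$bg_sd)
  vol <- array(vol, dims)
  vol[mask] <- params$level + params$sd * noise[mask]
  vol <- round(pmin(pmax(vol, 0), full))
  storage.mode(vol) <- "integer"
  list(volume = vol, mask = mask)
}

#' Published marginal frequencies of the semantic categories
#'
#' Category probabilities for the categorical semantic fields, matching the
#' observed cohort frequencies (each field normalized to sum to 1). The
#' lesion localization field, for which no frequencies were published, uses a
#' plausible fixed distribution.
#'
#' @return Named list of per-field probability vectors.
#' @export
default_semantic_frequencies <- function() {
  norm <- function(x) x / sum(x)
  list(
    familiarity = norm(c(none = 62, "1" = 33, ">1" = 4)),
    hormone_therapy = norm(c("0" = 89, "1" = 10)),
    menopause = norm(c("0" = 42, "1" = 57)),
    curve_type = norm(c("1" = 3, "2" = 53, "3" = 43)),
    margins = norm(c(regular = 3, irregular = 46, lobulated = 30, spiculated = 20)),
    histotype = norm(c(IDC = 83, ILC = 12, medullary = 4)),
    grading = norm(c("1" = 12, "2" = 45, "3" = 42)),
    tumor_class = norm(c("Luminal A" = 39, "Luminal B" = 35, HER2 = 9, TN = 16)),
    localization = norm(c("retro-areolar" = 12, "upper-external" = 38,
                          "lower-external" = 18, "upper-internal" = 20,
                          "lower-internal" = 12))
  )
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# Draw raw immunohistochemistry values consistent with a tumor class, so that
# the derived class matches the sampled one.
sample_ihc_for_class <- function(class) {
  switch(class,
    "Luminal A" = list(er = runif(1, 25, 95), pgr = runif(1, 15, 90),
                       her2 = sample(0:2, 1), ki67 = runif(1, 1, 13.5)),
    "Luminal B" = list(er = runif(1, 25, 95), pgr = runif(1, 11, 90),
                       her2 = sample(0:3, 1), ki67 = runif(1, 15, 60)),
    "HER2" = list(er = runif(1, 0, 9), pgr = runif(1, 0, 9),
                  her2 = 3L, ki67 = runif(1, 10, 60)),
    "TN" = list(er = runif(1, 0, 9), pgr = runif(1, 0, 9),
                her2 = sample(0:2, 1), ki67 = runif(1, 5, 70))
  )
}

#' Sample one semantic record
#'
#' Categorical fields are drawn from the published marginal frequencies.
#' With `semantic_effect > 0` the histotype becomes label-dependent (for
#' node-positive cases the log-odds of ductal histology are raised by
#' `0.8 * semantic_effect` relative to the lobular/medullary alternatives);
#' with effect 0 the field is independent of the label. Raw
#' immunohistochemistry values are drawn consistently with the sampled tumor
#' class; age and diameter come from truncated normal / log-normal ranges
#' typical of a pre-operative breast-MRI population (age 37-82, mean 55.5).
#'
#' @param frequencies Per-field category probabilities (each summing to 1);
#'   see [default_semantic_frequencies()].
#' @param label Binary node status of the case.
#' @param semantic_effect Nonnegative label-dependence effect size.
#' @param seed Integer seed.
#' @return A one-row tibble of raw semantic fields.
#' @export
sample_semantic <- function(frequencies = default_semantic_frequencies(),
                            label = 0L, semantic_effect = 1, seed = 1L) {
  for (f in names(frequencies))
    if (abs(sum(frequencies[[f]]) - 1) > 1e-6)
      abort(sprintf("Frequencies for `%s` must sum to 1.", f))
  set.seed(derive_seed(seed, 13L))
  draw <- function(p) names(p)[sample.int(length(p), 1, prob = p)]

  p_hist <- frequencies$histotype
  if (semantic_effect > 0 && label == 1) {
    w <- log(p_hist)
    w["IDC"] <- w["IDC"] + 0.8 * semantic_effect
    p_hist <- exp(w) / sum(exp(w))
  }
  class <- draw(frequencies$tumor_class)
  ihc <- sample_ihc_for_class(class)
  tibble(
    age = round(rtrunc_norm(1, 55.48, 10, 37, 82), 1),
    menopause = as.integer(draw(frequencies$menopause)),
    hormone_therapy = as.integer(draw(frequencies$hormone_therapy)),
    familiarity = draw(frequencies$familiarity),
    localization = draw(frequencies$localization),
    margins = draw(frequencies$margins),
    max_diameter = round(min(max(exp(rnorm(1, log(22), 0.45)), 5), 80), 1),
    curve_type = as.integer(draw(frequencies$curve_type)),
    histotype = draw(p_hist),
    grading = as.integer(draw(frequencies$grading)),
    tumor_class = class,
    er_percent = round(ihc$er, 1),
    pgr_percent = round(ihc$pgr, 1),
    her2_score = as.integer(ihc$her2),
    ki67_percent = round(ihc$ki67, 1)
  )
}

#' Simulate a full synthetic cohort
#'
#' Generates `n_cases` lesions with exactly `round(n_cases *
#' positive_fraction)` node-positive labels, class-conditional texture, and
#' semantic records drawn from the published marginals. The same spec and
#' seed reproduce the cohort bit for bit.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per case: `case_id`, `label`, list-columns
#'   `volume` and `mask`, and the raw semantic fields.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a cohort_spec.")
  n <- spec$n_cases
  n_pos <- round(n * spec$positive_fraction)
  if (n_pos < 1 || n_pos > n - 1)
    abort("`positive_fraction` leaves a class empty at this cohort size.")
  set.seed(derive_seed(spec$seed, 1L))
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  cases <- purrr::map(seq_len(n), function(i) {
    case_seed <- derive_seed(spec$seed, 1000L + i)
    les <- simulate_lesion(spec$grid_shape,
                           class_texture_params(labels[i], spec$texture_effect,
                                                spec$bit_depth),
                           spicule_rate = spec$spicule_rate,
                           bit_depth = spec$bit_depth, seed = case_seed)
    sem <- sample_semantic(default_semantic_frequencies(), labels[i],
                           spec$semantic_effect, seed = case_seed)
    dplyr::bind_cols(
      tibble(case_id = sprintf("case_%03d", i), label = labels[i],
             volume = list(les$volume), mask = list(les$mask)),
      sem)
  })
  dplyr::bind_rows(cases)
}

#' Simulate a plain feature table with one planted discriminative feature
#'
#' A lightweight companion to the image-level generator for studying the
#' selection and classification stages in isolation: `feat_signal` is
#' label + Gaussian noise scaled so the planted class separation equals
#' `effect` standard deviations; the remaining features are pure noise.
#' Optionally the planted feature is duplicated to study redundancy
#' tie-breaking.
#'
#' @param n_cases Number of cases.
#' @param n_noise Number of noise features.
#' @param effect Planted effect size (standardized mean difference).
#' @param positive_fraction Fraction of positive labels.
#' @param duplicate_signal Add `feat_signal_dup`, an exact copy of the
#'   planted feature.
#' @param seed Integer seed.
#' @return Tibble with `case_id`, `label`, `feat_signal` and
#'   `feat_noise_01..`.
#' @export
simulate_feature_table <- function(n_cases = 200L, n_noise = 11L, effect = 1.5,
                                   positive_fraction = 27 / 99,
                                   duplicate_signal = FALSE, seed = 1L) {
  set.seed(derive_seed(seed, 29L))
  n_pos <- round(n_cases * positive_fraction)
  label <- sample(c(rep(1L, n_pos), rep(0L, n_cases - n_pos)))
  signal <- effect * label + rnorm(n_cases)
  noise <- matrix(rnorm(n_cases * n_noise), n_cases)
  colnames(noise) <- sprintf("feat_noise_%02d", seq_len(n_noise))
  out <- dplyr::bind_cols(
    tibble(case_id = sprintf("case_%03d", seq_len(n_cases)), label = label,
           feat_signal = signal),
    as_tibble(noise))
  if (duplicate_signal) out$feat_signal_dup <- out$feat_signal
  out
}
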