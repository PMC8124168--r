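# Independent brute-force oracles used to validate the package's vectorized
# implementations on small fixtures. These deliberately share no code with
# the package: flood fill by explicit stack walking, pair counting by double
# loops, hull membership by exhaustive tetrahedron tests, AUC by O(n^2)
# pair comparison, and histogram measures by naive per-bin loops.

# --- connected components: stack-based flood fill --------------------------
flood_fill_components <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  seen <- array(FALSE, dims)
  comps <- list()
  vox <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(vox))) {
    start <- vox[v, ]
    if (seen[start[1], start[2], start[3]]) next
    comp <- array(FALSE, dims)
    stack <- list(start)
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (seen[p[1], p[2], p[3]]) next
      seen[p[1], p[2], p[3]] <- TRUE
      comp[p[1], p[2], p[3]] <- TRUE
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (all(q >= 1) && all(q <= dims) &&
            mask[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]])
          stack[[length(stack) + 1L]] <- q
      }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# Canonical fingerprint of a component partition (order-independent).
partition_fingerprint <- function(comps) {
  sort(vapply(comps, function(c) paste(which(c), collapse = ","), character(1)))
}

# --- convex hull membership: exhaustive tetrahedron test -------------------
# A point is in the convex hull of a 3D point set iff it lies inside (or on)
# some tetrahedron formed by 4 of the points (Caratheodory). Only usable for
# small point sets.
point_in_tetra <- function(p, a, b, c, d, tol = 1e-9) {
  M <- cbind(b - a, c - a, d - a)
  if (abs(det(M)) < tol) return(FALSE)
  lam <- solve(M, p - a)
  all(lam >= -tol) && sum(lam) <= 1 + tol
}

brute_hull_mask <- function(points, dims) {
  out <- array(FALSE, dims)
  combs <- utils::combn(nrow(points), 4)
  grid <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                z = seq_len(dims[3])))
  for (g in seq_len(nrow(grid))) {
    p <- grid[g, ]
    for (k in seq_len(ncol(combs))) {
      q <- points[combs[, k], , drop = FALSE]
      if (point_in_tetra(p, q[1, ], q[2, ], q[3, ], q[4, ])) {
        out[p[1], p[2], p[3]] <- TRUE
        break
      }
    }
  }
  out
}

# --- GLCM: double-loop pair counting ---------------------------------------
brute_glcm <- function(qvol, mask, d, n_levels) {
  counts <- matrix(0, n_levels, n_levels)
  dims <- dim(qvol)
  vox <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(vox))) {
    p <- vox[v, ]
    q <- p + d
    if (any(q < 1) || any(q > dims)) next
    if (!mask[q[1], q[2], q[3]]) next
    gi <- qvol[p[1], p[2], p[3]]
    gj <- qvol[q[1], q[2], q[3]]
    counts[gi + 1, gj + 1] <- counts[gi + 1, gj + 1] + 1
  }
  counts
}

# Naive per-cell GLCM measures.
brute_glcm_measures <- function(counts) {
  n <- sum(counts)
  N <- nrow(counts)
  P <- counts / n
  mu_r <- 0; mu_c <- 0
  for (i in 1:N) for (j in 1:N) {
    mu_r <- mu_r + (i - 1) * P[i, j]
    mu_c <- mu_c + (j - 1) * P[i, j]
  }
  out <- c(autocorrelation = 0, homogeneity = 0, entropy = 0, energy = 0,
           covariance = 0, inertia = 0, abs_contrast = 0)
  for (i in 1:N) for (j in 1:N) {
    p <- P[i, j]
    gi <- i - 1; gj <- j - 1
    out["autocorrelation"] <- out["autocorrelation"] + gi * gj * p
    out["homogeneity"] <- out["homogeneity"] + p / (1 + abs(gi - gj))
    if (p > 0) out["entropy"] <- out["entropy"] - p * log2(p)
    out["energy"] <- out["energy"] + p^2
    out["covariance"] <- out["covariance"] + (gi - mu_r) * (gj - mu_c) * p
    out["inertia"] <- out["inertia"] + (gi - gj)^2 * p
    out["abs_contrast"] <- out["abs_contrast"] + abs(gi - gj) * p
  }
  out
}

# --- AUC: O(n^2) pair counting ---------------------------------------------
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# --- first-order measures: naive scalar implementation ---------------------
brute_first_order <- function(counts, mids, window = 2) {
  n <- sum(counts)
  p <- counts / n
  B <- length(counts)
  mu <- 0; for (b in 1:B) mu <- mu + p[b] * mids[b]
  v <- 0; for (b in 1:B) v <- v + p[b] * (mids[b] - mu)^2
  s <- sqrt(v)
  sk <- 0; ku <- 0
  if (s > 0) {
    for (b in 1:B) sk <- sk + p[b] * ((mids[b] - mu) / s)^3
    for (b in 1:B) ku <- ku + p[b] * ((mids[b] - mu) / s)^4
  }
  occ <- which(counts > 0)
  width <- mids[max(occ)] - mids[min(occ)]
  ent <- 0; for (b in 1:B) if (p[b] > 0) ent <- ent - p[b] * log2(p[b])
  en <- 0; for (b in 1:B) en <- en + p[b]^2
  imax <- which.max(counts)
  e_abs <- 0
  for (b in max(1, imax - window):min(B, imax + window)) e_abs <- e_abs + p[b]^2
  peaks <- integer(0)
  for (b in 1:B) {
    l <- if (b > 1) counts[b - 1] else -Inf
    r <- if (b < B) counts[b + 1] else -Inf
    if (counts[b] > l && counts[b] > r) peaks <- c(peaks, b)
  }
  win <- integer(0)
  for (pk in peaks) win <- union(win, max(1, pk - window):min(B, pk + window))
  e_rel <- 0; for (b in win) e_rel <- e_rel + p[b]^2
  c(mean = mu, sd = s, skewness = sk, kurtosis = ku, width = width,
    entropy = ent, energy = en, max_value = p[imax], max_grey = mids[imax],
    energy_abs_max = e_abs, n_rel_max = length(peaks), energy_rel_max = e_rel)
}

# --- LBP code-space enumeration --------------------------------------------
# Rotation classes and uniformity by explicit string manipulation.
enumerate_lbp_classes <- function(P = 8) {
  codes <- 0:(2^P - 1)
  to_bits <- function(x) as.integer(intToBits(x))[1:P]
  rot_min <- integer(length(codes))
  transitions <- integer(length(codes))
  for (i in seq_along(codes)) {
    b <- to_bits(codes[i])
    vals <- integer(P)
    for (k in 0:(P - 1)) {
      rb <- c(b[(k + 1):P], b[seq_len(k)])
      vals[k + 1] <- sum(rb * 2^(0:(P - 1)))
    }
    rot_min[i] <- min(vals)
    transitions[i] <- sum(b != c(b[-1], b[1]))
  }
  list(n_ri = length(unique(rot_min)),
       n_uniform = sum(transitions <= 2),
       n_u_bins = sum(transitions <= 2) + 1L,
       n_uri_bins = length(unique(rot_min[transitions <= 2])) + 1L,
       rot_min = rot_min, transitions = transitions)
}

# --- small geometric fixtures ----------------------------------------------
make_ellipsoid_mask <- function(dims, ctr, semi) {
  X <- array(seq_len(dims[1]), dims)
  Y <- array(rep(seq_len(dims[2]), each = dims[1]), dims)
  Z <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims)
  ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
    ((Z - ctr[3]) / semi[3])^2 <= 1
}

random_mask <- function(dims, p = 0.3, seed = 1) {
  set.seed(seed)
  array(runif(prod(dims)) < p, dims)
}

random_case <- function(dims = c(20, 20, 20), seed = 1) {
  lesion <- simulate_lesion(grid_shape = dims, seed = seed)
  lesion
}
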