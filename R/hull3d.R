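# Incremental 3D convex hull over voxel-center points, plus half-space
# rasterization back onto the voxel grid. Points are integer voxel indices,
# so geometric predicates are well conditioned; tolerances are absolute.

# Affine rank of a point set (0 = single point, 1 = collinear, 2 = coplanar,
# 3 = full-dimensional).
affine_rank <- function(pts, tol = 1e-7) {
  if (nrow(pts) < 2L) return(0L)
  centred <- sweep(pts, 2, pts[1L, ])
  qr(centred, tol = tol)$rank
}

# Incremental convex hull of full-dimensional points.
# Returns list(normals, offsets, vertices): outward unit normals n and offsets
# b such that every hull point satisfies n . x <= b.
convhull3d <- function(pts, tol = 1e-9) {
  pts <- unique(pts)
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 4L || affine_rank(pts) < 3L) return(NULL)

  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])

  # --- initial tetrahedron -------------------------------------------------
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  d12 <- pts[i2, ] - pts[i1, ]
  # farthest point from the line i1-i2
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * d12[3] - rel[, 3] * d12[2],
              rel[, 3] * d12[1] - rel[, 1] * d12[3],
              rel[, 1] * d12[2] - rel[, 2] * d12[1])
  dline <- rowSums(cr^2)
  i3 <- which.max(dline)
  nrm <- cross3(d12, pts[i3, ] - pts[i1, ])
  dplane <- abs(rel %*% nrm)
  i4 <- which.max(dplane)
  verts <- c(i1, i2, i3, i4)
  interior <- colMeans(pts[verts, ])

  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  orient <- function(f) {
    a <- pts[f[1], ]; nn <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
    if (sum(nn * (interior - a)) > 0) f[c(1, 3, 2)] else f
  }
  faces <- lapply(faces, orient)
  face_normal <- function(f) {
    a <- pts[f[1], ]; nn <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
    nn / sqrt(sum(nn^2))
  }
  normals <- t(vapply(faces, face_normal, numeric(3)))
  offsets <- vapply(seq_along(faces), function(i) sum(normals[i, ] * pts[faces[[i]][1], ]),
                    numeric(1))

  # --- incremental insertion ----------------------------------------------
  remaining <- setdiff(seq_len(n), verts)
  for (ip in remaining) {
    p <- pts[ip, ]
    dist <- drop(normals %*% p) - offsets
    visible <- which(dist > tol)
    if (length(visible) == 0L) next
    # horizon: directed edges of visible faces whose reverse is not visible
    edges <- do.call(rbind, lapply(faces[visible], function(f)
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])))
    keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[keys %in% names(which(table(keys) == 1L)), , drop = FALSE]
    faces <- faces[-visible]
    normals <- normals[-visible, , drop = FALSE]
    offsets <- offsets[-visible]
    for (e in seq_len(nrow(horizon))) {
      f <- c(horizon[e, 1], horizon[e, 2], ip)
      a <- pts[f[1], ]
      nn <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
      nl <- sqrt(sum(nn^2))
      if (nl < tol) next  # degenerate sliver, skip
      nn <- nn / nl
      if (sum(nn * (interior - a)) > 0) { f <- f[c(1, 3, 2)]; nn <- -nn }
      faces <- c(faces, list(f))
      normals <- rbind(normals, nn)
      offsets <- c(offsets, sum(nn * a))
    }
  }

  list(normals = normals, offsets = offsets,
       vertices = sort(unique(unlist(faces))))
}

# Rasterize a hull onto a voxel grid: a voxel belongs to the hull mask iff its
# center (integer index) lies inside or on every supporting half-space.
rasterize_hull <- function(hull, dims, tol = 1e-9) {
  out <- array(FALSE, dims)
  bb <- attr(hull, "bbox")  # vertex bounding box, supplied by the caller
  xs <- seq.int(bb[1, 1], bb[2, 1]); ys <- seq.int(bb[1, 2], bb[2, 2])
  zs <- seq.int(bb[1, 3], bb[2, 3])
  centers <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  inside <- rowSums(centers %*% t(hull$normals) >
                      rep(hull$offsets + tol, each = nrow(centers))) == 0
  out[centers[inside, , drop = FALSE]] <- TRUE
  out
}

# Column-extreme candidate reduction: every hull vertex is the min or max of
# its axis-aligned column along at least one axis, so hulling this subset is
# exact while being much smaller than the full voxel set.
column_extremes <- function(idx) {
  keep <- logical(nrow(idx))
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    key <- paste(idx[, others[1]], idx[, others[2]])
    ord <- order(key, idx[, ax])
    first <- !duplicated(key[ord])
    last <- !duplicated(key[ord], fromLast = TRUE)
    keep[ord[first | last]] <- TRUE
  }
  idx[keep, , drop = FALSE]
}

# Hull mask of a set of voxel indices (n x 3 matrix, 1-based), on a grid of
# shape `dims`. Returns NULL when the points are not full-dimensional.
hull_mask_of_points <- function(idx, dims, tol = 1e-9) {
  if (affine_rank(idx) < 3L) return(NULL)
  cand <- column_extremes(idx)
  hull <- convhull3d(cand, tol = tol)
  if (is.null(hull)) return(NULL)
  bb <- rbind(apply(idx, 2, min), apply(idx, 2, max))
  attr(hull, "bbox") <- bb
  rasterize_hull(hull, dims, tol = tol)
}
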