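# Independent oracles used across the suite. These deliberately use
# different algorithms from the package internals.

# Connected-component labeling by iterative minimum-label propagation:
# every true voxel starts with its own label (its linear index) and
# repeatedly takes the minimum over its neighbourhood until a fixed point.
oracle_label <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  off <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  off <- off[rowSums(abs(off)) > 0, ]
  ord <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3), ]
  lab <- array(ifelse(mask, seq_along(mask), 0L), dm)
  repeat {
    new <- lab
    for (r in seq_len(nrow(off))) {
      sh <- array(0L, dm)
      si <- max(1, 1 + off[r, 1]):min(dm[1], dm[1] + off[r, 1])
      sj <- max(1, 1 + off[r, 2]):min(dm[2], dm[2] + off[r, 2])
      sk <- max(1, 1 + off[r, 3]):min(dm[3], dm[3] + off[r, 3])
      di <- si - off[r, 1]; dj <- sj - off[r, 2]; dk <- sk - off[r, 3]
      sh[si, sj, sk] <- lab[di, dj, dk]
      upd <- mask & sh > 0L & (sh < new | new == 0L)
      new[upd] <- sh[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # canonicalize to 1..K in order of first occurrence
  ids <- unique(lab[lab > 0L])
  out <- array(0L, dm)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

oracle_component_sizes <- function(mask, connectivity = 26) {
  lab <- oracle_label(mask, connectivity)
  if (max(lab) == 0L) integer(0) else tabulate(lab)
}

# Same partition of voxels into components?
same_partition <- function(lab_a, lab_b) {
  va <- as.vector(lab_a); vb <- as.vector(lab_b)
  if (!identical(va > 0L, vb > 0L)) return(FALSE)
  nz <- va > 0L
  length(unique(paste(va[nz], vb[nz]))) ==
    length(unique(va[nz])) &&
    length(unique(va[nz])) == length(unique(vb[nz]))
}

# Exhaustive nearest neighbour / radius search.
oracle_nn <- function(points, ids, centre) {
  d <- sqrt(rowSums(sweep(points, 2, centre, "-")^2))
  dmin <- min(d)
  list(point_id = min(ids[d == dmin]), distance = dmin)
}

oracle_radius <- function(points, ids, centre, radius) {
  d2 <- rowSums(sweep(points, 2, centre, "-")^2)
  sort(ids[d2 <= radius^2])
}

random_rigid_transform <- function() {
  rigid_transform(q = stats::rnorm(4), t = stats::runif(3, -20, 20))
}

# 4x4 homogeneous matrix form of a rigid transform (matrix oracle).
as_homogeneous <- function(tr) {
  m <- diag(4)
  q <- tr$q
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  m[1:3, 1:3] <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
  m[1:3, 4] <- tr$t
  m
}

random_blob_mask <- function(dims, p = 0.25) {
  array(stats::runif(prod(dims)) < p, dims)
}
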