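#' Signed Euclidean distance fields
#'
#' Each fragment carries a signed Euclidean distance field sampled on its own
#' voxel grid: negative at voxel centres inside the fragment, positive
#' outside, in millimetres, computed with per-axis anisotropic spacing by the
#' separable lower-envelope (Felzenszwalb-Huttenlocher) squared distance
#' transform. Between voxel centres the field is interpolated trilinearly;
#' its zero level set sits midway between the last interior and first
#' exterior voxel centre, i.e. on the voxel interface, and its normalised
#' gradient approximates the outward surface normal.
#'
#' Fields are stored in the fragment's local frame so that moving a fragment
#' never triggers recomputation; contact queries transform world points into
#' the local frame instead.
#'
#' @name distance-fields
NULL

# 1-D squared distance transform with sample spacing h (lower envelope of
# parabolas). f holds squared distances (Inf where no source yet).
.dt1d_sq <- function(f, h) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  v <- integer(n)
  z <- numeric(n + 1)
  k <- 1L
  v[1] <- fin[1]
  z[1] <- -Inf
  z[2] <- Inf
  h2 <- h * h
  if (length(fin) > 1L) {
    for (q in fin[-1]) {
      repeat {
        p <- v[k]
        s <- ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2 * h * (q - p))
        if (s <= z[k] && k > 1L) k <- k - 1L else break
      }
      k <- k + 1L
      v[k] <- q
      z[k] <- s
      z[k + 1] <- Inf
    }
  }
  d <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < h * q) k <- k + 1L
    p <- v[k]
    d[q] <- h2 * (q - p)^2 + f[p]
  }
  d
}

# Squared EDT of a 3-D seed array (0 at sources, Inf elsewhere), anisotropic.
.edt_sq <- function(seed, spacing) {
  dm <- dim(seed)
  a <- apply(seed, c(2, 3), .dt1d_sq, h = spacing[1])
  dim(a) <- dm
  a <- apply(a, c(1, 3), .dt1d_sq, h = spacing[2])
  a <- aperm(a, c(2, 1, 3))
  a <- apply(a, c(1, 2), .dt1d_sq, h = spacing[3])
  aperm(a, c(2, 3, 1))
}

#' Signed distance array of a binary mask
#'
#' Positive outside, negative inside, mm, measured between voxel centres.
#'
#' @param mask Logical 3-D array.
#' @param spacing Per-axis spacing, mm.
#' @return Numeric 3-D array.
#' @export
signed_distance <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  spacing <- .check_spacing(spacing)
  seed_in <- array(Inf, dim(mask)); seed_in[mask] <- 0
  seed_out <- array(Inf, dim(mask)); seed_out[!mask] <- 0
  d_to_mask <- sqrt(.edt_sq(seed_in, spacing))    # 0 inside
  d_to_bg <- sqrt(.edt_sq(seed_out, spacing))     # 0 outside
  d_to_mask - d_to_bg
}

#' Build a fragment's signed distance field
#'
#' The grid covers the fragment's bounding box plus `padding` voxels on every
#' side (clipped to the source volume extended by the padding), in the
#' fragment's local frame, which is the world frame of the source volume.
#'
#' @param lv A `labeled_volume`.
#' @param label Fragment label (>= 1) present in `lv`.
#' @param padding Voxels of margin around the fragment (default 3).
#' @return A `distance_field`: list of `values` (3-D array, mm), `spacing`,
#'   `origin` (local frame, mm).
#' @export
build_distance_field <- function(lv, label, padding = 3) {
  stopifnot(inherits(lv, "labeled_volume"))
  idx <- which(lv$labels == label)
  if (length(idx) == 0L) {
    stop(sprintf("label %d not present in the volume", label), call. = FALSE)
  }
  dm <- dim(lv$labels)
  ai <- arrayInd(idx, dm)
  lo <- pmax(1L, apply(ai, 2, min) - as.integer(padding))
  hi <- pmin(dm, apply(ai, 2, max) + as.integer(padding))
  sub <- lv$labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(sub) <- hi - lo + 1L
  mask <- sub == label
  # extra all-background shell so the zero level set never touches the grid edge
  dms <- dim(mask) + 2L
  padmask <- array(FALSE, dms)
  padmask[2:(dms[1] - 1), 2:(dms[2] - 1), 2:(dms[3] - 1)] <- mask
  vals <- signed_distance(padmask, lv$spacing)
  origin <- lv$origin + (lo - 2L) * lv$spacing  # local frame = volume world frame
  structure(list(values = vals, spacing = lv$spacing, origin = origin,
                 label = as.integer(label)),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("<distance_field> %s grid, spacing [%s] mm, range [%.3g, %.3g] mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(x$spacing, collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

# Continuous (1-based, voxel-centre) index coordinates of local-frame points.
.field_index_coords <- function(field, pts) {
  sweep(sweep(pts, 2, field$origin, "-"), 2, field$spacing, "/") + 0.5
}

#' Trilinear interpolation of a distance field at local-frame points
#'
#' Points outside the grid's interpolable domain return `Inf` (they are
#' certainly outside the fragment; padding guarantees the zero level set is
#' interior to the grid).
#'
#' @param field A `distance_field`.
#' @param pts `N x 3` local-frame points, mm.
#' @return Numeric vector of field values, mm.
#' @export
field_value <- function(field, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  u <- .field_index_coords(field, pts)
  dm <- dim(field$values)
  out <- rep(Inf, nrow(pts))
  ok <- u[, 1] >= 1 & u[, 1] <= dm[1] & u[, 2] >= 1 & u[, 2] <= dm[2] &
    u[, 3] >= 1 & u[, 3] <= dm[3]
  if (!any(ok)) return(out)
  out[ok] <- .trilinear(field$values, u[ok, , drop = FALSE])
  out
}

.trilinear <- function(arr, u) {
  dm <- dim(arr)
  i0 <- pmin(pmax(floor(u[, 1]), 1), dm[1] - 1)
  j0 <- pmin(pmax(floor(u[, 2]), 1), dm[2] - 1)
  k0 <- pmin(pmax(floor(u[, 3]), 1), dm[3] - 1)
  fx <- u[, 1] - i0; fy <- u[, 2] - j0; fz <- u[, 3] - k0
  at <- function(di, dj, dk) {
    arr[cbind(i0 + di, j0 + dj, k0 + dk)]
  }
  (1 - fx) * (1 - fy) * (1 - fz) * at(0L, 0L, 0L) +
    fx * (1 - fy) * (1 - fz) * at(1L, 0L, 0L) +
    (1 - fx) * fy * (1 - fz) * at(0L, 1L, 0L) +
    fx * fy * (1 - fz) * at(1L, 1L, 0L) +
    (1 - fx) * (1 - fy) * fz * at(0L, 0L, 1L) +
    fx * (1 - fy) * fz * at(1L, 0L, 1L) +
    (1 - fx) * fy * fz * at(0L, 1L, 1L) +
    fx * fy * fz * at(1L, 1L, 1L)
}

#' Central-difference gradient of a distance field at local-frame points
#'
#' Sampled with a half-voxel step per axis; sample points are clamped into
#' the interpolable domain, so near the grid edge the estimate degrades to a
#' one-sided difference.
#'
#' @inheritParams field_value
#' @return `N x 3` matrix of gradient components (dimensionless, ~unit norm
#'   away from the medial axis).
#' @export
field_gradient <- function(field, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, nrow = 1)
  dm <- dim(field$values)
  u <- .field_index_coords(field, pts)
  g <- matrix(0, nrow(pts), 3)
  for (ax in 1:3) {
    up <- u; dn <- u
    up[, ax] <- pmin(u[, ax] + 1.0, dm[ax])
    dn[, ax] <- pmax(u[, ax] - 1.0, 1)
    # clamp the remaining axes too, so edge queries stay interpolable
    for (bx in 1:3) {
      up[, bx] <- pmin(pmax(up[, bx], 1), dm[bx])
      dn[, bx] <- pmin(pmax(dn[, bx], 1), dm[bx])
    }
    dist_mm <- (up[, ax] - dn[, ax]) * field$spacing[ax]
    g[, ax] <- (.trilinear(field$values, up) - .trilinear(field$values, dn)) /
      pmax(dist_mm, 1e-12)
  }
  g
}

#' Axis-aligned bounding box of a field's grid, local frame
#' @noRd
field_bounds <- function(field) {
  list(lo = field$origin, hi = field$origin + dim(field$values) * field$spacing)
}
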