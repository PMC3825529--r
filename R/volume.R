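#' Volume containers and CT pre-processing
#'
#' The segmentation pipeline mirrors standard CT bone pre-processing:
#' threshold the intensity volume to a bone mask, drop small isolated
#' components (the classic `bwareaopen`-style filter), then label connected
#' components as candidate fragments. Voxel index `(i, j, k)` (1-based) maps
#' to the world position `origin + (index - 0.5) * spacing` — voxel-centre
#' convention with per-axis anisotropic spacing in millimetres.
#'
#' @name volume-segmentation
NULL

.check_spacing <- function(spacing) {
  .check_finite(spacing, "spacing")
  stopifnot(length(spacing) == 3)
  if (any(spacing <= 0)) stop("spacing must be strictly positive", call. = FALSE)
  as.numeric(spacing)
}

#' Construct an intensity volume
#'
#' @param voxels 3-D numeric array (Hounsfield-like units).
#' @param spacing Per-axis voxel size, mm (default the CT protocol this
#'   toolkit targets: 0.35 x 0.35 mm in-plane, 0.60 mm between slices).
#' @param origin World position of the volume corner, mm; voxel `(1,1,1)` is
#'   centred at `origin + spacing / 2`.
#' @export
intensity_volume <- function(voxels, spacing = c(0.35, 0.35, 0.60),
                             origin = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  structure(list(voxels = voxels, spacing = .check_spacing(spacing),
                 origin = as.numeric(origin)),
            class = "intensity_volume")
}

#' Construct a labeled fragment volume
#'
#' Label 0 is background; labels >= 1 are fragments. Construction checks
#' that the nonzero labels form a contiguous set `1..K`.
#'
#' @param labels 3-D non-negative integer array.
#' @inheritParams intensity_volume
#' @export
labeled_volume <- function(labels, spacing = c(0.35, 0.35, 0.60),
                           origin = c(0, 0, 0)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be non-negative", call. = FALSE)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(as.integer(ids), seq_len(max(ids)))) {
    stop("nonzero labels must form a contiguous set 1..K", call. = FALSE)
  }
  structure(list(labels = labels, spacing = .check_spacing(spacing),
                 origin = as.numeric(origin)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  k <- max(0L, x$labels)
  cat(sprintf("<labeled_volume> %s voxels, %d fragment(s), spacing [%s] mm\n",
              paste(dim(x$labels), collapse = "x"), k,
              paste(x$spacing, collapse = ", ")))
  invisible(x)
}

#' World coordinates of voxel centres
#'
#' @param vol An `intensity_volume` or `labeled_volume`.
#' @param index Integer matrix `N x 3` of 1-based voxel indices (or a
#'   length-3 vector).
#' @return `N x 3` matrix of world positions, mm.
#' @export
voxel_centers <- function(vol, index) {
  if (is.null(dim(index))) index <- matrix(index, nrow = 1)
  sweep(sweep(index - 0.5, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Threshold bone from an intensity volume
#'
#' A voxel is bone iff its intensity is greater than or equal to
#' `threshold`. A threshold outside the volume's intensity range still
#' returns the (empty or full) mask but emits a warning.
#'
#' @param v An `intensity_volume`.
#' @param threshold Scalar intensity.
#' @return Logical 3-D array, same dimensions.
#' @export
threshold_bone <- function(v, threshold) {
  stopifnot(inherits(v, "intensity_volume"))
  .check_finite(threshold, "threshold")
  rng <- range(v$voxels)
  if (threshold <= rng[1] || threshold > rng[2]) {
    warning(sprintf(
      "threshold %g outside the volume intensity range [%g, %g]; mask is %s",
      threshold, rng[1], rng[2],
      if (threshold <= rng[1]) "full" else "empty"), call. = FALSE)
  }
  v$voxels >= threshold
}

#' 6/18/26 neighbourhood offsets
#' @noRd
connectivity_offsets <- function(connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3)
  unname(g[keep, , drop = FALSE])
}

#' Label connected components of a binary volume
#'
#' Components are labeled `1..K` in a deterministic order: descending voxel
#' count, ties broken by the smallest linear (column-major) voxel index.
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param spacing,origin Geometry carried onto the result.
#' @return A `labeled_volume`.
#' @export
label_components <- function(mask, connectivity = 26,
                             spacing = c(0.35, 0.35, 0.60),
                             origin = c(0, 0, 0)) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  dm <- dim(mask)
  lab <- .label_components_raw(mask, dm, connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab)
    first <- integer(length(sizes))
    nz <- which(lab > 0L)
    # first (smallest) linear index per provisional label; nz is ascending
    firsts <- nz[!duplicated(lab[nz])]
    first[lab[firsts]] <- firsts
    ord <- order(-sizes, first)
    relab <- integer(length(sizes))
    relab[ord] <- seq_along(ord)
    lab[nz] <- relab[lab[nz]]
  }
  dim(lab) <- dm
  labeled_volume(lab, spacing = spacing, origin = origin)
}

# Vectorised frontier (BFS) labeling on the linearised array.
.label_components_raw <- function(mask, dm, connectivity) {
  off <- connectivity_offsets(connectivity)
  n <- prod(dm)
  mask <- as.logical(mask)
  lab <- integer(n)
  todo <- which(mask)
  k <- 0L
  # precompute per-offset linear shifts; boundary handled via i/j/k coords
  while (length(todo)) {
    seed <- todo[1]
    k <- k + 1L
    lab[seed] <- k
    frontier <- seed
    while (length(frontier)) {
      i0 <- (frontier - 1L) %% dm[1] + 1L
      j0 <- ((frontier - 1L) %/% dm[1]) %% dm[2] + 1L
      k0 <- (frontier - 1L) %/% (dm[1] * dm[2]) + 1L
      nxt <- integer(0)
      for (r in seq_len(nrow(off))) {
        ii <- i0 + off[r, 1]; jj <- j0 + off[r, 2]; kk <- k0 + off[r, 3]
        ok <- ii >= 1L & ii <= dm[1] & jj >= 1L & jj <= dm[2] &
          kk >= 1L & kk <= dm[3]
        if (!any(ok)) next
        lin <- ii[ok] + (jj[ok] - 1L) * dm[1] + (kk[ok] - 1L) * dm[1] * dm[2]
        lin <- lin[mask[lin] & lab[lin] == 0L]
        if (length(lin)) {
          lab[lin] <- k
          nxt <- c(nxt, lin)
        }
      }
      frontier <- unique(nxt)
    }
    todo <- todo[lab[todo] == 0L]
  }
  lab
}

#' Remove small connected components from a binary mask
#'
#' Components with strictly fewer than `min_size` voxels are removed;
#' a component of exactly `min_size` voxels survives. This is the
#' "fewer than 100 connected voxels" clean-up applied to thresholded CT
#' bone masks before fragment labeling.
#'
#' @param mask Logical 3-D array.
#' @param min_size Minimum surviving component size in voxels (default 100).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Logical 3-D array.
#' @export
remove_small_components <- function(mask, min_size = 100, connectivity = 26) {
  dm <- dim(mask)
  lab <- .label_components_raw(mask, dm, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dm))
  sizes <- tabulate(lab)
  keep <- sizes >= min_size
  out <- lab > 0L & keep[pmax(lab, 1L)]
  dim(out) <- dm
  out
}

#' Per-component voxel counts of a labeled volume
#'
#' @param lv A `labeled_volume`.
#' @return A tibble with columns `label` and `voxels`, descending size.
#' @export
component_sizes <- function(lv) {
  stopifnot(inherits(lv, "labeled_volume"))
  k <- max(0L, lv$labels)
  if (k == 0L) return(tibble::tibble(label = integer(), voxels = integer()))
  tibble::tibble(label = seq_len(k), voxels = tabulate(lv$labels, k))
}

#' Match labels between two labelings of the same grid
#'
#' For every label of `lv_a`, the label of `lv_b` with the largest voxel
#' overlap. Used to reconcile a re-labeled segmentation with a phantom's
#' ground-truth labels.
#'
#' @param lv_a,lv_b `labeled_volume`s on identical grids.
#' @return A tibble with `label_a`, `label_b`, `overlap` (voxels) and
#'   `jaccard`.
#' @export
match_labels <- function(lv_a, lv_b) {
  stopifnot(inherits(lv_a, "labeled_volume"), inherits(lv_b, "labeled_volume"),
            identical(dim(lv_a$labels), dim(lv_b$labels)))
  ka <- max(0L, lv_a$labels)
  rows <- purrr::map(seq_len(ka), function(a) {
    sel <- lv_a$labels == a
    hits <- lv_b$labels[sel]
    hits <- hits[hits > 0L]
    if (length(hits) == 0L) {
      return(tibble::tibble(label_a = a, label_b = NA_integer_,
                            overlap = 0L, jaccard = 0))
    }
    tab <- tabulate(hits)
    b <- which.max(tab)
    ov <- tab[b]
    un <- sum(sel) + sum(lv_b$labels == b) - ov
    tibble::tibble(label_a = a, label_b = b, overlap = as.integer(ov),
                   jaccard = ov / un)
  })
  dplyr::bind_rows(rows)
}
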