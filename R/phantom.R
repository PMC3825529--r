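#' Synthetic fractured-bone phantoms with ground truth
#'
#' The phantom generator is the test bed standing in for patient CT data: a
#' simple bone-like intact shape (cube, ellipsoid shell, or mandible-like
#' bent tube) is cut by randomized rough surfaces into fragments, each
#' fragment is displaced by a known rigid transform, and the inverse
#' transforms are stored as ground truth. Cut surfaces are planes perturbed
#' by smooth low-frequency noise so the mating faces interdigitate: a
#' perfectly flat cut would leave in-plane translation unobservable for any
#' surface-matching method, whereas rough faces give the snap a unique
#' local minimum, as real fracture interlock does. Options add
#' compression-fracture-style face erosion and sub-100-voxel junk specks
#' (so the segmentation filter has real work), and the default spacing is
#' the anisotropic CT protocol (0.35 x 0.35 x 0.60 mm) so voxel-to-mm
#' conventions stay honest.
#'
#' All randomness derives from the single spec seed through a documented
#' splitting scheme, so a fixed spec is bit-reproducible.
#'
#' @name phantom-generator
NULL

.sub_seed <- function(seed, k) as.integer((seed * 1009 + k * 9973) %% 2147483629)

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

#' Phantom specification
#'
#' @param base_shape `"cube"`, `"ellipsoid_shell"` or `"bent_tube"`.
#' @param dims Voxel grid of the intact volume (default `c(56, 56, 40)`,
#'   a roughly 20 mm bone piece at the default spacing).
#' @param spacing Per-axis spacing, mm (default `c(0.35, 0.35, 0.60)`).
#' @param n_cuts Number of rough cut surfaces (default 1).
#' @param cut_roughness RMS amplitude of the cut-surface perturbation, mm
#'   (default 2.0 mm: fracture braiding must span several voxels to be
#'   resolvable at CT resolution, and real fracture interlock in cortical
#'   bone is of millimetre scale).
#' @param displacement_mm,displacement_deg Maximum fragment displacement;
#'   each displaced fragment draws uniformly from 60-100% of these.
#' @param erosion_voxels Depth, in voxels, of the compression-fracture
#'   damage craters carved into the fracture faces of the displaced
#'   fragments (portions of the surface go missing; 0 = intact faces).
#' @param noise_components Number of junk specks added to the rendered
#'   intensity volume; each is strictly below 100 voxels.
#' @param noise_size Two-element range of speck sizes in voxels.
#' @param seed Integer seed; fixes every random choice.
#' @export
phantom_spec <- function(base_shape = c("cube", "ellipsoid_shell", "bent_tube"),
                         dims = c(56, 56, 40),
                         spacing = c(0.35, 0.35, 0.60),
                         n_cuts = 1, cut_roughness = 2.0,
                         displacement_mm = 4, displacement_deg = 10,
                         erosion_voxels = 0,
                         noise_components = 4, noise_size = c(5, 60),
                         seed = 1) {
  base_shape <- match.arg(base_shape)
  stopifnot(length(dims) == 3, all(dims >= 8), n_cuts >= 0,
            cut_roughness >= 0, displacement_mm >= 0, displacement_deg >= 0,
            erosion_voxels >= 0, noise_components >= 0,
            length(noise_size) == 2, noise_size[2] < 100)
  structure(list(base_shape = base_shape, dims = as.integer(dims),
                 spacing = .check_spacing(spacing),
                 n_cuts = as.integer(n_cuts), cut_roughness = cut_roughness,
                 displacement_mm = displacement_mm,
                 displacement_deg = displacement_deg,
                 erosion_voxels = erosion_voxels,
                 noise_components = as.integer(noise_components),
                 noise_size = as.numeric(noise_size),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# World coordinates (N x 3) of every voxel centre of a dims/spacing grid.
.grid_coords <- function(dims, spacing, origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  cbind(rep(xs, times = dims[2] * dims[3]),
        rep(rep(ys, each = dims[1]), times = dims[3]),
        rep(zs, each = dims[1] * dims[2]))
}

# Analytic membership predicate of the intact base shape at points P (mm).
.base_shape_pred <- function(spec, P) {
  ext <- spec$dims * spec$spacing
  ctr <- ext / 2
  switch(spec$base_shape,
    cube = {
      lo <- 0.18 * ext; hi <- 0.82 * ext
      P[, 1] > lo[1] & P[, 1] < hi[1] & P[, 2] > lo[2] & P[, 2] < hi[2] &
        P[, 3] > lo[3] & P[, 3] < hi[3]
    },
    ellipsoid_shell = {
      ax <- 0.40 * ext
      r2 <- ((P[, 1] - ctr[1]) / ax[1])^2 + ((P[, 2] - ctr[2]) / ax[2])^2 +
        ((P[, 3] - ctr[3]) / ax[3])^2
      r2 <= 1 & r2 >= 0.55^2
    },
    bent_tube = {
      # mandible-like arch: half-circle centreline in the xy-plane
      R <- 0.32 * min(ext[1], ext[2])
      r <- 0.16 * min(ext)
      cc <- c(ctr[1], ctr[2] - 0.3 * R, ctr[3])
      dx <- P[, 1] - cc[1]; dy <- P[, 2] - cc[2]
      ang <- atan2(dy, dx)
      rad <- sqrt(dx^2 + dy^2)
      d_arc <- sqrt((rad - R)^2 + (P[, 3] - cc[3])^2)
      d_arc <= r & ang >= 0 & ang <= pi
    })
}

.base_shape_mask <- function(spec) {
  P <- .grid_coords(spec$dims, spec$spacing)
  array(.base_shape_pred(spec, P), spec$dims)
}

# Cut-side sign pattern of points P as an integer code.
.cut_code <- function(cuts, P) {
  code <- rep(0L, nrow(P))
  for (j in seq_along(cuts)) {
    code <- code + as.integer(.cut_side(cuts[[j]], P) > 0) * 2L^(j - 1L)
  }
  code
}

# One rough cut surface: a plane through `point` with normal `normal`,
# offset by a sum of low-frequency in-plane sinusoids with RMS amplitude
# `roughness` mm. Returns the cut definition; evaluate with .cut_side().
.make_cut <- function(centre_pts, roughness, extent) {
  normal <- .random_unit_vector()
  point <- centre_pts + stats::runif(3, -0.08, 0.08) * extent
  a <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(normal, a); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(normal, e1)
  # mixed interlock spectrum: one dominant long-wavelength undulation keeps
  # neighbouring basins far from a coarse-alignment start, three shorter
  # components sharpen the in-plane rotational minimum
  wavelength <- c(stats::runif(1, 9, 13), stats::runif(3, 3.5, 6))   # mm
  theta <- stats::runif(4, 0, 2 * pi)
  phase <- stats::runif(4, 0, 2 * pi)
  amps <- c(stats::runif(1, 1.3, 1.6), stats::runif(3, 0.7, 1.0))
  # analytic RMS of a sum of independent sinusoids: sqrt(sum(a^2)/2);
  # rescale so the perturbation has RMS `roughness` mm, independent of
  # where the cut is later evaluated
  amps <- amps * roughness / sqrt(sum(amps^2) / 2)
  list(normal = normal, point = point, e1 = e1, e2 = e2,
       k = 2 * pi / wavelength, theta = theta, phase = phase, amps = amps,
       scale = roughness)
}

# Signed side value of points P (N x 3, mm) for a cut: plane offset + noise.
.cut_side <- function(cut, P) {
  d <- sweep(P, 2, cut$point, "-")
  u <- d %*% cut$e1
  v <- d %*% cut$e2
  g <- 0
  for (m in seq_along(cut$k)) {
    g <- g + cut$amps[m] *
      sin(cut$k[m] * (cos(cut$theta[m]) * u + sin(cut$theta[m]) * v) +
            cut$phase[m])
  }
  as.numeric(d %*% cut$normal) + as.numeric(g)
}

# Fragment labels of the intact mask given the cuts: connected components
# within each region of constant cut-side sign pattern.
.fragment_labels <- function(mask, cuts, dims, spacing) {
  P <- .grid_coords(dims, spacing)
  code <- .cut_code(cuts, P)
  lab <- integer(prod(dims))
  k <- 0L
  for (cd in sort(unique(code[as.vector(mask)]))) {
    sub <- mask & array(code == cd, dims)
    sl <- .label_components_raw(sub, dims, 26)
    nz <- sl > 0L
    lab[nz] <- sl[nz] + k
    k <- k + max(sl)
  }
  dim(lab) <- dims
  lab
}

.relabel_by_size <- function(lab) {
  k <- max(lab)
  if (k == 0L) return(lab)
  sizes <- tabulate(lab, k)
  nz <- which(lab > 0L)
  firsts <- nz[!duplicated(lab[nz])]
  first <- integer(k); first[lab[firsts]] <- firsts
  ord <- order(-sizes, first)
  relab <- integer(k); relab[ord] <- seq_len(k)
  lab[nz] <- relab[lab[nz]]
  lab
}

#' Generate a fractured phantom with ground truth
#'
#' @param spec A `phantom_spec`.
#' @return A `phantom_truth`: `labeled` (displaced `labeled_volume`),
#'   `intact` (`labeled_volume` before displacement), `truth_poses` (named
#'   list, label -> `rigid_transform` restoring the displaced fragment to
#'   the intact configuration), `displacements` (the applied transforms),
#'   `cuts` (cut-surface definitions), `intensity` (rendered
#'   `intensity_volume` of the displaced state with junk specks),
#'   `speck_voxels` (voxel count per speck), and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  for (attempt in 0:19) {
    pt <- .with_seed(.sub_seed(spec$seed, attempt * 101),
                     .generate_phantom_once(spec))
    if (!is.null(pt)) {
      pt$attempt <- attempt
      return(pt)
    }
  }
  stop("phantom generation kept producing degenerate fragments; relax the spec",
       call. = FALSE)
}

.generate_phantom_once <- function(spec) {
  dims <- spec$dims
  spacing <- spec$spacing
  mask <- .base_shape_mask(spec)
  if (sum(mask) < 50) stop("base shape is degenerate", call. = FALSE)
  P <- .grid_coords(dims, spacing)
  ctr_pts <- colMeans(P[as.vector(mask), , drop = FALSE])
  ext <- dims * spacing
  cuts <- lapply(seq_len(spec$n_cuts), function(j) {
    .make_cut(ctr_pts, spec$cut_roughness, ext)
  })
  lab <- if (spec$n_cuts > 0) {
    .fragment_labels(mask, cuts, dims, spacing)
  } else {
    l <- array(0L, dims); l[mask] <- 1L; l
  }
  lab <- .relabel_by_size(lab)
  k <- max(lab)
  # rough cuts grazing corners shed sub-resolution slivers; anything below
  # the 100-voxel debris threshold (which the segmentation filter would
  # delete anyway) is dropped from the phantom rather than kept as a
  # "fragment"
  sizes <- tabulate(lab, k)
  dropped <- array(FALSE, dims)
  if (any(sizes < 100)) {
    dropped <- array(lab %in% which(sizes < 100), dims)
    lab[dropped] <- 0L
    lab <- .relabel_by_size(.relabel_contiguous(lab))
    k <- max(lab)
  }
  if (k < max(1L, spec$n_cuts)) return(NULL)

  # per-fragment cut-side code and the cuts each fragment borders
  code_all <- .cut_code(cuts, P)
  code_of <- integer(k)
  border_cuts <- vector("list", k)
  voxdiag <- sqrt(sum(spacing^2))
  for (kk in seq_len(k)) {
    vox <- which(lab == kk)
    code_of[kk] <- code_all[vox[1]]
    border_cuts[[kk]] <- which(vapply(seq_along(cuts), function(j) {
      min(abs(.cut_side(cuts[[j]], P[vox, , drop = FALSE]))) < voxdiag
    }, logical(1)))
  }

  # compression-fracture damage: patches of the fracture face go missing.
  # Spherical craters of depth `erosion_voxels` are carved analytically
  # where they intersect the near-cut band of a non-anchor fragment, so the
  # intact and displaced voxelizations agree exactly.
  erosion_depth <- spec$erosion_voxels * mean(spacing)
  damage <- list()
  if (erosion_depth > 0 && k > 1) {
    for (kk in 2:k) {
      vox <- which(lab == kk)
      for (j in border_cuts[[kk]]) {
        face <- vox[abs(.cut_side(cuts[[j]], P[vox, , drop = FALSE])) <
                      2 * voxdiag]
        if (length(face) < 10) next
        centres <- P[sample(face, min(5, length(face))), , drop = FALSE]
        radii <- stats::runif(nrow(centres), 2, 3.5)
        damage[[length(damage) + 1]] <-
          list(label = kk, cut = j, centres = centres, radii = radii)
      }
    }
  }
  .eroded <- function(kk, pts) {
    out <- rep(FALSE, nrow(pts))
    if (erosion_depth <= 0 || kk == 1L) return(out)
    for (dm_ in damage) {
      if (dm_$label != kk) next
      band <- abs(.cut_side(cuts[[dm_$cut]], pts)) < erosion_depth
      if (!any(band)) next
      hit <- rep(FALSE, nrow(pts))
      for (q in seq_len(nrow(dm_$centres))) {
        hit <- hit | sqrt(rowSums(sweep(pts, 2, dm_$centres[q, ], "-")^2)) <
          dm_$radii[q]
      }
      out <- out | (band & hit)
    }
    out
  }
  lab0 <- lab   # pre-erosion labels, used for component disambiguation
  lab0[dropped] <- -1L   # dropped slivers must not be claimed by any fragment
  if (erosion_depth > 0 && k > 1) {
    for (kk in 2:k) {
      vox <- which(lab == kk)
      ero <- .eroded(kk, P[vox, , drop = FALSE])
      if (any(ero) && !all(ero)) lab[vox[ero]] <- 0L
    }
    if (any(tabulate(lab, k) < 8)) return(NULL)
  }

  intact <- labeled_volume(lab, spacing = spacing, origin = c(0, 0, 0))

  # random rigid displacement per fragment; the largest fragment anchors
  displacements <- vector("list", k)
  names(displacements) <- as.character(seq_len(k))
  displacements[["1"]] <- transform_identity()
  if (k > 1) {
    for (kk in 2:k) {
      vox <- which(lab == kk)
      c_k <- colMeans(P[vox, , drop = FALSE])
      ang <- spec$displacement_deg * stats::runif(1, 0.6, 1) * pi / 180
      axis <- .random_unit_vector()
      dir <- c_k - ctr_pts + 0.4 * sqrt(sum((c_k - ctr_pts)^2)) * .random_unit_vector()
      nd <- sqrt(sum(dir^2))
      dir <- if (nd > 1e-9) dir / nd else .random_unit_vector()
      shift <- spec$displacement_mm * stats::runif(1, 0.6, 1) * dir
      q <- quat_from_axis_angle(axis, ang)
      Rm <- quat_to_matrix(q)
      displacements[[as.character(kk)]] <-
        rigid_transform(q, c_k - as.numeric(Rm %*% c_k) + shift)
    }
  }

  # displaced volume on an enlarged grid, same world frame; each fragment is
  # re-voxelized analytically (base-shape predicate + exact cut sides at the
  # inverse-displaced position) so both sides of a cut carry independent,
  # moire-free voxelization error; the intact label grid only disambiguates
  # disconnected components that share a cut-side code.
  # Displaced fragments must end up pairwise separated (no 26-adjacency) or
  # segmentation could never recover them as distinct components: when two
  # fragments touch, the smaller one's translation is escalated outward and
  # the volume re-voxelized.
  pad <- as.integer(ceiling((2 * spec$displacement_mm + 4) / spacing)) + 2L
  dims_d <- dims + 2L * pad
  origin_d <- -pad * spacing
  Pd <- .grid_coords(dims_d, spacing, origin = origin_d)
  for (escalation in 1:12) {
  lab_d <- integer(prod(dims_d))
  for (kk in seq_len(k)) {
    inv <- transform_inverse(displacements[[as.character(kk)]])
    P0 <- apply_transform(inv, Pd)
    member <- .base_shape_pred(spec, P0)
    if (spec$n_cuts > 0) {
      member[member] <- .cut_code(cuts, P0[member, , drop = FALSE]) == code_of[kk]
    }
    if (any(member)) {
      # reject points whose nearest intact voxel is a different component
      # with the same code
      idx <- round(sweep(P0[member, , drop = FALSE], 2, spacing, "/") + 0.5)
      idx[, 1] <- pmin(pmax(idx[, 1], 1), dims[1])
      idx[, 2] <- pmin(pmax(idx[, 2], 1), dims[2])
      idx[, 3] <- pmin(pmax(idx[, 3], 1), dims[3])
      lin <- idx[, 1] + (idx[, 2] - 1) * dims[1] + (idx[, 3] - 1) * dims[1] * dims[2]
      nnlab <- lab0[lin]
      keep <- nnlab == kk | nnlab == 0L |
        (nnlab > 0L & code_of[pmax(nnlab, 1L)] != code_of[kk])
      member[member] <- keep
    }
    if (any(member)) {
      member[member] <- !.eroded(kk, P0[member, , drop = FALSE])
    }
    hit <- which(member)
    hit <- hit[lab_d[hit] == 0L]
    lab_d[hit] <- kk
  }
  if (any(tabulate(lab_d, k) < 8)) return(NULL)
  dim(lab_d) <- dims_d
  touching <- if (k > 1) .labels_adjacent(lab_d) else integer(0)
  if (length(touching) == 0L) break
  if (escalation == 12) return(NULL)
  for (kk in setdiff(touching, 1L)) {
    D <- displacements[[as.character(kk)]]
    vox <- which(lab == kk)
    c_k <- colMeans(P[vox, , drop = FALSE])
    dir <- c_k - ctr_pts
    nd <- sqrt(sum(dir^2))
    dir <- if (nd > 1e-9) dir / nd else c(1, 0, 0)
    displacements[[as.character(kk)]] <-
      rigid_transform(D$q, D$t + 0.75 * dir)
  }
  }
  labeled <- labeled_volume(lab_d, spacing = spacing, origin = origin_d)

  truth <- lapply(displacements, transform_inverse)

  render <- .render_intensity(labeled, spec)

  structure(list(labeled = labeled, intact = intact,
                 truth_poses = truth, displacements = displacements,
                 cuts = cuts, damage = damage, intensity = render$volume,
                 speck_voxels = render$speck_voxels, spec = spec),
            class = "phantom_truth")
}

# Bone-intensity rendering of the displaced label volume plus junk specks,
# each strictly below 100 voxels and kept clear of the fragments.
.render_intensity <- function(labeled, spec, bone = 700, tissue = 40) {
  dims <- dim(labeled$labels)
  vox <- array(tissue, dims)
  vox[labeled$labels > 0L] <- bone
  speck_sizes <- integer(0)
  if (spec$noise_components > 0) {
    seed_in <- array(Inf, dims); seed_in[labeled$labels > 0L] <- 0
    dist_frag <- sqrt(.edt_sq(seed_in, labeled$spacing))
    allowed <- dist_frag > 2 * max(labeled$spacing)
    off <- connectivity_offsets(6)
    for (s in seq_len(spec$noise_components)) {
      target <- round(stats::runif(1, spec$noise_size[1],
                                   min(spec$noise_size[2], 99)))
      cand <- which(allowed & vox < bone)
      if (length(cand) == 0L) break
      cur <- sample(cand, 1)
      speck <- cur
      tries <- 0L
      while (length(speck) < target && tries < 200 * target) {
        tries <- tries + 1L
        src <- speck[sample.int(length(speck), 1)]
        i <- (src - 1L) %% dims[1] + 1L
        j <- ((src - 1L) %/% dims[1]) %% dims[2] + 1L
        kk <- (src - 1L) %/% (dims[1] * dims[2]) + 1L
        o <- off[sample.int(nrow(off), 1), ]
        ii <- i + o[1]; jj <- j + o[2]; kz <- kk + o[3]
        if (ii < 1 || ii > dims[1] || jj < 1 || jj > dims[2] ||
            kz < 1 || kz > dims[3]) next
        lin <- ii + (jj - 1L) * dims[1] + (kz - 1L) * dims[1] * dims[2]
        if (!allowed[lin]) next
        if (!lin %in% speck) speck <- c(speck, lin)
      }
      vox[speck] <- bone
      speck_sizes <- c(speck_sizes, length(speck))
    }
  }
  list(volume = intensity_volume(vox, spacing = labeled$spacing,
                                 origin = labeled$origin),
       speck_voxels = speck_sizes)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> %s, %d fragment(s), %d cut(s), grid %s, %d speck(s)\n",
    x$spec$base_shape, max(x$labeled$labels), length(x$cuts),
    paste(dim(x$labeled$labels), collapse = "x"), length(x$speck_voxels)))
  invisible(x)
}

#' Ground-truth fracture-face markings
#'
#' For every pair of fragments that mate across a cut surface, marks the
#' shell points of each side that lie within one voxel diagonal of the
#' generating cut (evaluated in the intact configuration via the stored
#' truth poses) and adjacent to the partner fragment, so each marking
#' covers exactly one mating interface.
#'
#' @param pt A `phantom_truth`.
#' @param fragments Named list of `fragment`s built from `pt$labeled`
#'   (e.g. via [fragment_from_labels()]); names are labels.
#' @return A tibble with one row per mating pair: `cut`, `label_a`,
#'   `label_b`, `n_a`, `n_b` (marked counts) and list columns `marking_a`,
#'   `marking_b` of `marked_surface` objects.
#' @export
fracture_face_markings <- function(pt, fragments) {
  stopifnot(inherits(pt, "phantom_truth"))
  voxdiag <- sqrt(sum(pt$labeled$spacing^2))
  labs <- as.integer(names(fragments))
  # intact-frame shell points and near-cut masks per fragment and cut
  intact_pts <- lapply(names(fragments), function(lb) {
    apply_transform(pt$truth_poses[[lb]],
                    shell_points(fragments[[lb]]$shell))
  })
  names(intact_pts) <- names(fragments)
  rows <- list()
  for (j in seq_along(pt$cuts)) {
    near <- lapply(names(fragments), function(lb) {
      s <- .cut_side(pt$cuts[[j]], intact_pts[[lb]])
      which(abs(s) <= voxdiag)
    })
    names(near) <- names(fragments)
    active <- names(fragments)[vapply(near, length, integer(1)) >= 3]
    if (length(active) < 2) next
    for (ia in seq_along(active)) {
      for (ib in seq_along(active)) {
        if (ib <= ia) next
        a <- active[ia]; b <- active[ib]
        pa <- intact_pts[[a]][near[[a]], , drop = FALSE]
        pb <- intact_pts[[b]][near[[b]], , drop = FALSE]
        # restrict each side to points adjacent to the partner band
        nw_a <- nearest_within(pa, pb, 2 * voxdiag)
        nw_b <- nearest_within(pb, pa, 2 * voxdiag)
        sel_a <- near[[a]][!is.na(nw_a$index)]
        sel_b <- near[[b]][!is.na(nw_b$index)]
        if (length(sel_a) < 3 || length(sel_b) < 3) next
        fa <- fragments[[a]]; fb <- fragments[[b]]
        rows[[length(rows) + 1]] <- tibble::tibble(
          cut = j, label_a = as.integer(a), label_b = as.integer(b),
          n_a = length(sel_a), n_b = length(sel_b),
          marking_a = list(marked_surface(fa$label, fa$shell$point_id[sel_a])),
          marking_b = list(marked_surface(fb$label, fb$shell$point_id[sel_b])))
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(cut = integer(), label_a = integer(),
                          label_b = integer(), n_a = integer(),
                          n_b = integer(), marking_a = list(),
                          marking_b = list()))
  }
  dplyr::bind_rows(rows)
}

#' Markings of the mating faces between two fragments
#'
#' Picks the cut along which both fragments carry fracture-face markings
#' (the one with the largest combined marked count when several qualify).
#'
#' @param pt A `phantom_truth`.
#' @param fragments Named list of `fragment`s (see
#'   [fracture_face_markings()]).
#' @param label_a,label_b The two fragment labels.
#' @return List with `marking_a`, `marking_b` and `cut`.
#' @export
mating_markings <- function(pt, fragments, label_a, label_b) {
  mk <- fracture_face_markings(pt, fragments)
  sel <- (mk$label_a == label_a & mk$label_b == label_b) |
    (mk$label_a == label_b & mk$label_b == label_a)
  mk <- mk[sel, ]
  if (nrow(mk) == 0L) {
    stop(sprintf("fragments %d and %d share no marked cut surface",
                 label_a, label_b), call. = FALSE)
  }
  best <- which.max(mk$n_a + mk$n_b)
  flip <- mk$label_a[best] != label_a
  list(marking_a = if (flip) mk$marking_b[[best]] else mk$marking_a[[best]],
       marking_b = if (flip) mk$marking_a[[best]] else mk$marking_b[[best]],
       cut = mk$cut[best])
}

#' Perturb a pose by exact translation and rotation magnitudes
#'
#' The returned pose differs from `pose` by exactly `offset_deg` of
#' rotation (about a random axis through the world point `centre`) and
#' exactly `offset_mm` of displacement of `centre`.
#'
#' @param pose A `rigid_transform`.
#' @param centre World point, mm (typically the fragment's world centroid).
#' @param offset_mm,offset_deg Perturbation magnitudes.
#' @param seed Integer seed for the random directions.
#' @export
perturb_pose <- function(pose, centre, offset_mm, offset_deg, seed = 1) {
  .with_seed(seed, {
    axis <- .random_unit_vector()
    dir <- .random_unit_vector()
    dq <- quat_from_axis_angle(axis, offset_deg * pi / 180)
    Rm <- quat_to_matrix(dq)
    q <- quat_multiply(dq, pose$q)
    t <- as.numeric(Rm %*% (pose$t - centre)) + centre + offset_mm * dir
    rigid_transform(q, t)
  })
}

#' Scripted handle trajectories on a phantom
#'
#' Deterministic interaction scripts for offline simulation:
#' `approach_press` drives the handle linearly from the moving fragment's
#' current position onto the target fragment's centroid (the final sample
#' penetrates the obstacle's bounding box by construction); `slide_along`
#' approaches until the bounding boxes touch and then slides tangentially;
#' `coarse_align` holds the handle at the moving fragment's truth pose
#' perturbed by exactly (`offset_mm`, `offset_deg`) — the approximate
#' initial position a user would leave a fragment in before snapping.
#'
#' @param pt A `phantom_truth`.
#' @param fragments Named list of `fragment`s built from `pt$labeled`.
#' @param scenario `"approach_press"`, `"slide_along"` or `"coarse_align"`.
#' @param moving_label Label of the manipulated fragment (default 2).
#' @param target_label Label of the obstacle/mating fragment (default 1).
#' @param offset_mm,offset_deg `coarse_align` perturbation (defaults 2 mm,
#'   5 degrees).
#' @param n_samples Samples along the trajectory.
#' @param seed Seed for the random perturbation directions.
#' @return A `handle_trajectory`; for `coarse_align` the perturbed pose is
#'   also in `attr(, "target_pose")`.
#' @export
scripted_trajectories <- function(pt, fragments,
                                  scenario = c("approach_press", "slide_along",
                                               "coarse_align"),
                                  moving_label = 2, target_label = 1,
                                  offset_mm = 2, offset_deg = 5,
                                  n_samples = 25, seed = 1) {
  scenario <- match.arg(scenario)
  moving <- fragments[[as.character(moving_label)]]
  target <- fragments[[as.character(target_label)]]
  stopifnot(!is.null(moving), !is.null(target))
  times <- seq(0, 1, length.out = n_samples)
  if (scenario == "coarse_align") {
    truth <- pt$truth_poses[[as.character(moving_label)]]
    centre <- apply_transform(truth, moving$centroid)
    tp <- perturb_pose(truth, centre, offset_mm, offset_deg,
                       seed = .sub_seed(seed, 7))
    traj <- handle_trajectory(times, rep(list(tp), n_samples))
    attr(traj, "target_pose") <- tp
    return(traj)
  }
  start <- moving$pose
  c_m <- fragment_world_centroid(moving)
  c_t <- fragment_world_centroid(target)
  if (scenario == "approach_press") {
    poses <- lapply(times, function(a) {
      rigid_transform(start$q, start$t + a * (c_t - c_m))
    })
    return(handle_trajectory(times, poses))
  }
  # slide_along: approach 60% of the way, then slide perpendicular
  d <- c_t - c_m
  dn <- d / sqrt(sum(d^2))
  tang <- cross3(dn, if (abs(dn[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0))
  tang <- tang / sqrt(sum(tang^2))
  half <- ceiling(n_samples / 2)
  poses <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    if (i <= half) {
      a <- (i - 1) / max(1, half - 1)
      poses[[i]] <- rigid_transform(start$q, start$t + 0.6 * a * d)
    } else {
      a <- (i - half) / max(1, n_samples - half)
      poses[[i]] <- rigid_transform(start$q,
                                    start$t + 0.6 * d + a * 5 * tang)
    }
  }
  handle_trajectory(times, poses)
}


# Labels involved in any 26-adjacency between two distinct nonzero labels
# (empty if all fragments are separated).
.labels_adjacent <- function(lab) {
  dm <- dim(lab)
  off <- connectivity_offsets(26)
  hit <- integer(0)
  for (r in seq_len(nrow(off))) {
    si <- max(1, 1 + off[r, 1]):min(dm[1], dm[1] + off[r, 1])
    sj <- max(1, 1 + off[r, 2]):min(dm[2], dm[2] + off[r, 2])
    sk <- max(1, 1 + off[r, 3]):min(dm[3], dm[3] + off[r, 3])
    a <- lab[si, sj, sk]
    b <- lab[si - off[r, 1], sj - off[r, 2], sk - off[r, 3]]
    tt <- a > 0L & b > 0L & a != b
    if (any(tt)) hit <- union(hit, c(a[tt], b[tt]))
  }
  hit
}


# Re-pack nonzero labels into 1..K preserving order.
.relabel_contiguous <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  nz <- lab > 0L
  lab[nz] <- map[lab[nz]]
  lab
}
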