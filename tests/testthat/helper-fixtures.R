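# Shared fixtures, built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) assign(key, builder(), .fixture_cache)
  get(key, .fixture_cache)
}

# Standard one-cut cube phantom with its fragments and mating markings.
snap_fixture <- function(seed, erosion_voxels = 0) {
  cached(sprintf("snapfix_%d_%d", seed, erosion_voxels), function() {
    pt <- generate_phantom(phantom_spec(seed = seed,
                                        erosion_voxels = erosion_voxels))
    frags <- lapply(stats::setNames(nm = as.character(1:2)),
                    function(lb) fragment_from_labels(pt$labeled, as.integer(lb)))
    for (lb in names(frags)) frags[[lb]]$pose <- pt$truth_poses[[lb]]
    mm <- mating_markings(pt, frags, 2, 1)
    list(pt = pt, frags = frags, mm = mm)
  })
}

# Small two-fragment phantom for collision tests.
contact_fixture <- function() {
  cached("contactfix", function() {
    pt <- generate_phantom(phantom_spec(dims = c(30, 30, 22), seed = 42,
                                        noise_components = 0))
    frags <- lapply(stats::setNames(nm = as.character(1:2)),
                    function(lb) fragment_from_labels(pt$labeled, as.integer(lb)))
    list(pt = pt, frags = frags)
  })
}

# A flat wall (static) plus a small cube (moving) on a shared 1 mm grid,
# used for the wall-press scenarios. The wall's outward face normal is +x.
wall_fixture <- function() {
  cached("wallfix", function() {
    dims <- c(26, 24, 24)
    lab <- array(0L, dims)
    lab[3:10, 2:23, 2:23] <- 1L            # wall slab
    lab[16:21, 10:15, 10:15] <- 2L         # cube, 6 mm, 5 mm clear of the wall
    lv <- labeled_volume(lab, spacing = c(1, 1, 1), origin = c(0, 0, 0))
    list(lv = lv,
         wall = fragment_from_labels(lv, 1L),
         cube = fragment_from_labels(lv, 2L),
         wall_face_x = 10)                 # wall surface plane x = 10 mm
  })
}

# Three-slab cube with two rough parallel-ish cuts: a controlled phantom
# with two geometrically similar mating sites for the middle slab.
two_site_fixture <- function() {
  cached("twosite", function() {
    dims <- c(34, 34, 26)
    sp <- c(0.5, 0.5, 0.7)
    lab <- array(0L, dims)
    xs <- (seq_len(dims[1]) - 0.5) * sp[1]
    ys <- (seq_len(dims[2]) - 0.5) * sp[2]
    zs <- (seq_len(dims[3]) - 0.5) * sp[3]
    P <- cbind(rep(xs, times = dims[2] * dims[3]),
               rep(rep(ys, each = dims[1]), times = dims[3]),
               rep(zs, each = dims[1] * dims[2]))
    rough <- function(p) 0.9 * sin(2 * pi * p[, 2] / 5.5) +
      0.7 * cos(2 * pi * p[, 3] / 4.5)
    s1 <- P[, 1] - (6 + rough(P))
    s2 <- P[, 1] - (11 + rough(P))
    inside <- P[, 1] > 1 & P[, 1] < 16 & P[, 2] > 1 & P[, 2] < 16 &
      P[, 3] > 1 & P[, 3] < 17
    lab[inside & s1 <= 0] <- 1L
    lab[inside & s1 > 0 & s2 <= 0] <- 2L
    lab[inside & s2 > 0] <- 3L
    lv <- labeled_volume(lab, spacing = sp, origin = c(0, 0, 0))
    frags <- lapply(stats::setNames(nm = as.character(1:3)),
                    function(lb) fragment_from_labels(lv, as.integer(lb)))
    # mark the faces of cut 1 (fragments 1 and 2) by distance to the cut
    band <- sqrt(sum(sp^2))
    mark_near_cut <- function(frag, sfun) {
      pts <- cbind(frag$shell$x, frag$shell$y, frag$shell$z)
      marked_surface(frag$label, frag$shell$point_id[abs(sfun(pts)) <= band])
    }
    cut1 <- function(p) p[, 1] - (6 + rough(p))
    cut2 <- function(p) p[, 1] - (11 + rough(p))
    list(lv = lv, frags = frags,
         ms1_f1 = mark_near_cut(frags[["1"]], cut1),
         ms1_f2 = mark_near_cut(frags[["2"]], cut1),
         ms2_f2 = mark_near_cut(frags[["2"]], cut2),
         ms2_f3 = mark_near_cut(frags[["3"]], cut2))
  })
}

pose_err_vs <- function(pose, truth, point) pose_error(pose, truth, point = point)
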