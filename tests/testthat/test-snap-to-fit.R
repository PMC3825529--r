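test_that("painting marks exactly the shell points within the brush", {
  wf <- wall_fixture()
  cube <- wf$cube
  # far path marks nothing
  expect_length(paint_surface(cube, c(200, 200, 200), 2)$marked_ids, 0)
  # a huge brush marks everything
  allm <- paint_surface(cube, fragment_world_centroid(cube), 50)
  expect_setequal(allm$marked_ids, cube$shell$point_id)
  # path along the -x face: equals the brute-force distance filter
  path <- cbind(15, seq(9, 16, by = 0.5), 12.5)
  ms <- paint_surface(cube, path, 1.2)
  world <- fragment_world_points(cube)
  d <- apply(world, 1, function(p) {
    min(sqrt(colSums((t(path) - p)^2)))
  })
  expect_setequal(ms$marked_ids, cube$shell$point_id[d <= 1.2])
  # idempotent and cumulative
  ms2 <- paint_surface(cube, path, 1.2, existing = ms)
  expect_identical(ms2$marked_ids, ms$marked_ids)
  more <- paint_surface(cube, c(18, 12.5, 9), 1.5, existing = ms)
  expect_true(all(ms$marked_ids %in% more$marked_ids))
  expect_gt(length(more$marked_ids), length(ms$marked_ids))
})

test_that("colinearity weight is 1 for mating, 0 for same-facing normals", {
  expect_equal(colinearity_weight(c(0, 0, 1), c(0, 0, -1)), 1)
  expect_equal(colinearity_weight(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(colinearity_weight(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(colinearity_weight(c(0, 0, 1),
                                  c(0, sin(pi / 3), -cos(pi / 3)), p = 2),
               cos(pi / 3)^2, tolerance = 1e-12)
})

# Two parallel planar marked faces with exactly opposing normals, offset d:
# per-pair force k_a * d toward contact, zero torque by symmetry.
planar_pair <- function(d, flip_target = FALSE, n_side = 5) {
  g <- as.matrix(expand.grid(seq_len(n_side), seq_len(n_side)))
  mk_shell <- function(z, nz) {
    sh <- tibble::tibble(point_id = seq_len(nrow(g)),
                         x = g[, 1], y = g[, 2], z = z,
                         nx = 0, ny = 0, nz = nz)
    class(sh) <- c("point_shell", class(sh))
    sh
  }
  field <- structure(list(values = array(1, c(2, 2, 2)),
                          spacing = c(1, 1, 1), origin = c(90, 90, 90)),
                     class = "distance_field")
  moving <- fragment(1L, mk_shell(d, +1), field)
  target <- fragment(2L, mk_shell(0, if (flip_target) +1 else -1), field)
  list(moving = moving, target = target,
       ms_m = marked_surface(1L, moving$shell$point_id),
       ms_t = marked_surface(2L, target$shell$point_id))
}

test_that("planar-face attraction matches the closed-form sum", {
  d <- 0.8
  pp <- planar_pair(d)
  sp <- snap_params(k_a = 2, capture_radius = 5)
  aw <- attraction_wrench(pp$moving, pp$target, pp$ms_m, pp$ms_t, sp)
  n_pairs <- nrow(pp$moving$shell)
  expect_equal(aw$n_pairs, n_pairs)
  expect_equal(aw$similarity, 1)
  expect_equal(aw$wrench$force, c(0, 0, -2 * n_pairs * d), tolerance = 1e-9)
  expect_equal(aw$wrench$torque, c(0, 0, 0), tolerance = 1e-9)

  # same geometry with same-facing normals: zero attraction
  pp2 <- planar_pair(d, flip_target = TRUE)
  aw2 <- attraction_wrench(pp2$moving, pp2$target, pp2$ms_m, pp2$ms_t, sp)
  expect_equal(aw2$wrench$force, c(0, 0, 0))
  expect_equal(aw2$similarity, 0)
})

test_that("empty markings give zero wrench, zero similarity and a warning", {
  pp <- planar_pair(0.5)
  sp <- snap_params()
  expect_warning(
    aw <- attraction_wrench(pp$moving, pp$target, marked_surface(1L),
                            marked_surface(2L, pp$ms_t$marked_ids), sp),
    "empty marking")
  expect_equal(aw$wrench$force, c(0, 0, 0))
  expect_equal(aw$similarity, 0)
  # points outside the capture radius contribute nothing
  far <- planar_pair(7)
  aw3 <- attraction_wrench(far$moving, far$target, far$ms_m, far$ms_t,
                           snap_params(capture_radius = 5))
  expect_equal(aw3$n_pairs, 0L)
})

test_that("snapping from the ground-truth pose stays at the ground truth", {
  fx <- snap_fixture(3)
  truth <- fx$pt$truth_poses[["2"]]
  res <- snap_to_fit(fx$frags[["2"]], fx$frags[["1"]], fx$mm$marking_a,
                     fx$mm$marking_b, start = truth)
  err <- pose_error(res$final_pose, truth, point = fx$frags[["2"]]$centroid)
  expect_lt(err[["trans_mm"]], 0.5)
  expect_lt(err[["rot_deg"]], 1)
  expect_gt(res$similarity, 0.4)
  expect_true(res$converged)
})

test_that("snap recovers a coarse misalignment on a phantom", {
  fx <- snap_fixture(5)
  truth <- fx$pt$truth_poses[["2"]]
  moving <- fx$frags[["2"]]
  centre <- apply_transform(truth, moving$centroid)
  start <- perturb_pose(truth, centre, 2, 5, seed = 99)
  res <- snap_to_fit(moving, fx$frags[["1"]], fx$mm$marking_a,
                     fx$mm$marking_b, start = start)
  err <- pose_error(res$final_pose, truth, point = moving$centroid)
  expect_lt(err[["trans_mm"]], 0.5)
  expect_lt(err[["rot_deg"]], 1)
  # the converged pose is a stable fit: re-running from a small
  # perturbation returns to the same pose
  nudged <- perturb_pose(res$final_pose, centre, 0.1, 0.5, seed = 7)
  res2 <- snap_to_fit(moving, fx$frags[["1"]], fx$mm$marking_a,
                      fx$mm$marking_b, start = nudged)
  d <- pose_error(res2$final_pose, res$final_pose, point = moving$centroid)
  expect_lt(d[["trans_mm"]], 0.2)
  expect_lt(d[["rot_deg"]], 0.5)
})

test_that("snap results expose tidy() and glance()", {
  fx <- snap_fixture(3)
  res <- snap_to_fit(fx$frags[["2"]], fx$frags[["1"]], fx$mm$marking_a,
                     fx$mm$marking_b, start = fx$pt$truth_poses[["2"]])
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("qw", "tx", "similarity", "converged") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_true(gl$similarity >= 0 && gl$similarity <= 1)
})

test_that("similarity decreases as marked faces rotate out of anti-alignment", {
  d <- 0.6
  sims <- vapply(c(0, 15, 30, 60), function(ang) {
    pp <- planar_pair(d)
    # tilt every moving normal by ang degrees
    a <- ang * pi / 180
    pp$moving$shell$nx <- sin(a)
    pp$moving$shell$nz <- cos(a)
    attraction_wrench(pp$moving, pp$target, pp$ms_m, pp$ms_t,
                      snap_params())$similarity
  }, numeric(1))
  expect_true(all(diff(sims) <= 1e-12))
  expect_equal(sims[1], 1)
})
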