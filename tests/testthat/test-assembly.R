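make_scene <- function(n = 3, seed = 61) {
  wf <- wall_fixture()
  set.seed(seed)
  frags <- lapply(seq_len(n), function(i) {
    f <- wf$cube
    f$label <- i
    f$pose <- random_rigid_transform()
    f
  })
  scene(frags)
}

world_poses <- function(sc) lapply(sc$fragments, function(f) f$pose)

test_that("grouping, attaching and detaching never move fragments", {
  sc <- make_scene()
  before <- world_poses(sc)
  sc <- create_group(sc, c(1, 2))
  gid <- attr(sc, "group_id")
  expect_identical(world_poses(sc), before)
  sc <- attach_fragment(sc, gid, 3)
  expect_identical(world_poses(sc), before)
  sc <- detach_fragment(sc, gid, 3)
  expect_identical(world_poses(sc), before)
  # grouping an already-grouped fragment names both groups
  expect_error(create_group(sc, 2), "g1")
  expect_error(attach_fragment(create_group(sc, 3), "g2", 1), "g1")
  expect_error(detach_fragment(sc, gid, 3), "not a member")
})

test_that("group motion matches the per-member matrix oracle", {
  set.seed(62)
  sc <- make_scene()
  before <- world_poses(sc)
  sc <- create_group(sc, c(1, 2, 3))
  gid <- attr(sc, "group_id")
  motion <- random_rigid_transform()
  sc <- set_group_pose(sc, gid, motion)
  for (lb in names(sc$fragments)) {
    expect_lt(max(abs(as_homogeneous(sc$fragments[[lb]]$pose) -
                        as_homogeneous(motion) %*%
                        as_homogeneous(before[[lb]]))), 1e-9)
  }
  # identity group pose moves nothing further; relative poses preserved
  rel_before <- compose(transform_inverse(sc$fragments[["1"]]$pose),
                        sc$fragments[["2"]]$pose)
  sc <- set_group_pose(sc, gid, compose(motion, random_rigid_transform()))
  rel_after <- compose(transform_inverse(sc$fragments[["1"]]$pose),
                       sc$fragments[["2"]]$pose)
  expect_true(transforms_equal(rel_before, rel_after, 1e-9, 1e-9))
})

test_that("random attach/move/detach sequences preserve offsets exactly", {
  set.seed(63)
  sc <- make_scene(4)
  sc <- create_group(sc, c(1, 2))
  gid <- attr(sc, "group_id")
  grouped <- c(1, 2)
  free <- c(3, 4)
  for (step in 1:200) {
    op <- sample(c("move", "attach", "detach"), 1)
    if (op == "move") {
      sc <- set_group_pose(sc, gid, random_rigid_transform())
    } else if (op == "attach" && length(free)) {
      lb <- free[1]
      pose_before <- sc$fragments[[as.character(lb)]]$pose
      sc <- attach_fragment(sc, gid, lb)
      expect_identical(sc$fragments[[as.character(lb)]]$pose, pose_before)
      grouped <- c(grouped, lb); free <- setdiff(free, lb)
    } else if (op == "detach" && length(grouped) > 1) {
      lb <- grouped[length(grouped)]
      pose_before <- sc$fragments[[as.character(lb)]]$pose
      sc <- detach_fragment(sc, gid, lb)
      expect_identical(sc$fragments[[as.character(lb)]]$pose, pose_before)
      grouped <- setdiff(grouped, lb); free <- c(free, lb)
    }
    # member world pose == compose(group_pose, offset) at all times
    g <- sc$groups[[gid]]
    for (lb in g$member_labels) {
      expect_true(transforms_equal(
        sc$fragments[[as.character(lb)]]$pose,
        compose(g$group_pose, g$member_offsets[[as.character(lb)]]),
        1e-9, 1e-9))
    }
  }
})

test_that("a group manipulated as one body moves members consistently", {
  wf <- wall_fixture()
  f1 <- wf$cube; f1$label <- 1L
  f2 <- wf$cube; f2$label <- 2L
  f2$pose <- rigid_transform(t = c(0, 7, 0))
  sc <- scene(list(f1, f2))
  sc <- create_group(sc, c(1, 2))
  gid <- attr(sc, "group_id")
  body <- group_body(sc, gid)
  expect_equal(nrow(body$shell), nrow(f1$shell) + nrow(f2$shell))
  # free-space tracking of the composite body, then apply the group pose
  handle <- rigid_transform(q = c(cos(0.1), 0, 0, sin(0.1)), t = c(1, 2, 3))
  st <- step_quasistatic(handle, body, list(), coupling_params())
  sc2 <- set_group_pose(sc, gid, st$fragment$pose)
  for (lb in c("1", "2")) {
    manual <- compose(st$fragment$pose,
                      sc$groups[[gid]]$member_offsets[[lb]])
    expect_true(transforms_equal(sc2$fragments[[lb]]$pose, manual,
                                 1e-9, 1e-9))
  }
})

test_that("plans round-trip through JSON bit-precisely", {
  set.seed(64)
  sc <- make_scene()
  sc <- create_group(sc, c(1, 3))
  sc <- set_group_pose(sc, attr(sc, "group_id"), random_rigid_transform())
  sc$markings <- list(marked_surface(2L, c(4L, 9L, 17L)))
  path <- withr::local_tempfile(fileext = ".json")
  export_plan(sc, path)

  sc_fresh <- make_scene()   # same labels, different poses
  back <- import_plan(sc_fresh, path)
  for (lb in names(sc$fragments)) {
    expect_true(transforms_equal(back$fragments[[lb]]$pose,
                                 sc$fragments[[lb]]$pose, 1e-9, 1e-9))
  }
  expect_equal(back$groups[["g1"]]$member_labels,
               sc$groups[["g1"]]$member_labels)
  expect_equal(back$markings[[1]]$marked_ids, c(4L, 9L, 17L))
})

test_that("plan import rejects version mismatches and truncated files", {
  sc <- make_scene()
  path <- withr::local_tempfile(fileext = ".json")
  export_plan(sc, path)
  txt <- readLines(path)
  writeLines(sub("fragreduce-plan-1", "fragreduce-plan-99", txt), path)
  expect_error(import_plan(sc, path), "version mismatch")
  one <- paste(txt, collapse = "")
  writeLines(substr(one, 1, nchar(one) %/% 2), path)
  expect_error(import_plan(sc, path), "parse")
})

test_that("reduction reports match direct per-fragment recomputation", {
  set.seed(65)
  sc <- make_scene()
  truth <- world_poses(sc)
  rep0 <- reduction_report(sc, truth)
  expect_equal(rep0$trans_err_mm, rep(0, 3))
  expect_equal(rep0$rot_err_deg, rep(0, 3))

  # one fragment offset by exactly 1 mm
  sc1 <- sc
  sc1$fragments[["2"]]$pose <- compose(rigid_transform(t = c(1, 0, 0)),
                                       sc$fragments[["2"]]$pose)
  rep1 <- reduction_report(sc1, truth)
  expect_equal(rep1$trans_err_mm[rep1$label == 2], 1, tolerance = 1e-9)
  expect_equal(rep1$trans_err_mm[rep1$label != 2], rep(0, 2))

  # random perturbations against independent recomputation
  sc2 <- sc
  for (lb in names(sc2$fragments)) {
    sc2$fragments[[lb]]$pose <- compose(random_rigid_transform(),
                                        sc2$fragments[[lb]]$pose)
  }
  rep2 <- reduction_report(sc2, truth)
  for (i in seq_len(nrow(rep2))) {
    lb <- as.character(rep2$label[i])
    frag <- sc2$fragments[[lb]]
    c_scene <- apply_transform(frag$pose, frag$centroid)
    c_truth <- apply_transform(truth[[lb]], frag$centroid)
    expect_equal(rep2$trans_err_mm[i], sqrt(sum((c_scene - c_truth)^2)),
                 tolerance = 1e-9)
    qd <- abs(sum(frag$pose$q * truth[[lb]]$q))
    expect_equal(rep2$rot_err_deg[i], 2 * acos(min(1, qd)) * 180 / pi,
                 tolerance = 1e-6)
  }
  expect_error(reduction_report(sc, truth[1:2]), "missing")
  gl <- glance(rep2)
  expect_equal(gl$rms_trans_mm, sqrt(mean(rep2$trans_err_mm^2)))
})
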