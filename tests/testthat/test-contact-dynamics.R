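test_that("separated fragments produce zero wrench and no contacts", {
  wf <- wall_fixture()
  ct <- contact_wrench(wf$cube, list(wf$wall), k_c = 50)
  expect_equal(nrow(ct$contacts), 0L)
  expect_equal(ct$wrench$force, c(0, 0, 0))
  expect_equal(ct$wrench$torque, c(0, 0, 0))
  expect_equal(ct$max_penetration, 0)
})

test_that("a single point inside a flat wall feels k_c * penetration along +x", {
  wf <- wall_fixture()
  # Penetration is the interpolated signed-field deficit -f(x). For the
  # centre-to-centre signed EDT of a flat wall with its surface at x = 10
  # (1 mm grid), f(x) = 2 (x - 10) in the boundary band [9.5, 10.5] and
  # f(x) = x - 10.5 deeper inside: the closed form the probe must feel.
  for (x in c(9.7, 9.2)) {
    pen <- if (x >= 9.5) 2 * (10 - x) else 10.5 - x
    sh <- tibble::tibble(point_id = 1L, x = x, y = 12, z = 12,
                         nx = -1, ny = 0, nz = 0)
    class(sh) <- c("point_shell", class(sh))
    probe <- fragment(9L, sh, wf$cube$field, centroid = c(x, 12, 12))
    ct <- contact_wrench(probe, list(wf$wall), k_c = 50)
    expect_equal(nrow(ct$contacts), 1L)
    expect_equal(ct$max_penetration, pen, tolerance = 1e-9)
    expect_equal(ct$wrench$force, 50 * pen * c(1, 0, 0), tolerance = 1e-9)
    expect_equal(ct$wrench$torque, c(0, 0, 0), tolerance = 1e-9)
  }
})

test_that("pruned contact equals exhaustive evaluation on random poses", {
  set.seed(51)
  ff <- contact_fixture()
  moving <- ff$frags[["2"]]; static <- ff$frags[["1"]]
  c_m <- moving$centroid; c_s <- static$centroid
  for (i in 1:25) {
    # random pose that often overlaps the static fragment
    off <- runif(3, -2, 2) + (c_s - c_m) * runif(1, 0, 1)
    moving$pose <- rigid_transform(q = rnorm(4), t = off)
    a <- contact_wrench(moving, list(static), k_c = 50, prune = TRUE)
    b <- contact_wrench(moving, list(static), k_c = 50, prune = FALSE)
    expect_identical(a$contacts$point_id, b$contacts$point_id)
    expect_equal(a$wrench$force, b$wrench$force, tolerance = 1e-9)
    expect_equal(a$wrench$torque, b$wrench$torque, tolerance = 1e-9)
    expect_equal(a$max_penetration, b$max_penetration, tolerance = 1e-12)
  }
})

test_that("coupling wrench has the closed spring forms", {
  p <- coupling_params(k_t = 2, k_r = 30)
  pose <- rigid_transform(t = c(1, 2, 3))
  expect_equal(coupling_wrench(pose, pose, p)$force, c(0, 0, 0))
  expect_equal(coupling_wrench(pose, pose, p)$torque, c(0, 0, 0))

  handle <- rigid_transform(t = c(3, 2, 3))   # pure 2 mm x-offset
  w <- coupling_wrench(handle, pose, p)
  expect_equal(w$force, c(2 * 2, 0, 0))
  expect_equal(w$torque, c(0, 0, 0))

  handle_rot <- rigid_transform(q = c(cos(pi / 4), 0, 0, sin(pi / 4)),
                                t = pose$t)   # 90 deg about z
  w2 <- coupling_wrench(handle_rot, pose, p)
  expect_equal(w2$force, c(0, 0, 0))
  expect_equal(w2$torque, c(0, 0, 30 * pi / 2), tolerance = 1e-9)
})

test_that("free-space tracking converges to the handle pose", {
  wf <- wall_fixture()
  p <- coupling_params()
  handle <- rigid_transform(q = c(cos(0.2), 0, sin(0.2), 0), t = c(2, -1, 3))
  st <- step_quasistatic(handle, wf$cube, list(), p)
  expect_true(st$converged)
  err <- pose_error(st$fragment$pose, handle)
  expect_lt(err[["trans_mm"]], 10 * p$tol)
  expect_lt(err[["rot_deg"]], 10 * p$tol * 180 / pi)
})

test_that("wall press obeys the spring/penalty penetration bound", {
  wf <- wall_fixture()
  p <- coupling_params(k_t = 1, k_c = 50)
  press <- 3   # handle driven 3 mm past the contact point
  gap <- 5     # cube face starts 5 mm from the wall
  n <- 24
  times <- seq(0, 1, length.out = n)
  poses <- lapply(times, function(a) {
    rigid_transform(t = c(-(gap + press) * a, 0, 0))
  })
  log <- simulate_manipulation(handle_trajectory(times, poses),
                               wf$cube, list(wf$wall), p)
  voxdiag <- sqrt(sum(wf$lv$spacing^2))
  bound <- p$k_t * press / p$k_c + voxdiag
  expect_lt(attr(log, "max_penetration"), bound)
  expect_true(all(log$converged))

  # 1-D closed form at the final step: k_t (D - pen) = n_c k_c pen
  last <- log[nrow(log), ]
  frag <- attr(log, "fragment")
  ct <- contact_wrench(frag, list(wf$wall), k_c = p$k_c)
  nc <- nrow(ct$contacts)
  expect_gt(nc, 0)
  pen_pred <- p$k_t * press / (p$k_t + nc * p$k_c)
  expect_lt(abs(ct$max_penetration - pen_pred), 0.1)
  # monotone non-decreasing contact force while the handle advances
  f <- log$force_mag
  expect_true(all(diff(f) >= -1e-6 * max(f)))
})

test_that("sliding along the wall keeps the penetration bound each step", {
  wf <- wall_fixture()
  p <- coupling_params()
  press <- 2; gap <- 5
  n <- 30
  times <- seq(0, 1, length.out = n)
  poses <- lapply(seq_len(n), function(i) {
    if (i <= 12) {
      a <- (i - 1) / 11
      rigid_transform(t = c(-(gap + press) * a, 0, 0))
    } else {
      a <- (i - 12) / (n - 12)
      rigid_transform(t = c(-(gap + press), 4 * a, 0))
    }
  })
  log <- simulate_manipulation(handle_trajectory(times, poses),
                               wf$cube, list(wf$wall), p)
  bound <- p$k_t * press / p$k_c + sqrt(sum(wf$lv$spacing^2))
  expect_true(all(log$max_penetration <= bound))
  # the fragment tracked the tangential motion
  final <- log$pose[[nrow(log)]]
  expect_equal(final$t[2], 4, tolerance = 0.05)
})

test_that("simulation is deterministic", {
  wf <- wall_fixture()
  p <- coupling_params()
  times <- seq(0, 1, length.out = 10)
  poses <- lapply(times, function(a) rigid_transform(t = c(-6 * a, a, 0)))
  traj <- handle_trajectory(times, poses)
  log1 <- simulate_manipulation(traj, wf$cube, list(wf$wall), p)
  log2 <- simulate_manipulation(traj, wf$cube, list(wf$wall), p)
  expect_identical(log1$force_mag, log2$force_mag)
  expect_identical(lapply(log1$pose, unclass), lapply(log2$pose, unclass))
})

test_that("quasi-static stepping is equivariant under rigid scene motion", {
  set.seed(52)
  wf <- wall_fixture()
  p <- coupling_params(max_iters = 600)
  handle <- rigid_transform(t = c(-6, 0.5, -0.5))
  base <- step_quasistatic(handle, wf$cube, list(wf$wall), p)

  for (i in 1:3) {
    g <- random_rigid_transform()
    cube2 <- wf$cube; cube2$pose <- compose(g, wf$cube$pose)
    wall2 <- wf$wall; wall2$pose <- compose(g, wf$wall$pose)
    st2 <- step_quasistatic(compose(g, handle), cube2, list(wall2), p)
    expect_true(transforms_equal(st2$fragment$pose,
                                 compose(g, base$fragment$pose),
                                 tol_rot = 1e-5, tol_trans = 1e-4))
  }
})

test_that("simulation logs flatten to CSV", {
  wf <- wall_fixture()
  times <- seq(0, 1, length.out = 4)
  poses <- lapply(times, function(a) rigid_transform(t = c(-a, 0, 0)))
  log <- simulate_manipulation(handle_trajectory(times, poses),
                               wf$cube, list(wf$wall), coupling_params())
  path <- withr::local_tempfile(fileext = ".csv")
  write_simulation_log(log, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 4)
  expect_true(all(c("qw", "tx", "force_mag", "max_penetration") %in%
                    names(back)))
})
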