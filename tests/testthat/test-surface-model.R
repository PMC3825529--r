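test_that("signed distance of a solid cube matches the boundary-face oracle", {
  # 11^3 cube at 1 mm spacing: centre is 5.5 mm from the nearest face
  lab <- array(0L, c(15, 15, 15)); lab[3:13, 3:13, 3:13] <- 1L
  lv <- labeled_volume(lab, spacing = c(1, 1, 1))
  field <- build_distance_field(lv, 1L)
  centre_val <- field_value(field, voxel_centers(lv, c(8, 8, 8)))
  expect_lt(abs(centre_val - (-5.5)), 0.6)
  expect_lt(centre_val, 0)

  # a far outside voxel: positive and >= true distance - one voxel diagonal
  p <- voxel_centers(lv, c(1, 1, 1))
  surf <- which(lab == 1L, arr.ind = TRUE)
  # brute-force nearest surface voxel centre
  dtrue <- min(sqrt(rowSums(sweep(voxel_centers(lv, surf), 2, p, "-")^2)))
  v <- field_value(field, p)
  expect_gt(v, 0)
  expect_gte(v, dtrue - sqrt(3))
})

test_that("anisotropic signed distance agrees with brute force on random masks", {
  set.seed(41)
  sp <- c(0.35, 0.35, 0.60)
  for (trial in 1:4) {
    dims <- c(7, 6, 5)
    mask <- random_blob_mask(dims, 0.35)
    if (!any(mask) || all(mask)) next
    sd <- signed_distance(mask, sp)
    ctr <- voxel_centers(list(spacing = sp, origin = c(0, 0, 0)),
                         as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3])))
    inpts <- ctr[as.vector(mask), , drop = FALSE]
    outpts <- ctr[!as.vector(mask), , drop = FALSE]
    for (i in sample(nrow(ctr), 20)) {
      p <- ctr[i, ]
      inside <- as.vector(mask)[i]
      other <- if (inside) outpts else inpts
      dtrue <- min(sqrt(rowSums(sweep(other, 2, p, "-")^2)))
      expect_equal(abs(sd[i]), dtrue, tolerance = 1e-9)
      expect_equal(sign(sd[i]), if (inside) -1 else 1)
    }
  }
})

test_that("one-voxel fragments give a negative centre and a valid tiny shell", {
  lab <- array(0L, c(7, 7, 7)); lab[4, 4, 4] <- 1L
  lv <- labeled_volume(lab, spacing = c(0.35, 0.35, 0.60))
  field <- build_distance_field(lv, 1L)
  expect_lt(field_value(field, voxel_centers(lv, c(4, 4, 4))), 0)
  expect_gt(field_value(field, voxel_centers(lv, c(2, 4, 4))), 0)
  shell <- extract_point_shell(lv, 1L, field)
  expect_gte(nrow(shell), 1)
  expect_lte(nrow(shell), 6)
  expect_equal(sqrt(shell$nx^2 + shell$ny^2 + shell$nz^2), rep(1, nrow(shell)),
               tolerance = 1e-6)
})

test_that("shell point count equals the brute-force surface-voxel count", {
  lab <- array(0L, c(12, 10, 9)); lab[3:9, 3:8, 3:7] <- 1L
  lv <- labeled_volume(lab, spacing = c(0.35, 0.35, 0.60))
  frag <- fragment_from_labels(lv, 1L)
  # brute force: voxels of the label with at least one 6-neighbour outside
  cnt <- 0
  for (i in 3:9) for (j in 3:8) for (k in 3:7) {
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    if (any(lab[nb] == 0L)) cnt <- cnt + 1
  }
  expect_equal(nrow(frag$shell), cnt)
})

test_that("sphere shell normals are radial and point outward", {
  dims <- c(30, 30, 30); sp <- c(1, 1, 1)
  ctr <- dims * sp / 2
  idx <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
  P <- sweep(idx - 0.5, 2, sp, "*")
  r <- sqrt(rowSums(sweep(P, 2, ctr, "-")^2))
  lab <- array(0L, dims); lab[r <= 10] <- 1L
  lv <- labeled_volume(lab, spacing = sp)
  frag <- fragment_from_labels(lv, 1L, normals = "plane_fit")
  pts <- cbind(frag$shell$x, frag$shell$y, frag$shell$z)
  nrm <- cbind(frag$shell$nx, frag$shell$ny, frag$shell$nz)
  radial <- sweep(pts, 2, ctr, "-")
  radial <- radial / sqrt(rowSums(radial^2))
  ang <- acos(pmin(1, rowSums(nrm * radial))) * 180 / pi
  expect_gte(mean(ang <= 5), 0.95)

  # outwardness of the default gradient normals: the field increases along
  # the normal direction
  fragg <- fragment_from_labels(lv, 1L)
  nrg <- cbind(fragg$shell$nx, fragg$shell$ny, fragg$shell$nz)
  eps <- 0.25 * min(sp)
  v0 <- field_value(frag$field, pts)
  v1 <- field_value(frag$field, pts + eps * nrg)
  expect_gte(mean(v1 > v0), 0.99)
  # every shell point sits within a voxel diagonal of the zero level set
  expect_lt(max(abs(v0)), sqrt(sum(sp^2)))
})

test_that("union of two disjoint fragments has the pointwise-min field", {
  lab <- array(0L, c(16, 10, 8))
  lab[2:6, 2:8, 2:6] <- 1L
  lab[10:14, 3:9, 3:7] <- 2L
  lv <- labeled_volume(lab, spacing = c(0.5, 0.5, 0.5))
  f1 <- build_distance_field(lv, 1L, padding = 12)
  f2 <- build_distance_field(lv, 2L, padding = 12)
  merged <- lab; merged[merged == 2L] <- 1L
  fu <- build_distance_field(labeled_volume(merged, spacing = lv$spacing), 1L,
                             padding = 12)
  set.seed(43)
  pts <- cbind(runif(50, 1, 7), runif(50, 1, 4), runif(50, 1, 3.5))
  vu <- field_value(fu, pts)
  vmin <- pmin(field_value(f1, pts), field_value(f2, pts))
  ok <- is.finite(vu) & is.finite(vmin)
  expect_lt(max(abs(vu[ok] - vmin[ok])), sqrt(sum(lv$spacing^2)))
})

test_that("spatial index queries equal exhaustive search", {
  set.seed(44)
  ff <- contact_fixture()
  shell <- ff$frags[["1"]]$shell
  idx <- build_spatial_index(shell)
  pts <- cbind(shell$x, shell$y, shell$z)
  for (i in 1:60) {
    centre <- runif(3, min = apply(pts, 2, min) - 2,
                    max = apply(pts, 2, max) + 2)
    r <- runif(1, 0.2, 4)
    expect_identical(radius_query(idx, centre, r),
                     oracle_radius(pts, shell$point_id, centre, r))
    nn <- nn_query(idx, centre)
    onn <- oracle_nn(pts, shell$point_id, centre)
    expect_equal(nn$point_id, onn$point_id)
    expect_equal(nn$distance, onn$distance, tolerance = 1e-12)
  }
  # empty radius
  expect_identical(radius_query(idx, apply(pts, 2, min) - 50, 0.5), integer(0))
  # tiny shell
  tiny <- shell[1:3, ]
  ti <- build_spatial_index(tiny)
  expect_equal(nn_query(ti, c(0, 0, 0))$point_id,
               oracle_nn(pts[1:3, ], tiny$point_id, c(0, 0, 0))$point_id)
})

test_that("nearest_within matches exhaustive search with ties to lowest row", {
  set.seed(45)
  A <- matrix(runif(90, 0, 10), ncol = 3)
  B <- matrix(runif(150, 0, 10), ncol = 3)
  res <- nearest_within(A, B, 3)
  for (i in seq_len(nrow(A))) {
    d <- sqrt(rowSums(sweep(B, 2, A[i, ], "-")^2))
    if (min(d) <= 3) {
      expect_equal(res$index[i], which.min(d))
      expect_equal(res$distance[i], min(d), tolerance = 1e-12)
    } else {
      expect_true(is.na(res$index[i]))
    }
  }
})
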