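#' Snap-to-fit: painted fracture surfaces and attraction forces
#'
#' Precision alignment aid for mating fracture surfaces. The user paints the
#' fracture surface of each fragment with a spherical brush; only painted
#' shell points enter the attraction model, which prevents a fragment from
#' snapping to plausible-looking but wrong regions. Each marked point of the
#' moving fragment is paired with its nearest marked point on the target
#' within a capture radius, and the pair attracts with a linear spring
#' scaled by the colinearity of the two outward surface normals:
#' `w = max(0, -n_moving . n_target)^p`. Mating fracture faces have opposing
#' outward normals, so well-matching surfaces attract strongly (w near 1)
#' while same-facing or unrelated surfaces contribute nothing. Damped
#' descent on the attraction wrench (plus, optionally, the contact wrench)
#' pulls the fragment into the closest locally stable fit.
#'
#' @name snap-to-fit
NULL

#' A painted subset of a fragment's shell
#'
#' @param fragment_label Fragment label.
#' @param marked_ids Integer `point_id`s of the painted shell points.
#' @export
marked_surface <- function(fragment_label, marked_ids = integer(0)) {
  structure(list(fragment_label = as.integer(fragment_label),
                 marked_ids = sort(unique(as.integer(marked_ids)))),
            class = "marked_surface")
}

#' @export
print.marked_surface <- function(x, ...) {
  cat(sprintf("<marked_surface> fragment %d, %d marked point(s)\n",
              x$fragment_label, length(x$marked_ids)))
  invisible(x)
}

#' Snap-to-fit parameters
#'
#' @param k_a Attraction stiffness per pair, N/mm.
#' @param capture_radius Maximum pairing distance, mm (default 5).
#' @param colinearity_exponent Exponent `p >= 1` sharpening the normal
#'   colinearity weight (default 2).
#' @param max_iters Descent iteration cap.
#' @param tol Convergence tolerance on the equivalent pose increment
#'   (mm and rad).
#' @param contact_enabled Include the contact wrench against the target
#'   during descent (default FALSE: voxelized distance-field surfaces of
#'   two mating fragments overlap by a fraction of a voxel, so a penalty
#'   contact during snapping biases the equilibrium outward by that
#'   overlap; resolve residual contact afterwards with
#'   [step_quasistatic()] if needed).
#' @export
snap_params <- function(k_a = 1, capture_radius = 5, colinearity_exponent = 2,
                        max_iters = 500, tol = 1e-4, contact_enabled = FALSE) {
  stopifnot(k_a > 0, capture_radius > 0, colinearity_exponent >= 1,
            max_iters >= 1, tol > 0)
  structure(list(k_a = k_a, capture_radius = capture_radius,
                 colinearity_exponent = colinearity_exponent,
                 max_iters = as.integer(max_iters), tol = tol,
                 contact_enabled = isTRUE(contact_enabled)),
            class = "snap_params")
}

#' Paint a fracture surface with a spherical brush
#'
#' Marks every shell point whose world position lies within `brush_radius`
#' of any cursor path point. Painting is idempotent and cumulative: pass a
#' previous `marked_surface` via `existing` to extend it.
#'
#' @param frag A `fragment`.
#' @param cursor_path `N x 3` matrix of world points, mm (or length-3
#'   vector).
#' @param brush_radius Brush radius, mm.
#' @param existing Optional `marked_surface` to extend.
#' @return A `marked_surface`.
#' @export
paint_surface <- function(frag, cursor_path, brush_radius, existing = NULL) {
  stopifnot(inherits(frag, "fragment"), brush_radius > 0)
  if (is.null(dim(cursor_path))) cursor_path <- matrix(cursor_path, nrow = 1)
  stopifnot(nrow(cursor_path) >= 1)
  world <- fragment_world_points(frag)
  nw <- nearest_within(world, cursor_path, brush_radius)
  ids <- frag$shell$point_id[!is.na(nw$index)]
  if (!is.null(existing)) {
    stopifnot(inherits(existing, "marked_surface"),
              existing$fragment_label == frag$label)
    ids <- union(existing$marked_ids, ids)
  }
  marked_surface(frag$label, ids)
}

#' Normal-colinearity weight of a candidate pair
#'
#' `w = max(0, -n_moving . n_target)^p`: 1 for exactly opposing outward
#' normals (mating faces), 0 for parallel same-direction or perpendicular
#' normals.
#'
#' @param n_moving,n_target Unit normals (length-3, or `N x 3` matrices).
#' @param p Exponent `>= 1`.
#' @return Scalar (or vector) in `[0, 1]`.
#' @export
colinearity_weight <- function(n_moving, n_target, p = 2) {
  if (is.null(dim(n_moving))) n_moving <- matrix(n_moving, nrow = 1)
  if (is.null(dim(n_target))) n_target <- matrix(n_target, nrow = 1)
  w <- pmax(0, -rowSums(n_moving * n_target))^p
  if (length(w) == 1L) as.numeric(w) else w
}

.marked_rows <- function(frag, ms) {
  stopifnot(inherits(ms, "marked_surface"), ms$fragment_label == frag$label)
  match(ms$marked_ids, frag$shell$point_id)
}

#' Attraction wrench between painted fracture surfaces
#'
#' Pairs each marked moving point with its nearest marked target point
#' within the capture radius (ties to the lowest target `point_id`); each
#' pair pulls with force `k_a * w * (target - moving)` where `w` is the
#' colinearity weight of the pair's world normals. The wrench is summed
#' about the moving fragment's world centroid. `similarity` is the mean
#' weight over pairs (0 with no pairs). Unmarked points never contribute.
#'
#' @param moving,target `fragment`s.
#' @param ms_moving,ms_target `marked_surface`s of the two fragments.
#' @param sp `snap_params`.
#' @return List: `wrench`, `similarity`, `n_pairs`, `pairs` tibble
#'   (moving_id, target_id, distance, weight).
#' @export
attraction_wrench <- function(moving, target, ms_moving, ms_target, sp) {
  stopifnot(inherits(sp, "snap_params"))
  centroid <- fragment_world_centroid(moving)
  empty <- list(wrench = wrench(point = centroid), similarity = 0,
                n_pairs = 0L,
                pairs = tibble::tibble(moving_id = integer(),
                                       target_id = integer(),
                                       distance = numeric(),
                                       weight = numeric()))
  if (length(ms_moving$marked_ids) == 0L || length(ms_target$marked_ids) == 0L) {
    rlang::warn("empty marking: attraction wrench is zero",
                .frequency = "once", .frequency_id = "fragreduce_empty_marking")
    return(empty)
  }
  mi <- .marked_rows(moving, ms_moving)
  ti <- .marked_rows(target, ms_target)
  xm <- fragment_world_points(moving)[mi, , drop = FALSE]
  nm <- fragment_world_normals(moving)[mi, , drop = FALSE]
  xt <- fragment_world_points(target)[ti, , drop = FALSE]
  nt <- fragment_world_normals(target)[ti, , drop = FALSE]
  nw <- nearest_within(xm, xt, sp$capture_radius)
  ok <- !is.na(nw$index)
  if (!any(ok)) return(empty)
  j <- nw$index[ok]
  w <- colinearity_weight(nm[ok, , drop = FALSE], nt[j, , drop = FALSE],
                          p = sp$colinearity_exponent)
  delta <- xt[j, , drop = FALSE] - xm[ok, , drop = FALSE]
  f <- sp$k_a * w * delta
  r <- sweep(xm[ok, , drop = FALSE], 2, centroid, "-")
  tq <- cbind(r[, 2] * f[, 3] - r[, 3] * f[, 2],
              r[, 3] * f[, 1] - r[, 1] * f[, 3],
              r[, 1] * f[, 2] - r[, 2] * f[, 1])
  pairs <- tibble::tibble(
    moving_id = ms_moving$marked_ids[ok],
    target_id = ms_target$marked_ids[j],
    distance = nw$distance[ok],
    weight = as.numeric(w))
  list(wrench = wrench(colSums(f), colSums(tq), centroid),
       similarity = mean(w), n_pairs = sum(ok), pairs = pairs)
}

#' Snap a fragment to the closest stable fit
#'
#' Damped descent on the attraction wrench between the painted surfaces
#' (plus the contact wrench against the target when
#' `sp$contact_enabled`), starting from `start`. Pairing is recomputed
#' every iteration. Terminates when the equivalent pose increment drops
#' below `sp$tol` (converged) or at `sp$max_iters`; non-convergence never
#' raises, it is reported in the result.
#'
#' @param moving A `fragment`.
#' @param target A `fragment`, or a list of fragments to snap against
#'   simultaneously (e.g. the already-placed members of a group): the
#'   attraction model is additive over targets, so a fragment mating with
#'   several placed neighbours is constrained by all its interfaces at
#'   once.
#' @param ms_moving `marked_surface` of the moving fragment.
#' @param ms_target `marked_surface`, or a list of them matching `target`.
#' @param start Starting pose for the moving fragment (default: its current
#'   pose).
#' @param sp `snap_params`.
#' @param cp `coupling_params` (supplies `k_c` for the contact term).
#' @return A `snap_result`: `final_pose`, `converged`, `similarity`,
#'   `iterations`, `residual_rms` (mm over paired points at the final
#'   pose), `n_pairs`.
#' @export
snap_to_fit <- function(moving, target, ms_moving, ms_target,
                        start = moving$pose, sp = snap_params(),
                        cp = coupling_params()) {
  stopifnot(inherits(sp, "snap_params"), inherits(cp, "coupling_params"))
  if (inherits(target, "fragment")) target <- list(target)
  if (inherits(ms_target, "marked_surface")) ms_target <- list(ms_target)
  stopifnot(length(target) == length(ms_target))
  pose <- start
  converged <- FALSE
  iter <- 0L
  # targets never move during a snap: precompute their marked points and
  # normals in world coordinates, and the moving marked subset in local
  mi <- .marked_rows(moving, ms_moving)
  xt <- NULL; nt <- NULL
  for (ii in seq_along(target)) {
    tr <- .marked_rows(target[[ii]], ms_target[[ii]])
    if (length(tr) == 0L) next
    xt <- rbind(xt, apply_transform(
      target[[ii]]$pose, shell_points(target[[ii]]$shell)[tr, , drop = FALSE]))
    nt <- rbind(nt, rotate_vectors(
      target[[ii]]$pose, shell_normals(target[[ii]]$shell)[tr, , drop = FALSE]))
  }
  have_marks <- length(mi) > 0 && !is.null(xt)
  if (have_marks) {
    pm_local <- shell_points(moving$shell)[mi, , drop = FALSE]
    nm_local <- shell_normals(moving$shell)[mi, , drop = FALSE]
  }
  similarity <- 0
  n_pairs <- 0L
  residual_rms <- NA_real_
  repeat {
    iter <- iter + 1L
    centroid <- apply_transform(pose, moving$centroid)
    force <- c(0, 0, 0); torque <- c(0, 0, 0)
    k_eff_t <- 0; k_eff_r <- 0
    n_pairs <- 0L
    if (have_marks) {
      xm <- apply_transform(pose, pm_local)
      nm <- rotate_vectors(pose, nm_local)
      nw <- nearest_within(xm, xt, sp$capture_radius)
      ok <- !is.na(nw$index)
      n_pairs <- sum(ok)
      if (n_pairs > 0L) {
        j <- nw$index[ok]
        w <- colinearity_weight(nm[ok, , drop = FALSE], nt[j, , drop = FALSE],
                                p = sp$colinearity_exponent)
        delta <- xt[j, , drop = FALSE] - xm[ok, , drop = FALSE]
        f <- sp$k_a * w * delta
        r <- sweep(xm[ok, , drop = FALSE], 2, centroid, "-")
        force <- colSums(f)
        torque <- colSums(cbind(r[, 2] * f[, 3] - r[, 3] * f[, 2],
                                r[, 3] * f[, 1] - r[, 1] * f[, 3],
                                r[, 1] * f[, 2] - r[, 2] * f[, 1]))
        k_eff_t <- sp$k_a * sum(w)
        k_eff_r <- sp$k_a * sum(w * rowSums(r^2))
        similarity <- mean(w)
        residual_rms <- sqrt(mean(nw$distance[ok]^2))
      } else {
        similarity <- 0
        residual_rms <- NA_real_
      }
    }
    nc <- 0L
    if (sp$contact_enabled) {
      frag <- moving; frag$pose <- pose
      ct <- contact_wrench(frag, target, k_c = cp$k_c)
      force <- force + ct$wrench$force
      torque <- torque + ct$wrench$torque
      nc <- nrow(ct$contacts)
      if (nc) {
        cr2 <- sum((ct$contacts$px - centroid[1])^2 +
                     (ct$contacts$py - centroid[2])^2 +
                     (ct$contacts$pz - centroid[3])^2)
        k_eff_t <- k_eff_t + cp$k_c * nc
        k_eff_r <- k_eff_r + cp$k_c * cr2
      }
    }
    if (n_pairs == 0L && nc == 0L) break   # nothing within reach
    k_eff_t <- max(k_eff_t, 1e-9)
    k_eff_r <- max(k_eff_r, 1e-9)
    dt_mag <- sqrt(sum(force^2)) / k_eff_t
    dr_mag <- sqrt(sum(torque^2)) / k_eff_r
    if (dt_mag <= sp$tol && dr_mag <= sp$tol) {
      converged <- TRUE
      break
    }
    if (iter >= sp$max_iters) break
    pose <- .descent_update(pose, centroid, force, torque, k_eff_t, k_eff_r,
                            cp$step_scale)
  }
  structure(list(final_pose = pose, converged = converged,
                 similarity = similarity,
                 iterations = iter, residual_rms = residual_rms,
                 n_pairs = n_pairs),
            class = "snap_result")
}

#' @export
print.snap_result <- function(x, ...) {
  cat(sprintf(
    "<snap_result> %s in %d iteration(s), similarity %.3f, residual RMS %.3g mm (%d pairs)\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$similarity, x$residual_rms, x$n_pairs))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a snap result
#'
#' One row per quantity a downstream table wants: final pose flattened plus
#' the diagnostics.
#'
#' @param x A `snap_result`.
#' @param ... Unused.
#' @export
tidy.snap_result <- function(x, ...) {
  tibble::tibble(
    qw = x$final_pose$q[1], qx = x$final_pose$q[2],
    qy = x$final_pose$q[3], qz = x$final_pose$q[4],
    tx = x$final_pose$t[1], ty = x$final_pose$t[2], tz = x$final_pose$t[3],
    converged = x$converged, similarity = x$similarity,
    iterations = x$iterations, residual_rms = x$residual_rms,
    n_pairs = x$n_pairs)
}

#' One-row summary of a snap result
#' @inheritParams tidy.snap_result
#' @export
glance.snap_result <- function(x, ...) {
  tibble::tibble(converged = x$converged, similarity = x$similarity,
                 iterations = x$iterations, residual_rms = x$residual_rms,
                 n_pairs = x$n_pairs)
}
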