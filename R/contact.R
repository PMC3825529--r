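#' Six-DOF contact and the static virtual coupling
#'
#' Contact between the manipulated (moving) fragment and the static
#' fragments is a penalty model on the precomputed structures: every shell
#' point of the moving fragment is tested against each static fragment's
#' signed distance field; a point at (interpolated) field value `-d < 0`
#' contributes a force `k_c * d * n` along the static field's normalised
#' gradient. Forces and torques are summed about the moving fragment's world
#' centroid.
#'
#' The handle is coupled to the manipulated fragment by a static virtual
#' coupling: a translational spring `k_t` and a rotational spring `k_r`.
#' Because the coupling is static (no device dynamics), the fragment pose is
#' the quasi-static equilibrium of coupling plus contact wrenches, tracked by
#' damped first-order descent. In free space the fixed point is the handle
#' pose; pressed against an obstacle the fragment rests on the surface with
#' a penetration bounded by `k_t / k_c` times the spring stretch, which is
#' what makes the manipulated fragment stop at another fragment's surface
#' instead of passing through it.
#'
#' @name contact-dynamics
NULL

#' Coupling / stepping parameters
#'
#' @param k_t Translational spring stiffness, N/mm.
#' @param k_r Rotational spring stiffness, N.mm/rad.
#' @param k_c Contact penalty stiffness per shell point, N/mm. The ratio
#'   `k_c / k_t` (default 50) controls the penetration bound; absolute
#'   values only scale the reported wrenches.
#' @param step_scale Damped-descent step fraction in (0, 1].
#' @param max_iters Iteration cap per quasi-static step.
#' @param tol Convergence tolerance on the equivalent pose residual:
#'   `|F| / k_t` in mm and `|T| / k_r` in rad must both fall below `tol`.
#' @export
coupling_params <- function(k_t = 1, k_r = 20, k_c = 50 * k_t,
                            step_scale = 0.5, max_iters = 400, tol = 1e-4) {
  stopifnot(k_t > 0, k_r > 0, k_c > 0, tol > 0,
            step_scale > 0, step_scale <= 1, max_iters >= 1)
  structure(list(k_t = k_t, k_r = k_r, k_c = k_c, step_scale = step_scale,
                 max_iters = as.integer(max_iters), tol = tol),
            class = "coupling_params")
}

.empty_contacts <- function() {
  tibble::tibble(point_id = integer(), static_label = integer(),
                 penetration = numeric(),
                 px = numeric(), py = numeric(), pz = numeric(),
                 nx = numeric(), ny = numeric(), nz = numeric())
}

#' Contact wrench on the moving fragment
#'
#' @param moving A `fragment` (the manipulated body).
#' @param statics List of `fragment`s it may collide with.
#' @param k_c Penalty stiffness per shell point, N/mm.
#' @param prune Use bounding-volume pruning (default). With `prune = FALSE`
#'   every shell point is evaluated against every static field; results are
#'   identical, this switch exists so the pruned path can be checked against
#'   the exhaustive one.
#' @return A `contact_result`: `wrench` (about the moving world centroid),
#'   `max_penetration` (mm), `contacts` tibble (point_id, static_label,
#'   penetration, world position `px..pz`, world normal `nx..nz`).
#' @export
contact_wrench <- function(moving, statics, k_c = 50, prune = TRUE) {
  stopifnot(inherits(moving, "fragment"))
  x_world <- fragment_world_points(moving)
  centroid <- fragment_world_centroid(moving)
  contacts <- .empty_contacts()
  for (st in statics) {
    stopifnot(inherits(st, "fragment"))
    if (identical(st$label, moving$label)) next
    inv <- transform_inverse(st$pose)
    x_local <- apply_transform(inv, x_world)
    rows <- seq_len(nrow(x_local))
    if (prune) {
      b <- field_bounds(st$field)
      inside <- x_local[, 1] >= b$lo[1] & x_local[, 1] <= b$hi[1] &
        x_local[, 2] >= b$lo[2] & x_local[, 2] <= b$hi[2] &
        x_local[, 3] >= b$lo[3] & x_local[, 3] <= b$hi[3]
      rows <- rows[inside]
    }
    if (length(rows) == 0L) next
    v <- field_value(st$field, x_local[rows, , drop = FALSE])
    pen_rows <- rows[v < 0]
    if (length(pen_rows) == 0L) next
    d <- -v[v < 0]
    g <- field_gradient(st$field, x_local[pen_rows, , drop = FALSE])
    g <- g / pmax(sqrt(rowSums(g^2)), 1e-12)
    n_world <- rotate_vectors(st$pose, g)
    contacts <- dplyr::bind_rows(contacts, tibble::tibble(
      point_id = moving$shell$point_id[pen_rows],
      static_label = st$label,
      penetration = d,
      px = x_world[pen_rows, 1], py = x_world[pen_rows, 2],
      pz = x_world[pen_rows, 3],
      nx = n_world[, 1], ny = n_world[, 2], nz = n_world[, 3]))
  }
  w <- .contacts_to_wrench(contacts, k_c, centroid)
  structure(list(wrench = w,
                 max_penetration = if (nrow(contacts)) max(contacts$penetration) else 0,
                 contacts = contacts),
            class = "contact_result")
}

.contacts_to_wrench <- function(contacts, k_c, centroid) {
  if (nrow(contacts) == 0L) return(wrench(point = centroid))
  f <- k_c * contacts$penetration * cbind(contacts$nx, contacts$ny, contacts$nz)
  r <- cbind(contacts$px - centroid[1], contacts$py - centroid[2],
             contacts$pz - centroid[3])
  tq <- cbind(r[, 2] * f[, 3] - r[, 3] * f[, 2],
              r[, 3] * f[, 1] - r[, 1] * f[, 3],
              r[, 1] * f[, 2] - r[, 2] * f[, 1])
  wrench(colSums(f), colSums(tq), centroid)
}

#' @export
print.contact_result <- function(x, ...) {
  cat(sprintf("<contact_result> %d contact(s), max penetration %.4g mm\n",
              nrow(x$contacts), x$max_penetration))
  print(x$wrench)
  invisible(x)
}

#' Virtual-coupling wrench between handle and fragment pose
#'
#' Force `k_t * (handle_t - fragment_t)`; torque `k_r` times the
#' shortest-arc axis-angle of the relative rotation fragment -> handle,
#' about the fragment's world centroid.
#'
#' @param handle,fragment_pose `rigid_transform`s.
#' @param p `coupling_params`.
#' @param centroid Fragment world centroid, mm (torque reference point).
#' @return A `wrench`.
#' @export
coupling_wrench <- function(handle, fragment_pose, p,
                            centroid = fragment_pose$t) {
  stopifnot(is_rigid_transform(handle), is_rigid_transform(fragment_pose))
  force <- p$k_t * (handle$t - fragment_pose$t)
  q_rel <- quat_multiply(handle$q, quat_conjugate(fragment_pose$q))
  torque <- p$k_r * quat_to_rotvec(q_rel)
  wrench(force, torque, centroid)
}

# One damped descent update of a pose under a wrench about `centroid`,
# using effective stiffnesses for step scaling. `contact_normal` (unit)
# splits the translational damping: the contact penalty only stiffens the
# normal direction, so tangential motion keeps the soft spring scale and
# the fragment can slide along a surface at full speed.
.descent_update <- function(pose, centroid, force, torque, k_eff_t, k_eff_r,
                            step_scale, k_t_tan = k_eff_t,
                            contact_normal = NULL) {
  if (!is.null(contact_normal)) {
    f_n <- sum(force * contact_normal) * contact_normal
    dt <- step_scale * (f_n / k_eff_t + (force - f_n) / k_t_tan)
  } else {
    dt <- step_scale * force / k_eff_t
  }
  rotvec <- step_scale * torque / k_eff_r
  dq <- quat_from_rotvec(rotvec)
  new_q <- quat_multiply(dq, pose$q)
  new_t <- as.numeric(quat_to_matrix(dq) %*% (pose$t - centroid)) + centroid + dt
  rigid_transform(new_q, new_t)
}

#' One quasi-static step: track the handle against contacts
#'
#' Iterates damped descent on the total wrench (coupling + contact) until
#' the equivalent pose residual (`|F|/k_t` mm, `|T|/k_r` rad) drops below
#' `p$tol` or `p$max_iters` is reached. Never raises on non-convergence: the
#' best pose found is returned with `converged = FALSE`.
#'
#' @param handle Handle `rigid_transform`.
#' @param moving A `fragment` (its `pose` is the starting point).
#' @param statics List of static `fragment`s.
#' @param p `coupling_params`.
#' @return List: `fragment` (pose updated), `contact` (`contact_result` at
#'   the final pose), `converged`, `iterations`.
#' @export
step_quasistatic <- function(handle, moving, statics, p) {
  stopifnot(inherits(p, "coupling_params"))
  pose <- moving$pose
  converged <- FALSE
  iter <- 0L
  ct <- NULL
  repeat {
    iter <- iter + 1L
    frag <- moving; frag$pose <- pose
    centroid <- fragment_world_centroid(frag)
    ct <- contact_wrench(frag, statics, k_c = p$k_c)
    cw <- coupling_wrench(handle, pose, p, centroid = centroid)
    force <- cw$force + ct$wrench$force
    torque <- cw$torque + ct$wrench$torque
    if (sqrt(sum(force^2)) / p$k_t <= p$tol &&
        sqrt(sum(torque^2)) / p$k_r <= p$tol) {
      converged <- TRUE
      break
    }
    if (iter >= p$max_iters) break
    nc <- nrow(ct$contacts)
    r2 <- if (nc) sum((ct$contacts$px - centroid[1])^2 +
                        (ct$contacts$py - centroid[2])^2 +
                        (ct$contacts$pz - centroid[3])^2) else 0
    k_eff_t <- p$k_t + p$k_c * nc
    k_eff_r <- p$k_r + p$k_c * r2
    cn <- NULL
    if (nc) {
      cn <- colSums(p$k_c * ct$contacts$penetration *
                      cbind(ct$contacts$nx, ct$contacts$ny, ct$contacts$nz))
      cnn <- sqrt(sum(cn^2))
      cn <- if (cnn > 1e-12) cn / cnn else NULL
    }
    pose <- .descent_update(pose, centroid, force, torque, k_eff_t, k_eff_r,
                            p$step_scale, k_t_tan = p$k_t, contact_normal = cn)
  }
  moving$pose <- pose
  list(fragment = moving, contact = ct, converged = converged,
       iterations = iter)
}

#' Build a handle trajectory
#'
#' @param times Strictly increasing times, seconds.
#' @param poses List of `rigid_transform`s, same length.
#' @return A `handle_trajectory` tibble with columns `time` and `pose`
#'   (list column).
#' @export
handle_trajectory <- function(times, poses) {
  stopifnot(length(times) == length(poses), all(diff(times) > 0))
  stopifnot(all(vapply(poses, is_rigid_transform, logical(1))))
  tibble::new_tibble(list(time = as.numeric(times), pose = poses),
                     class = "handle_trajectory", nrow = length(times))
}

#' Simulate manipulation along a scripted handle trajectory
#'
#' The offline stand-in for the haptic servo loop: each trajectory sample is
#' one quasi-static step starting from the previous equilibrium. The run is
#' deterministic given its inputs.
#'
#' @param traj A `handle_trajectory`.
#' @param moving A `fragment`.
#' @param statics List of static `fragment`s.
#' @param p `coupling_params`.
#' @return A `simulation_log` tibble: `step`, `time`, `pose` (list column),
#'   `force_mag` (N), `torque_mag` (N.mm), `max_penetration` (mm),
#'   `n_contacts`, `converged`, `iterations`; the final fragment is in
#'   `attr(, "fragment")` and the run-wide max penetration in
#'   `attr(, "max_penetration")`.
#' @export
simulate_manipulation <- function(traj, moving, statics, p) {
  stopifnot(inherits(traj, "handle_trajectory"))
  n <- nrow(traj)
  rows <- vector("list", n)
  frag <- moving
  for (i in seq_len(n)) {
    st <- step_quasistatic(traj$pose[[i]], frag, statics, p)
    frag <- st$fragment
    rows[[i]] <- tibble::tibble(
      step = i, time = traj$time[i], pose = list(frag$pose),
      force_mag = sqrt(sum(st$contact$wrench$force^2)),
      torque_mag = sqrt(sum(st$contact$wrench$torque^2)),
      max_penetration = st$contact$max_penetration,
      n_contacts = nrow(st$contact$contacts),
      converged = st$converged, iterations = st$iterations)
  }
  log <- dplyr::bind_rows(rows)
  class(log) <- c("simulation_log", class(log))
  attr(log, "fragment") <- frag
  attr(log, "max_penetration") <- max(c(0, log$max_penetration))
  log
}

#' Write a simulation log as CSV
#'
#' Flattens the pose list column into quaternion and translation columns.
#'
#' @param log A `simulation_log`.
#' @param path Output CSV path.
#' @export
write_simulation_log <- function(log, path) {
  qm <- do.call(rbind, lapply(log$pose, function(p) c(p$q, p$t)))
  colnames(qm) <- c("qw", "qx", "qy", "qz", "tx", "ty", "tz")
  flat <- dplyr::bind_cols(
    dplyr::select(tibble::as_tibble(log), -"pose"),
    tibble::as_tibble(qm))
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
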