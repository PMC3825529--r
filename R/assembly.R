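#' Scenes, grouping and plan export
#'
#' A scene holds the fragments of one planning session plus any groups and
#' painted markings. Grouping lets fragments that have been positioned
#' relative to one another be manipulated as one rigid unit: a group stores
#' a group pose and, per member, the fixed offset (member local -> group
#' frame) captured at attach time, so creating, attaching to or detaching
#' from a group never moves anything. The completed plan (all poses, groups
#' and markings) round-trips through a versioned JSON file.
#'
#' Contacts between members of the same group are skipped while the group
#' is manipulated: the group moves as one rigid body, so its internal
#' contact state is frozen by construction.
#'
#' @name assembly
NULL

PLAN_FORMAT_VERSION <- "fragreduce-plan-1"

#' Create a scene from fragments
#'
#' @param fragments List of `fragment`s (unique labels).
#' @param provenance Optional named list describing the source volume.
#' @return A `scene`.
#' @export
scene <- function(fragments, provenance = list()) {
  stopifnot(all(vapply(fragments, inherits, logical(1), "fragment")))
  labels <- vapply(fragments, function(f) f$label, integer(1))
  if (anyDuplicated(labels)) stop("duplicate fragment labels", call. = FALSE)
  names(fragments) <- as.character(labels)
  structure(list(fragments = fragments, groups = list(),
                 markings = list(), provenance = provenance,
                 next_group = 1L),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d fragment(s), %d group(s)\n",
              length(x$fragments), length(x$groups)))
  invisible(x)
}

.scene_fragment <- function(sc, label) {
  f <- sc$fragments[[as.character(label)]]
  if (is.null(f)) stop(sprintf("no fragment with label %d", label), call. = FALSE)
  f
}

.group_of <- function(sc, label) {
  for (gid in names(sc$groups)) {
    if (label %in% sc$groups[[gid]]$member_labels) return(gid)
  }
  NULL
}

#' Group fragments into one rigidly co-manipulated unit
#'
#' The group pose starts at identity and each member offset is its current
#' world pose, so creation is motion-free. Fragments already in a group
#' cannot be grouped again.
#'
#' @param sc A `scene`.
#' @param labels Fragment labels (>= 1 of them).
#' @return The updated scene; the new group's id is in
#'   `attr(, "group_id")`.
#' @export
create_group <- function(sc, labels) {
  stopifnot(inherits(sc, "scene"), length(labels) >= 1)
  for (lb in labels) {
    .scene_fragment(sc, lb)
    g <- .group_of(sc, lb)
    if (!is.null(g)) {
      stop(sprintf("fragment %d already belongs to group %s", lb, g),
           call. = FALSE)
    }
  }
  gid <- sprintf("g%d", sc$next_group)
  sc$next_group <- sc$next_group + 1L
  offsets <- lapply(labels, function(lb) .scene_fragment(sc, lb)$pose)
  names(offsets) <- as.character(labels)
  pts <- do.call(rbind, lapply(labels, function(lb) {
    fragment_world_points(.scene_fragment(sc, lb))
  }))
  sc$groups[[gid]] <- list(group_id = gid,
                           member_labels = as.integer(labels),
                           group_pose = transform_identity(),
                           member_offsets = offsets,
                           centroid = colMeans(pts))
  attr(sc, "group_id") <- gid
  sc
}

#' Attach a fragment to an existing group
#'
#' Motion-free: the member offset is computed from the fragment's current
#' world pose and the current group pose.
#'
#' @param sc A `scene`.
#' @param group_id Group id.
#' @param label Fragment label (not yet grouped).
#' @export
attach_fragment <- function(sc, group_id, label) {
  g <- sc$groups[[group_id]]
  if (is.null(g)) stop(sprintf("no group %s", group_id), call. = FALSE)
  other <- .group_of(sc, label)
  if (!is.null(other)) {
    stop(sprintf("fragment %d already belongs to group %s (cannot attach to %s)",
                 label, other, group_id), call. = FALSE)
  }
  frag <- .scene_fragment(sc, label)
  g$member_labels <- c(g$member_labels, as.integer(label))
  g$member_offsets[[as.character(label)]] <-
    compose(transform_inverse(g$group_pose), frag$pose)
  sc$groups[[group_id]] <- g
  sc
}

#' Detach a fragment from its group
#'
#' The fragment keeps its current world pose (no snap-back).
#'
#' @inheritParams attach_fragment
#' @export
detach_fragment <- function(sc, group_id, label) {
  g <- sc$groups[[group_id]]
  if (is.null(g)) stop(sprintf("no group %s", group_id), call. = FALSE)
  if (!label %in% g$member_labels) {
    stop(sprintf("fragment %d is not a member of group %s", label, group_id),
         call. = FALSE)
  }
  g$member_labels <- setdiff(g$member_labels, as.integer(label))
  g$member_offsets[[as.character(label)]] <- NULL
  if (length(g$member_labels) == 0L) {
    sc$groups[[group_id]] <- NULL
  } else {
    sc$groups[[group_id]] <- g
  }
  sc
}

#' Move a group: set its pose and update member world poses
#'
#' Every member's world pose becomes `compose(pose, member_offset)`, so all
#' pairwise relative poses inside the group are preserved exactly.
#'
#' @param sc A `scene`.
#' @param group_id Group id.
#' @param pose New group `rigid_transform`.
#' @export
set_group_pose <- function(sc, group_id, pose) {
  g <- sc$groups[[group_id]]
  if (is.null(g)) stop(sprintf("no group %s", group_id), call. = FALSE)
  stopifnot(is_rigid_transform(pose))
  g$group_pose <- pose
  for (lb in g$member_labels) {
    key <- as.character(lb)
    sc$fragments[[key]]$pose <- compose(pose, g$member_offsets[[key]])
  }
  sc$groups[[group_id]] <- g
  sc
}

#' A group as a single rigid body for contact simulation
#'
#' Builds a pseudo-fragment whose shell is the union of the member shells
#' expressed in the group frame and whose pose is the group pose; its
#' centroid is the group centroid captured at creation. Manipulating this
#' body through the contact/coupling machinery and then applying the
#' resulting pose via [set_group_pose()] moves every member consistently.
#'
#' @param sc A `scene`.
#' @param group_id Group id.
#' @return A `fragment` (label 0 = composite; it carries the first member's
#'   field only for shape compatibility, contact queries use the statics'
#'   fields).
#' @export
group_body <- function(sc, group_id) {
  g <- sc$groups[[group_id]]
  if (is.null(g)) stop(sprintf("no group %s", group_id), call. = FALSE)
  inv <- transform_inverse(g$group_pose)
  shells <- lapply(g$member_labels, function(lb) {
    frag <- .scene_fragment(sc, lb)
    world <- fragment_world_points(frag)
    nrm <- fragment_world_normals(frag)
    pts <- apply_transform(inv, world)
    nl <- rotate_vectors(inv, nrm)
    tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                   nx = nl[, 1], ny = nl[, 2], nz = nl[, 3])
  })
  sh <- dplyr::bind_rows(shells)
  sh <- dplyr::bind_cols(tibble::tibble(point_id = seq_len(nrow(sh))), sh)
  class(sh) <- c("point_shell", class(sh))
  centroid_group <- apply_transform(inv, g$centroid)
  fragment(0L, sh, .scene_fragment(sc, g$member_labels[1])$field,
           pose = g$group_pose, centroid = centroid_group)
}

#' Export a plan to JSON
#'
#' Writes a versioned JSON file holding every fragment pose, all groups and
#' all markings at full floating-point precision.
#'
#' @param sc A `scene`.
#' @param path Output path.
#' @export
export_plan <- function(sc, path) {
  stopifnot(inherits(sc, "scene"))
  plan <- list(
    version = PLAN_FORMAT_VERSION,
    provenance = sc$provenance,
    fragments = lapply(unname(sc$fragments), function(f) {
      list(label = f$label, pose = transform_to_json(f$pose))
    }),
    groups = lapply(unname(sc$groups), function(g) {
      list(group_id = g$group_id,
           member_labels = g$member_labels,
           group_pose = transform_to_json(g$group_pose),
           centroid = g$centroid,
           member_offsets = lapply(g$member_offsets, transform_to_json))
    }),
    markings = lapply(sc$markings, function(ms) {
      list(fragment = ms$fragment_label, marked_ids = ms$marked_ids)
    })
  )
  jsonlite::write_json(plan, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a plan and apply it to a scene
#'
#' Reapplies the stored fragment poses, groups and markings. The file must
#' carry the expected format version; a truncated or malformed file raises
#' a parse error with context.
#'
#' @param sc A `scene` holding the same fragment labels the plan refers to.
#' @param path Plan JSON path.
#' @return The updated scene.
#' @export
import_plan <- function(sc, path) {
  stopifnot(inherits(sc, "scene"))
  plan <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) {
      stop(sprintf("cannot parse plan file '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (!identical(plan$version, PLAN_FORMAT_VERSION)) {
    stop(sprintf("plan version mismatch: file has '%s', expected '%s'",
                 plan$version %||% "<missing>", PLAN_FORMAT_VERSION),
         call. = FALSE)
  }
  for (fr in plan$fragments) {
    key <- as.character(fr$label)
    if (is.null(sc$fragments[[key]])) {
      stop(sprintf("plan refers to unknown fragment %s", key), call. = FALSE)
    }
    sc$fragments[[key]]$pose <- transform_from_json(fr$pose)
  }
  sc$groups <- list()
  maxg <- 0L
  for (g in plan$groups) {
    offsets <- lapply(g$member_offsets, transform_from_json)
    sc$groups[[g$group_id]] <- list(
      group_id = g$group_id,
      member_labels = as.integer(unlist(g$member_labels)),
      group_pose = transform_from_json(g$group_pose),
      member_offsets = offsets,
      centroid = as.numeric(unlist(g$centroid)))
    maxg <- max(maxg, as.integer(sub("^g", "", g$group_id)))
  }
  sc$next_group <- maxg + 1L
  sc$markings <- lapply(plan$markings, function(m) {
    marked_surface(m$fragment, as.integer(unlist(m$marked_ids)))
  })
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-fragment reduction error against ground truth
#'
#' Translation error is the displacement of the fragment centroid between
#' the scene pose and the truth pose; rotation error is the shortest-arc
#' angle between the two orientations, in degrees.
#'
#' @param sc A `scene`.
#' @param truth Named list (by fragment label) of ground-truth
#'   `rigid_transform`s; must cover every fragment in the scene.
#' @return A `reduction_report` tibble: `label`, `trans_err_mm`,
#'   `rot_err_deg`, with RMS aggregates in `attr(, "rms_trans_mm")` /
#'   `attr(, "rms_rot_deg")` and via [glance.reduction_report()].
#' @export
reduction_report <- function(sc, truth) {
  stopifnot(inherits(sc, "scene"))
  labels <- as.integer(names(sc$fragments))
  missing <- setdiff(as.character(labels), names(truth))
  if (length(missing)) {
    stop(sprintf("truth poses missing for label(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- purrr::map(labels, function(lb) {
    frag <- sc$fragments[[as.character(lb)]]
    err <- pose_error(frag$pose, truth[[as.character(lb)]],
                      point = frag$centroid)
    tibble::tibble(label = lb, trans_err_mm = err[["trans_mm"]],
                   rot_err_deg = err[["rot_deg"]])
  })
  rep <- dplyr::bind_rows(rows)
  class(rep) <- c("reduction_report", class(rep))
  attr(rep, "rms_trans_mm") <- sqrt(mean(rep$trans_err_mm^2))
  attr(rep, "rms_rot_deg") <- sqrt(mean(rep$rot_err_deg^2))
  rep
}

#' One-row summary of a reduction report
#' @param x A `reduction_report`.
#' @param ... Unused.
#' @export
glance.reduction_report <- function(x, ...) {
  tibble::tibble(n_fragments = nrow(x),
                 rms_trans_mm = attr(x, "rms_trans_mm"),
                 rms_rot_deg = attr(x, "rms_rot_deg"),
                 max_trans_mm = max(x$trans_err_mm),
                 max_rot_deg = max(x$rot_err_deg))
}
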