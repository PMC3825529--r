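#' End-to-end reduction workflows
#'
#' Convenience compositions of the package's building blocks: CT-style
#' segmentation (threshold, small-component filter, labeling) and the full
#' phantom closure loop — segment the rendered phantom volume, rebuild the
#' fragments, snap each one onto the growing assembly from a coarse start,
#' group the result, and score it against the stored ground truth.
#'
#' @name pipelines
NULL

#' Segment a bone volume into labeled fragments
#'
#' Threshold, remove components below `min_size` voxels, label the rest.
#'
#' @param v An `intensity_volume`.
#' @param threshold Bone intensity threshold (no universal default exists;
#'   calibrate per scanner protocol).
#' @param min_size Minimum component size in voxels (default 100).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A `labeled_volume`.
#' @export
segment_volume <- function(v, threshold, min_size = 100, connectivity = 26) {
  stopifnot(inherits(v, "intensity_volume"))
  mask <- threshold_bone(v, threshold)
  mask <- remove_small_components(mask, min_size = min_size,
                                  connectivity = connectivity)
  label_components(mask, connectivity = connectivity,
                   spacing = v$spacing, origin = v$origin)
}

#' Reassemble a phantom from its rendered volume
#'
#' The closure loop of the toolkit: segment the phantom's rendered
#' intensity volume, rebuild per-fragment distance fields and shells,
#' anchor the largest fragment at its ground-truth pose, then snap every
#' other fragment onto the already-placed assembly starting from a coarse
#' misalignment (`offset_mm`, `offset_deg` from its true pose), group the
#' placed fragments, and report per-fragment pose errors versus the stored
#' truth.
#'
#' @param pt A `phantom_truth`.
#' @param threshold Bone threshold applied to the rendered volume
#'   (default 300; the renderer draws bone at 700 against soft tissue
#'   at 40).
#' @param offset_mm,offset_deg Coarse-start misalignment magnitudes
#'   (defaults 2 mm, 5 degrees).
#' @param sp `snap_params` for the alignment.
#' @param cp `coupling_params` for the descent stepping (default uses
#'   `step_scale = 0.8`, appropriate for attraction-dominated descent).
#' @param seed Seed for the coarse-start directions.
#' @return A list: `scene` (placed fragments, grouped), `report`
#'   (`reduction_report`), `matches` (segmentation-to-truth label map),
#'   `snaps` (per-fragment `snap_result`s).
#' @export
reassemble_phantom <- function(pt, threshold = 300,
                               offset_mm = 2, offset_deg = 5,
                               sp = snap_params(),
                               cp = coupling_params(step_scale = 0.8),
                               seed = pt$spec$seed) {
  stopifnot(inherits(pt, "phantom_truth"))
  lv <- segment_volume(pt$intensity, threshold)
  matches <- match_labels(pt$labeled, lv)
  if (anyNA(matches$label_b) || anyDuplicated(matches$label_b)) {
    stop("segmentation did not reproduce the phantom fragments one-to-one",
         call. = FALSE)
  }
  # fragments keyed by TRUTH label
  frags <- list()
  for (i in seq_len(nrow(matches))) {
    frags[[as.character(matches$label_a[i])]] <-
      fragment_from_labels(lv, matches$label_b[i])
  }
  for (lb in names(frags)) frags[[lb]]$label <- as.integer(lb)
  mk <- fracture_face_markings(pt, frags)

  sizes <- component_sizes(pt$labeled)
  anchor <- as.character(sizes$label[which.max(sizes$voxels)])
  frags[[anchor]]$pose <- pt$truth_poses[[anchor]]
  placed <- anchor
  remaining <- setdiff(names(frags), anchor)
  snaps <- list()
  # greedy assembly order: always place next the fragment with the largest
  # marked interface to an already-placed fragment
  while (length(remaining)) {
    best <- NULL; best_n <- -1L
    for (i in seq_len(nrow(mk))) {
      pair <- as.character(c(mk$label_a[i], mk$label_b[i]))
      mov <- intersect(pair, remaining)
      tgt <- intersect(pair, placed)
      if (length(mov) != 1L || length(tgt) != 1L) next
      if (mk$n_a[i] + mk$n_b[i] > best_n) {
        best_n <- mk$n_a[i] + mk$n_b[i]
        flip <- as.character(mk$label_a[i]) != mov
        best <- list(lb = mov, tgt = tgt,
                     ma = if (flip) mk$marking_b[[i]] else mk$marking_a[[i]],
                     mb = if (flip) mk$marking_a[[i]] else mk$marking_b[[i]])
      }
    }
    if (is.null(best)) {
      warning(sprintf("fragment(s) %s share no marked cut with the assembly",
                      paste(remaining, collapse = ", ")))
      break
    }
    lb <- best$lb
    truth <- pt$truth_poses[[lb]]
    centre <- apply_transform(truth, frags[[lb]]$centroid)
    start <- perturb_pose(truth, centre, offset_mm, offset_deg,
                          seed = .sub_seed(seed, 31 + as.integer(lb)))
    res <- snap_to_fit(frags[[lb]], frags[[best$tgt]], best$ma, best$mb,
                       start = start, sp = sp, cp = cp)
    frags[[lb]]$pose <- res$final_pose
    snaps[[lb]] <- res
    placed <- c(placed, lb)
    remaining <- setdiff(remaining, lb)
  }
  sc <- scene(unname(frags))
  sc <- create_group(sc, as.integer(placed))
  report <- reduction_report(sc, pt$truth_poses)
  list(scene = sc, report = report, matches = matches, snaps = snaps)
}
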