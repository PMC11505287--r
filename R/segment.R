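#' Segment a dental arch scan
#'
#' Runs the full detect-and-segment pipeline on an occlusion-aligned mesh:
#' for every tooth with finite landmarks, sample the spiral camera
#' trajectory, render depth/normal view sequences, predict binary masks with
#' the recurrent U-Net, and unproject them to faces; then resolve classes by
#' multi-view-certainty region voting and enforce single connected regions
#' by component cleanup. Teeth with sentinel (infinite) landmarks are
#' skipped.
#'
#' @param mesh a \code{tri_mesh} in canonical pose (see
#'   \code{\link{fit_rigid_alignment}}).
#' @param landmarks a \code{landmark_set} in the same coordinates.
#' @param model a trained \code{seg_net}.
#' @param n_views views per tooth.
#' @param camera optional camera overrides for \code{\link{sample_views}}.
#' @param threshold mask probability cutoff. The pipeline default (0.995) is
#'   deliberately precision-biased: under multi-view certainty voting a
#'   pixel over-claimed in a single view irreversibly claims its face, while
#'   under-claimed pixels are recovered by the other views of the spiral, so
#'   the operating point belongs at the precision end of the mask ROC.
#'   (\code{\link{binarize}} keeps the conventional 0.5 default for plain
#'   mask binarization.)
#' @param verbose log per-stage progress.
#' @return list with \code{labels} (final \code{face_labels}),
#'   \code{voted} (pre-cleanup labels), \code{certainty}
#'   (\code{certainty_table}) and \code{report} (per-stage timings and
#'   counts).
#' @export
segment_case <- function(mesh, landmarks, model, n_views = 49L, camera = list(),
                         threshold = 0.995, verbose = FALSE) {
  res <- model$config$resolution
  teeth <- landmark_present(landmarks)
  if (length(teeth) == 0) stop("no teeth with finite landmarks")
  per_tooth <- list()
  timings <- c()
  t0 <- proc.time()[3]
  for (tooth in teeth) {
    pair <- list(landmarks[tooth, 1:3], landmarks[tooth, 4:6])
    poses <- do.call(sample_views, c(list(pair, n = n_views), camera))
    views <- render_sequence(mesh, poses, res)
    out <- forward(model, views, i_tt = tooth_type_signal(tooth))
    masks <- binarize(out$probs, threshold)
    records <- lapply(views, `[[`, "record")
    per_tooth[[tooth]] <- unproject_masks(masks, records, n_faces(mesh))
    if (verbose) {
      log_msg("segment", "tooth %s: %d candidate faces", tooth,
              length(per_tooth[[tooth]]$faces))
    }
  }
  timings["per_tooth"] <- proc.time()[3] - t0
  t0 <- proc.time()[3]
  table <- build_certainty(per_tooth, n_faces(mesh))
  voted <- region_voting(table)
  labels <- cca_cleanup(mesh, voted, table)
  timings["scan_level"] <- proc.time()[3] - t0
  if (verbose) {
    log_msg("segment", "done: %d teeth, %.1fs per-tooth, %.1fs scan-level",
            length(teeth), timings["per_tooth"], timings["scan_level"])
  }
  list(labels = labels, voted = voted, certainty = table,
       report = list(teeth = teeth, timings = timings,
                     n_faces = n_faces(mesh), n_views = n_views))
}

#' Ground-truth round trip through the projection machinery
#'
#' Renders the per-tooth ground-truth masks (instead of network
#' predictions), unprojects, votes and cleans up — measuring how much
#' information the projection/unprojection cycle itself loses.
#'
#' @param case a \code{synthetic_case}.
#' @inheritParams segment_case
#' @return as \code{\link{segment_case}}, plus \code{visible} (list per
#'   tooth of faces seen in at least one of its views).
#' @export
roundtrip_case <- function(case, n_views = 49L, resolution = 256L, camera = list()) {
  mesh <- case$mesh
  teeth <- landmark_present(case$landmarks)
  per_tooth <- list()
  visible <- list()
  for (tooth in teeth) {
    pair <- list(case$landmarks[tooth, 1:3], case$landmarks[tooth, 4:6])
    poses <- do.call(sample_views, c(list(pair, n = n_views), camera))
    views <- render_sequence(mesh, poses, resolution)
    masks <- make_targets(case$labels, tooth, views)
    records <- lapply(views, `[[`, "record")
    per_tooth[[tooth]] <- unproject_masks(masks, records, n_faces(mesh))
    visible[[tooth]] <- which(per_tooth[[tooth]]$visible > 0L)
  }
  table <- build_certainty(per_tooth, n_faces(mesh))
  voted <- region_voting(table)
  labels <- cca_cleanup(mesh, voted, table)
  list(labels = labels, voted = voted, certainty = table, visible = visible)
}

#' Tessellation-robustness harness
#'
#' Evaluates the segmentation pipeline on each case and on tessellation-
#' perturbed copies of its mesh (random vertex displacement, planar flipping
#' optimization, explicit remeshing), with ground-truth labels transported
#' to the perturbed meshes by nearest-face lookup, and reports the per-case
#' mean W-IoU change.
#'
#' @param model a trained \code{seg_net}.
#' @param cases list of \code{synthetic_case}.
#' @param perturbations character subset of \code{c("RVD", "PFO", "ER")}.
#' @param rvd_disp maximum vertex displacement for RVD, mm.
#' @param n_views,camera rendering settings (see \code{\link{segment_case}}).
#' @param seed integer seed for the RVD displacement field.
#' @param relabel how ground truth is carried to the perturbed mesh:
#'   \code{"nearest"} (nearest-face transport; works for any labeled mesh)
#'   or \code{"generator"} (exact analytic relabeling via
#'   \code{\link{synthetic_labels}}; synthetic cases only, free of transport
#'   noise at label boundaries).
#' @return data.frame with one row per case and perturbation: reference
#'   mean W-IoU, perturbed mean W-IoU and \code{delta} (perturbed - reference).
#' @export
robustness_eval <- function(model, cases, perturbations = c("RVD", "PFO", "ER"),
                            rvd_disp = 0.2, n_views = 9L, camera = list(),
                            seed = 1L, relabel = c("nearest", "generator")) {
  relabel <- match.arg(relabel)
  perturbations <- match.arg(perturbations, c("RVD", "PFO", "ER"), several.ok = TRUE)
  rows <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    ref_seg <- segment_case(case$mesh, case$landmarks, model, n_views, camera)
    ref_eval <- evaluate_case(case$mesh, case$labels, ref_seg$labels)
    for (pert in perturbations) {
      pmesh <- switch(pert,
        RVD = perturb_rvd(case$mesh, max_disp = rvd_disp, seed = seed + ci),
        PFO = perturb_pfo(case$mesh),
        ER = perturb_er(case$mesh))
      plabels <- if (relabel == "generator") synthetic_labels(case, pmesh) else
        transfer_labels_nearest(case$mesh, case$labels, pmesh)
      pseg <- segment_case(pmesh, case$landmarks, model, n_views, camera)
      peval <- evaluate_case(pmesh, plabels, pseg$labels)
      rows[[length(rows) + 1L]] <- data.frame(
        case = ci, perturbation = pert,
        wiou_ref = ref_eval$case$mean_wiou,
        wiou_pert = peval$case$mean_wiou,
        delta = peval$case$mean_wiou - ref_eval$case$mean_wiou,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
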