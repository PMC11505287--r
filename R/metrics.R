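#' Area-weighted intersection over union
#'
#' Faces contribute to the IoU by surface area rather than by count, so that
#' unevenly tessellated meshes are scored fairly: the sum of areas of faces
#' carrying class \code{cls} in both labelings divided by the sum of areas
#' of faces carrying it in either. Defined as 1 when the class is absent
#' from both labelings and 0 when absent from exactly one.
#'
#' @param mesh a \code{tri_mesh}.
#' @param gt,pred \code{face_labels} matching the mesh.
#' @param cls a class code.
#' @return scalar in [0, 1].
#' @export
weighted_iou <- function(mesh, gt, pred, cls) {
  stopifnot(length(gt) == n_faces(mesh), length(pred) == n_faces(mesh))
  a <- face_areas(mesh)
  in_gt <- as.character(gt) == cls
  in_pred <- as.character(pred) == cls
  uni <- sum(a[in_gt | in_pred])
  if (uni == 0) return(if (any(in_gt) == any(in_pred)) 1 else 0)
  sum(a[in_gt & in_pred]) / uni
}

#' Hausdorff distance between point sets
#'
#' The maximum over both directions of the largest nearest-neighbour
#' Euclidean distance.
#'
#' @param setA,setB non-empty n x 3 point matrices (mm).
#' @return distance in mm.
#' @export
hausdorff <- function(setA, setB) {
  setA <- matrix(as.numeric(setA), ncol = 3)
  setB <- matrix(as.numeric(setB), ncol = 3)
  if (nrow(setA) == 0 || nrow(setB) == 0) stop("Hausdorff distance of an empty point set is undefined")
  max(max(nearest_point_dist_cpp(setA, setB)),
      max(nearest_point_dist_cpp(setB, setA)))
}

#' 95th-percentile Hausdorff distance
#'
#' Robust variant of \code{\link{hausdorff}}: the maximum over both
#' directions of the 95th percentile (linear interpolation) of the
#' nearest-neighbour distance distribution. Less sensitive to single
#' outlying boundary vertices than the plain maximum.
#'
#' @inheritParams hausdorff
#' @param probs percentile in [0, 1].
#' @param pooled logical; if \code{TRUE}, take the percentile of the pooled
#'   two-direction distance distribution instead of the per-direction
#'   maximum.
#' @return distance in mm.
#' @export
hausdorff_95 <- function(setA, setB, probs = 0.95, pooled = FALSE) {
  setA <- matrix(as.numeric(setA), ncol = 3)
  setB <- matrix(as.numeric(setB), ncol = 3)
  if (nrow(setA) == 0 || nrow(setB) == 0) stop("Hausdorff distance of an empty point set is undefined")
  dab <- nearest_point_dist_cpp(setA, setB)
  dba <- nearest_point_dist_cpp(setB, setA)
  if (pooled) {
    unname(stats::quantile(c(dab, dba), probs, type = 7))
  } else {
    max(stats::quantile(dab, probs, type = 7), stats::quantile(dba, probs, type = 7))
  }
}

#' Evaluate a predicted labeling against ground truth
#'
#' Per tooth class present in the ground truth: area-weighted IoU over
#' faces, and the 95th-percentile Hausdorff distance between the
#' label-boundary vertex clouds of ground truth and prediction. Teeth
#' absent from the prediction score W-IoU 0 with the boundary metric
#' flagged unavailable. Case values are unweighted means over ground-truth
#' teeth.
#'
#' @param mesh a \code{tri_mesh}.
#' @param gt,pred \code{face_labels} matching the mesh.
#' @return list with \code{per_tooth} (data.frame: tooth, wiou, dh95,
#'   missing_in_pred) and \code{case} (list: mean_wiou, mean_dh95 over teeth
#'   where defined).
#' @export
evaluate_case <- function(mesh, gt, pred) {
  teeth <- present_teeth(gt)
  rows <- lapply(teeth, function(cls) {
    wiou <- weighted_iou(mesh, gt, pred, cls)
    pred_has <- any(as.character(pred) == cls)
    if (pred_has) {
      bg <- label_boundary_vertices(mesh, gt, cls)
      bp <- label_boundary_vertices(mesh, pred, cls)
      dh <- if (nrow(bg) > 0 && nrow(bp) > 0) hausdorff_95(bg, bp) else NA_real_
    } else {
      dh <- NA_real_
    }
    data.frame(tooth = cls, wiou = wiou, dh95 = dh,
               missing_in_pred = !pred_has, stringsAsFactors = FALSE)
  })
  per_tooth <- do.call(rbind, rows)
  list(per_tooth = per_tooth,
       case = list(mean_wiou = mean(per_tooth$wiou),
                   mean_dh95 = mean(per_tooth$dh95, na.rm = TRUE)))
}
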