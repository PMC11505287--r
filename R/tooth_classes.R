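#' Tooth class codes
#'
#' The labeling alphabet for a dental arch: sixteen tooth classes named by
#' quadrant (\code{L}eft / \code{R}ight) and position 1 (central incisor) to
#' 8 (third molar), plus \code{G} for gingiva. Two orderings matter:
#' \describe{
#'   \item{class index}{\code{L1..L8, R1..R8, G}: the 0-based enumeration
#'     (\code{G} = 16) used for voting tie-breaks.}
#'   \item{arch order}{\code{L8..L1, R1..R8}: anatomical order along the
#'     dental arch, used for landmark slots and the tooth-type signal.}
#' }
#'
#' @param include_gingiva logical; append \code{"G"} to the vector.
#' @return Character vector of class codes in class-index order.
#' @export
tooth_class_codes <- function(include_gingiva = TRUE) {
  codes <- c(paste0("L", 1:8), paste0("R", 1:8))
  if (include_gingiva) codes <- c(codes, "G")
  codes
}

#' @rdname tooth_class_codes
#' @export
tooth_arch_order <- function() {
  c(paste0("L", 8:1), paste0("R", 1:8))
}

#' 0-based class index of a tooth class code
#'
#' @param code character vector of class codes (\code{L8..L1,R1..R8,G}).
#' @return Integer vector, 0 for \code{L8} through 15 for \code{R8}, 16 for \code{G}.
#' @export
tooth_class_index <- function(code) {
  idx <- match(code, tooth_class_codes())
  if (anyNA(idx)) {
    stop("unknown tooth class code(s): ", paste(unique(code[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' Tooth-type input signal
#'
#' Maps a tooth class to the scalar that conditions the shared segmentation
#' network: \code{i_tt = (type_index + 1) / 16}, where the type index runs
#' 0..15 over the arch order \code{L8..L1, R1..R8}. Distinct tooth types get
#' distinct values in (0, 1].
#'
#' @param cls a single tooth class code; \code{"G"} is rejected.
#' @return Scalar in (0, 1].
#' @export
tooth_type_signal <- function(cls) {
  stopifnot(length(cls) == 1L)
  if (cls == "G") stop("gingiva has no tooth-type signal")
  idx <- match(cls, tooth_arch_order())
  if (is.na(idx)) stop("unknown tooth class code: ", cls)
  idx / 16
}

#' Construct a per-face labeling
#'
#' A face labeling is a factor of class codes, one entry per face of an
#' associated mesh, with levels fixed to the full class alphabet.
#'
#' @param codes character (or factor) vector of class codes, one per face.
#' @param n_faces optional expected length for validation.
#' @return factor with class \code{"face_labels"}.
#' @export
face_labels <- function(codes, n_faces = NULL) {
  codes <- as.character(codes)
  bad <- setdiff(unique(codes), tooth_class_codes())
  if (length(bad) > 0) stop("unknown tooth class code(s): ", paste(bad, collapse = ", "))
  if (!is.null(n_faces) && length(codes) != n_faces) {
    stop(sprintf("labeling has %d entries but mesh has %d faces", length(codes), n_faces))
  }
  structure(factor(codes, levels = tooth_class_codes()), class = c("face_labels", "factor"))
}

#' Tooth classes present in a labeling (excluding gingiva)
#' @param labels a \code{face_labels} factor.
#' @return character vector of present tooth codes, in class-index order.
#' @export
present_teeth <- function(labels) {
  lv <- tooth_class_codes(include_gingiva = FALSE)
  lv[lv %in% as.character(unique(labels))]
}
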