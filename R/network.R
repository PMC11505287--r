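#' Segmentation network configuration
#'
#' @param stage_widths channel counts per U-Net stage (encoder top to
#'   bottleneck). Default \code{c(32, 64, 128, 256, 512)}.
#' @param recurrent_hidden hidden channels per direction of the
#'   bi-directional convolutional LSTM. Default 32.
#' @param input_channels input channels: depth + 3 normal components + the
#'   constant tooth-type channel.
#' @param resolution input image height = width; must be divisible by
#'   \code{2^(stages - 1)}.
#' @param deep_supervision logical; auxiliary sigmoid heads on every decoder
#'   stage, optimized jointly with the final head.
#' @param itt_embedding logical; additionally inject the tooth-type signal
#'   as a learned additive per-channel embedding at each decoder stage
#'   (variant of the default input-channel conditioning).
#' @param threshold probability cutoff for \code{\link{binarize}}.
#' @return object of class \code{network_config}.
#' @export
network_config <- function(stage_widths = c(32, 64, 128, 256, 512),
                           recurrent_hidden = 32L,
                           input_channels = 5L,
                           resolution = 256L,
                           deep_supervision = TRUE,
                           itt_embedding = FALSE,
                           threshold = 0.5) {
  stage_widths <- as.integer(stage_widths)
  if (length(stage_widths) < 2) stop("need at least 2 stages")
  if (resolution %% 2^(length(stage_widths) - 1) != 0) {
    stop("resolution must be divisible by 2^(stages - 1)")
  }
  structure(list(stage_widths = stage_widths,
                 recurrent_hidden = as.integer(recurrent_hidden),
                 input_channels = as.integer(input_channels),
                 resolution = as.integer(resolution),
                 deep_supervision = isTRUE(deep_supervision),
                 itt_embedding = isTRUE(itt_embedding),
                 threshold = threshold),
            class = "network_config")
}

#' Create a segmentation network
#'
#' Instantiates the tooth-type-conditioned recurrent U-Net with freshly
#' initialized weights (He initialization, forget-gate bias 1).
#'
#' @param config a \code{network_config}.
#' @param seed integer seed for weight initialization.
#' @return object of class \code{seg_net} holding the native model handle.
#' @export
seg_net <- function(config, seed = 1L) {
  ptr <- nn_create_cpp(config$stage_widths, config$input_channels,
                       config$recurrent_hidden, config$resolution,
                       config$deep_supervision, config$itt_embedding,
                       as.integer(seed))
  structure(list(ptr = ptr, config = config), class = "seg_net")
}

#' @export
print.seg_net <- function(x, ...) {
  cat(sprintf("<seg_net> stages [%s], recurrent %d/direction, %d params, %dx%d input\n",
              paste(x$config$stage_widths, collapse = ","),
              x$config$recurrent_hidden, n_parameters(x),
              x$config$resolution, x$config$resolution))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a \code{seg_net}.
#' @export
n_parameters <- function(model) nn_param_count_cpp(model$ptr)

#' Forward pass over a view sequence
#'
#' @param model a \code{seg_net}.
#' @param x input array \code{n x C x H x W} (see
#'   \code{\link{sequence_input}}), or a \code{view_sequence} together with
#'   \code{i_tt}.
#' @param i_tt tooth-type scalar; required when \code{x} is a
#'   \code{view_sequence} (also used for the decoder embedding variant).
#' @param aux logical; also return per-decoder-stage auxiliary probability
#'   maps (deep supervision heads).
#' @return list with \code{probs} (\code{n x H x W} array in [0,1]) and
#'   optionally \code{aux}.
#' @export
forward <- function(model, x, i_tt = NULL, aux = FALSE) {
  if (inherits(x, "view_sequence")) {
    if (is.null(i_tt)) stop("i_tt required when passing a view_sequence")
    x <- sequence_input(x, i_tt)
  }
  if (is.null(i_tt)) i_tt <- x[1, dim(x)[2], 1, 1]
  nn_forward_cpp(model$ptr, x, i_tt, aux)
}

#' Binarize probability maps
#'
#' Pixel value 1 iff the probability strictly exceeds the threshold.
#'
#' @param probs numeric array of probabilities in [0,1].
#' @param threshold cutoff (default 0.5).
#' @return integer array of the same shape with values \{0, 1\}.
#' @export
binarize <- function(probs, threshold = 0.5) {
  out <- array(0L, dim = dim(probs))
  out[probs > threshold] <- 1L
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the network configuration, all weights and the
#' batch-norm running statistics.
#'
#' @param model a \code{seg_net}.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(model, path) {
  state <- nn_get_state_cpp(model$ptr)
  saveRDS(list(config = model$config, state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return \code{load_checkpoint} returns a \code{seg_net}.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- seg_net(ck$config, seed = 0L)
  nn_set_state_cpp(model$ptr, ck$state)
  model
}

#' Extract / restore network state in-memory
#' @param model a \code{seg_net}.
#' @param state a state list from \code{network_state}.
#' @export
network_state <- function(model) nn_get_state_cpp(model$ptr)

#' @rdname network_state
#' @export
restore_network_state <- function(model, state) {
  nn_set_state_cpp(model$ptr, state)
  invisible(model)
}
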