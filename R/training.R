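#' Dice loss
#'
#' \code{1 - (2 * sum(p*r) + eps) / (sum(p) + sum(r) + eps)}; the epsilon
#' term keeps the loss stable on empty masks. Value in [0, 1) for
#' \code{eps > 0}.
#'
#' @param pred numeric probability image in [0,1].
#' @param ref binary reference image of the same shape.
#' @param eps stability term (default 1).
#' @return scalar loss.
#' @export
dice_loss <- function(pred, ref, eps = 1.0) {
  if (!all(dim(pred) == dim(ref)) || length(pred) != length(ref)) {
    stop("pred and ref shapes differ")
  }
  1 - (2 * sum(pred * ref) + eps) / (sum(pred) + sum(ref) + eps)
}

#' Analytic gradient of the Dice loss with respect to the prediction
#' @inheritParams dice_loss
#' @return array of the same shape as \code{pred}.
#' @export
dice_loss_grad <- function(pred, ref, eps = 1.0) {
  den <- sum(pred) + sum(ref) + eps
  num <- 2 * sum(pred * ref) + eps
  -(2 * ref * den - num) / den^2
}

#' Deep-supervision loss
#'
#' Unweighted sum of Dice losses over all decoder heads: the reference is
#' downsampled to each auxiliary head's resolution by nearest neighbour, and
#' the final full-resolution head contributes the last term.
#'
#' @param stage_preds list of probability images, coarse heads first and the
#'   full-resolution head last.
#' @param ref full-resolution binary reference.
#' @param eps Dice stability term.
#' @return scalar loss.
#' @export
deep_supervised_loss <- function(stage_preds, ref, eps = 1.0) {
  stopifnot(length(stage_preds) >= 1)
  sum(vapply(stage_preds, function(p) {
    f <- nrow(ref) / nrow(p)
    if (f != round(f)) stop("head resolution is not an integer divisor of the reference")
    r <- ref[seq(1, nrow(ref), by = f), seq(1, ncol(ref), by = f), drop = FALSE]
    dice_loss(p, r, eps)
  }, numeric(1)))
}

#' Sample a mesh-level augmentation transform
#'
#' Rotation by an angle uniform in [-pi/4, pi/4] about a uniformly random
#' axis, per-coordinate translation uniform in [-5, 5] mm, isotropic scale
#' uniform in [0.8, 1.2].
#'
#' @param seed integer seed.
#' @return object of class \code{augment_transform} with \code{rotation}
#'   (3x3), \code{translation}, \code{scale} and the sampled \code{angle}
#'   and \code{axis}.
#' @export
sample_augment <- function(seed = 1L) {
  with_seed(seed, {
    axis <- runif_sphere(1)[1, ]
    angle <- stats::runif(1, -pi / 4, pi / 4)
    structure(list(rotation = rotation_about_axis(axis, angle),
                   translation = stats::runif(3, -5, 5),
                   scale = stats::runif(1, 0.8, 1.2),
                   angle = angle, axis = axis),
              class = "augment_transform")
  })
}

#' Apply an augmentation transform to a mesh (and landmarks)
#'
#' Every vertex becomes \code{scale * R v + t}; topology and labels are
#' untouched. \code{augment_case} transforms the landmarks identically.
#'
#' @param mesh a \code{tri_mesh}.
#' @param xf an \code{augment_transform}.
#' @export
augment_mesh <- function(mesh, xf) {
  mesh$vertices <- sweep(xf$scale * (mesh$vertices %*% t(xf$rotation)), 2,
                         -xf$translation)
  mesh
}

#' @rdname augment_mesh
#' @param case a \code{synthetic_case} (or any list with \code{mesh},
#'   \code{labels}, \code{landmarks}).
#' @export
augment_case <- function(case, xf) {
  case$mesh <- augment_mesh(case$mesh, xf)
  lm <- unclass(case$landmarks)
  fin <- is.finite(lm[, 1])
  for (cols in list(1:3, 4:6)) {
    lm[fin, cols] <- sweep(xf$scale * (lm[fin, cols, drop = FALSE] %*% t(xf$rotation)),
                           2, -xf$translation)
  }
  case$landmarks <- landmark_set(lm)
  case
}

#' Ground-truth binary target masks for one tooth
#'
#' Target pixel 1 iff the view's first-hit face carries the tooth's label;
#' background pixels are 0.
#'
#' @param labels \code{face_labels} of the rendered mesh.
#' @param tooth tooth class code; must be present in \code{labels}.
#' @param views a \code{view_sequence} of that tooth.
#' @return integer array \code{n x H x W} with values \{0, 1\}.
#' @export
make_targets <- function(labels, tooth, views) {
  if (tooth == "G") stop("targets are per tooth; gingiva has no tooth mask")
  if (!tooth %in% as.character(labels)) stop("tooth ", tooth, " absent from labeling")
  H <- nrow(views[[1]]$record$first_hit); W <- ncol(views[[1]]$record$first_hit)
  out <- array(0L, dim = c(length(views), H, W))
  lab <- as.character(labels)
  for (v in seq_along(views)) {
    fh <- views[[v]]$record$first_hit
    m <- matrix(0L, H, W)
    hitpix <- fh > 0L
    m[hitpix] <- as.integer(lab[fh[hitpix]] == tooth)
    out[v, , ] <- m
  }
  out
}

#' Training configuration
#'
#' @param batch_size sequences per optimizer step.
#' @param learning_rate,weight_decay AdamW settings (default 0.001 each).
#' @param restart_period cosine-annealing warm-restart period in iterations.
#' @param iterations total optimizer iterations.
#' @param n_views views per tooth sequence.
#' @param resolution rendered map size in pixels.
#' @param epsilon Dice stability term.
#' @param val_fraction fraction of cases held out for validation (default
#'   1/5, i.e. a 4:1 train/validation split); 0 (or a single case) trains on
#'   everything and monitors the training cases instead (overfit regime).
#' @param n_augment augmented copies generated per training case before
#'   rendering (mesh-level rigid+scale transforms; no 2D augmentation).
#' @param n_remesh tessellation-augmented copies per training case: locally
#'   remeshed variants (edge flip/collapse/refine/relax at the native edge
#'   length) that decouple the learned features from the particular
#'   triangulation; ground truth comes from the generator labeler when the
#'   case carries one, else from nearest-face transport.
#' @param eval_every validation cadence in iterations.
#' @param seed integer seed controlling splits, augmentation and sampling.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(batch_size = 4L, learning_rate = 0.001,
                         weight_decay = 0.001, restart_period = 10000L,
                         iterations = 2000L, n_views = 49L, resolution = 256L,
                         epsilon = 1.0, val_fraction = 0.2, n_augment = 10L,
                         n_remesh = 0L, eval_every = 50L, seed = 1L) {
  stopifnot(batch_size >= 1, learning_rate > 0, restart_period >= 1,
            iterations >= 1, n_views >= 1, val_fraction >= 0, val_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 restart_period = as.integer(restart_period),
                 iterations = as.integer(iterations),
                 n_views = as.integer(n_views),
                 resolution = as.integer(resolution), epsilon = epsilon,
                 val_fraction = val_fraction, n_augment = as.integer(n_augment),
                 n_remesh = as.integer(n_remesh),
                 eval_every = as.integer(eval_every), seed = as.integer(seed)),
            class = "train_config")
}

# cosine annealing with warm restarts, minimum 0
cosine_lr <- function(iter, base_lr, period) {
  t_cur <- (iter - 1L) %% period
  base_lr / 2 * (1 + cos(pi * t_cur / period))
}

# tessellation-augmented copy of a case: locally remeshed geometry with
# exact (generator) or transported labels
remesh_variant <- function(case, seed = 1L) {
  target <- with_seed(seed, stats::runif(1, 0.85, 1.15)) *
    stats::median(edge_lengths(case$mesh))
  pmesh <- perturb_er(case$mesh, target_edge = target, passes = 3L)
  labels <- if (!is.null(case$labeler)) synthetic_labels(case, pmesh) else
    transfer_labels_nearest(case$mesh, case$labels, pmesh)
  out <- case
  out$mesh <- pmesh
  out$labels <- labels
  out
}

# render one training item (tooth of an augmented case) into input + target
render_item <- function(case, tooth, n_views, resolution, camera = list()) {
  lm <- case$landmarks
  pair <- list(lm[tooth, 1:3], lm[tooth, 4:6])
  poses <- do.call(sample_views, c(list(pair, n = n_views), camera))
  views <- render_sequence(case$mesh, poses, resolution)
  list(x = sequence_input(views, tooth_type_signal(tooth)),
       target = make_targets(case$labels, tooth, views),
       views = views)
}

#' Train the segmentation network on labeled cases
#'
#' Splits the cases into train/validation (4:1 by default), generates
#' \code{n_augment} augmented variants of every training case (meshes are
#' assumed pre-aligned to occlusion; augmentation precedes rendering, and no
#' 2D augmentation is applied), renders per-tooth view sequences on the fly,
#' and minimizes the deep-supervised Dice loss with AdamW under cosine
#' warm restarts. The best-validation network state is restored at the end.
#'
#' @param cases list of \code{synthetic_case} (or equivalently structured
#'   labeled meshes with landmarks), already in canonical pose.
#' @param net_cfg a \code{network_config}.
#' @param train_cfg a \code{train_config}.
#' @param camera optional list of camera overrides passed to
#'   \code{\link{sample_views}} (radius, max_zenith, half_extent, ...).
#' @param verbose log progress to stderr.
#' @return list with \code{model} (a \code{seg_net}, best-validation
#'   weights), \code{log} (data.frame of per-iteration losses) and
#'   \code{split} (train/val case indices).
#' @export
train <- function(cases, net_cfg, train_cfg, camera = list(), verbose = TRUE) {
  if (length(cases) < 1) stop("no training cases")
  cfg <- train_cfg
  with_seed(cfg$seed, {
    n <- length(cases)
    n_val <- round(cfg$val_fraction * n)
    if (n < 2) n_val <- 0L
    if (n_val > 0) {
      val_idx <- sort(sample.int(n, n_val))
      train_idx <- setdiff(seq_len(n), val_idx)
    } else {
      # overfit regime: no held-out cases, validation monitors the train set
      val_idx <- integer(0)
      train_idx <- seq_len(n)
    }

    # fixed augmented pool: original + rigid/scale and tessellation variants
    pool <- list()
    for (ci in train_idx) {
      pool[[length(pool) + 1L]] <- cases[[ci]]
      for (a in seq_len(cfg$n_augment)) {
        xf <- sample_augment(seed = sample.int(.Machine$integer.max, 1))
        pool[[length(pool) + 1L]] <- augment_case(cases[[ci]], xf)
      }
      for (a in seq_len(cfg$n_remesh)) {
        pool[[length(pool) + 1L]] <- remesh_variant(
          cases[[ci]], seed = sample.int(.Machine$integer.max, 1))
      }
    }
    items <- do.call(rbind, lapply(seq_along(pool), function(pi) {
      data.frame(pool = pi, tooth = landmark_present(pool[[pi]]$landmarks),
                 stringsAsFactors = FALSE)
    }))
    val_source <- if (length(val_idx) > 0) val_idx else train_idx
    val_items <- do.call(rbind, lapply(val_source, function(ci) {
      data.frame(case = ci, tooth = landmark_present(cases[[ci]]$landmarks),
                 stringsAsFactors = FALSE)
    }))
    # small fixed validation subset rendered once
    vi <- val_items[sample.int(nrow(val_items), min(8L, nrow(val_items))), ]
    val_data <- lapply(seq_len(nrow(vi)), function(k) {
      render_item(cases[[vi$case[k]]], vi$tooth[k], cfg$n_views, cfg$resolution, camera)
    })

    model <- seg_net(net_cfg, seed = sample.int(.Machine$integer.max, 1))
    nn_zero_grad_cpp(model$ptr)
    # item inputs are deterministic; cache rendered tensors for small pools
    use_cache <- nrow(items) <= 128L
    render_cache <- vector("list", nrow(items))
    get_item <- function(k) {
      if (use_cache && !is.null(render_cache[[k]])) return(render_cache[[k]])
      item <- render_item(pool[[items$pool[k]]], items$tooth[k],
                          cfg$n_views, cfg$resolution, camera)
      item$views <- NULL
      if (use_cache) render_cache[[k]] <<- item
      item
    }
    best_val <- Inf
    best_state <- NULL
    log_rows <- vector("list", cfg$iterations)

    for (it in seq_len(cfg$iterations)) {
      pick <- sample.int(nrow(items), cfg$batch_size, replace = nrow(items) < cfg$batch_size)
      loss_sum <- 0
      for (k in pick) {
        item <- get_item(k)
        loss_sum <- loss_sum + nn_accumulate_cpp(model$ptr, item$x, item$target,
                                                 tooth_type_signal(items$tooth[k]),
                                                 cfg$epsilon)
      }
      if (!is.finite(loss_sum)) stop("non-finite training loss at iteration ", it)
      lr <- cosine_lr(it, cfg$learning_rate, cfg$restart_period)
      nn_adam_step_cpp(model$ptr, lr, cfg$weight_decay, 1 / cfg$batch_size)
      val_loss <- NA_real_
      if (it %% cfg$eval_every == 0 || it == cfg$iterations) {
        val_loss <- mean(vapply(val_data, function(d) {
          out <- nn_forward_cpp(model$ptr, d$x, d$x[1, 5, 1, 1], FALSE)
          mean(vapply(seq_len(dim(out$probs)[1]), function(v) {
            dice_loss(out$probs[v, , ], d$target[v, , ], cfg$epsilon)
          }, numeric(1)))
        }, numeric(1)))
        if (is.finite(val_loss) && val_loss < best_val) {
          best_val <- val_loss
          best_state <- network_state(model)
        }
        if (verbose) {
          log_msg("train", "iter %d/%d loss %.4f val %.4f lr %.2e",
                  it, cfg$iterations, loss_sum / cfg$batch_size, val_loss, lr)
        }
      }
      log_rows[[it]] <- data.frame(iteration = it,
                                   loss = loss_sum / cfg$batch_size,
                                   val_loss = val_loss, lr = lr)
    }
    if (!is.null(best_state)) restore_network_state(model, best_state)
    list(model = model, log = do.call(rbind, log_rows),
         split = list(train = train_idx, val = val_idx), best_val = best_val)
  })
}
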