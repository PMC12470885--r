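# Skeleton Distance Loss, boundary loss and the composite / cascaded
# training objectives.
#
# All user-facing functions here operate on single images: masks are binary
# (H x W) matrices, predictions are (H x W) foreground-probability matrices.
# The batched, differentiable counterparts used by the training loop are in
# train.R and reuse the same weight maps.

check_binary <- function(mask, what = "mask") {
  if (!all(mask %in% c(0, 1)))
    stop(sprintf("%s must be strictly binary (0/1)", what))
  invisible(NULL)
}

#' Morphological skeleton of a binary mask
#'
#' Iterative two-subcycle thinning (Zhang-Suen) down to a one-pixel-wide
#' medial representation that preserves the connectivity of the foreground.
#'
#' @param mask binary matrix (0/1); vessel pixels are 1.
#' @return binary matrix of the same size, a subset of `mask`.
#' @export
skeletonize <- function(mask) {
  mask <- as.matrix(mask)
  check_binary(mask)
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  out <- thin_mask(m)
  storage.mode(out) <- "double"
  out
}

#' Euclidean distance to the nearest skeleton pixel
#'
#' Exact Euclidean distance transform of the skeleton: every pixel is
#' assigned its distance (in pixels) to the closest skeleton pixel, so the
#' map is zero exactly on the skeleton and strictly positive elsewhere.
#' An empty skeleton (a tile with no vessels) yields an all-zero map with a
#' warning rather than an error, since random crops can contain no vessels.
#'
#' @param skeleton binary matrix as produced by [skeletonize()].
#' @return non-negative numeric matrix of the same size.
#' @export
skeleton_distance_map <- function(skeleton) {
  skeleton <- as.matrix(skeleton)
  check_binary(skeleton, "skeleton")
  if (!any(skeleton == 1)) {
    warning("empty skeleton: distance map defined as all-zero")
    return(matrix(0, nrow(skeleton), ncol(skeleton)))
  }
  edt(skeleton == 1)
}

# Normalised SDL weight map for a mask: distance to the mask's skeleton,
# scaled into [0, 1] by the per-image maximum.
sdl_weight_map <- function(mask) {
  skel <- skeletonize(mask)
  if (!any(skel == 1)) {
    warning("empty mask: SDL weight map is all-zero")
    return(matrix(0, nrow(mask), ncol(mask)))
  }
  d <- edt(skel == 1)
  mx <- max(d)
  if (mx > 0) d <- d / mx
  d
}

#' Skeleton Distance Loss
#'
#' Mean over the image domain of the predicted vessel probability weighted
#' by the (per-image max-normalised) Euclidean distance to the skeleton of
#' the reference mask.  The weights are non-negative everywhere and vanish
#' exactly on the skeleton, so the loss is zero iff all predicted mass sits
#' on the skeleton, and it is linear in the prediction.
#'
#' @param pred foreground-probability matrix in \[0, 1\].
#' @param mask binary reference mask of the same size.
#' @return a single non-negative number.
#' @export
sdl_loss <- function(pred, mask) {
  pred <- as.matrix(pred)
  mask <- as.matrix(mask)
  if (!all(dim(pred) == dim(mask)))
    stop("prediction and mask shapes differ")
  w <- sdl_weight_map(mask)
  mean(w * pred)
}

#' Signed boundary weight map
#'
#' Signed Euclidean distance to the mask boundary (foreground pixels with a
#' background 4-neighbour): negative inside the foreground, positive in the
#' background, zero on the boundary itself.  This is the weight map of the
#' reference boundary loss, shown for contrast with the SDL map: any filled
#' region of radius at least 2 produces negative interior weights.
#'
#' @inheritParams sdl_loss
#' @return numeric matrix of signed distances.
#' @export
boundary_weight_map <- function(mask) {
  mask <- as.matrix(mask)
  check_binary(mask)
  bd <- boundary_pixels(mask)
  if (!any(bd)) return(matrix(0, nrow(mask), ncol(mask)))
  d <- edt(bd)
  d * ifelse(mask == 1, -1, 1)
}

# Foreground pixels with at least one background 4-neighbour.
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(1, H + 2, W + 2)   # pixels beyond the frame count as fg,
  pad[2:(H + 1), 2:(W + 1)] <- mask  # so the image edge is not a boundary
  inner <- pad[2:(H + 1), 2:(W + 1)]
  nb_min <- pmin(pad[1:H, 2:(W + 1)], pad[3:(H + 2), 2:(W + 1)],
                 pad[2:(H + 1), 1:W], pad[2:(H + 1), 3:(W + 2)])
  inner == 1 & nb_min == 0
}

#' Boundary loss (reference formulation)
#'
#' Two-integral form: mean of the signed boundary map times the prediction
#' minus the mean of the map times the reference mask.  Provided for
#' comparison with [sdl_loss()]; it is not part of the training objective.
#'
#' @inheritParams sdl_loss
#' @export
boundary_loss <- function(pred, mask) {
  pred <- as.matrix(pred)
  mask <- as.matrix(mask)
  if (!all(dim(pred) == dim(mask)))
    stop("prediction and mask shapes differ")
  phi <- boundary_weight_map(mask)
  mean(phi * pred) - mean(phi * mask)
}

# ------------------------------------------------------- regional losses ---

regional_loss <- function(pred, mask, type = c("ce", "dice"), eps = 1e-7) {
  type <- match.arg(type)
  if (type == "ce") {
    p <- pmin(pmax(pred, eps), 1 - eps)
    -mean(mask * log(p) + (1 - mask) * log(1 - p))
  } else {
    1 - (2 * sum(pred * mask) + eps) / (sum(pred) + sum(mask) + eps)
  }
}

# --------------------------------------------------------- configuration ---

#' Loss configuration
#'
#' @param alpha_max maximum weight of the Skeleton Distance Loss in the
#'   composite objective.  Must lie in \[0, 0.7\]; the pure-SDL setting
#'   `alpha_max = 1` is only admitted with `sensitivity = TRUE`, the mode
#'   used for the alpha sensitivity sweep.
#' @param regional regional loss: `"ce"` (cross-entropy) or `"dice"`.
#' @param w0,w1 non-negative supervision weights of the first (mid) and
#'   second (end) cascade stage.
#' @param alpha_ramp_frac fraction of training over which alpha ramps
#'   linearly from 0 up to `alpha_max` (constant afterwards).
#' @param sensitivity allow `alpha_max` in (0.7, 1\] for sensitivity sweeps.
#' @return an object of class `"loss_config"`.
#' @export
loss_config <- function(alpha_max = 0.7, regional = c("ce", "dice"),
                        w0 = 0.5, w1 = 0.5, alpha_ramp_frac = 0.5,
                        sensitivity = FALSE) {
  regional <- match.arg(regional)
  lim <- if (sensitivity) 1 else 0.7
  if (alpha_max < 0 || alpha_max > lim)
    stop(sprintf("alpha_max must lie in [0, %.1f]", lim))
  if (w0 < 0 || w1 < 0) stop("stage weights must be non-negative")
  structure(list(alpha_max = alpha_max, regional = regional,
                 w0 = w0, w1 = w1, alpha_ramp_frac = alpha_ramp_frac,
                 sensitivity = sensitivity),
            class = "loss_config")
}

#' SDL weight at a given epoch
#'
#' Linear ramp from 0 to `alpha_max` over the first `alpha_ramp_frac` of
#' training, constant afterwards; non-decreasing in the epoch and capped at
#' `alpha_max`.
#'
#' @param cfg a [loss_config()].
#' @param epoch 1-based epoch index.
#' @param n_epochs total number of training epochs.
#' @export
alpha_at <- function(cfg, epoch, n_epochs) {
  stopifnot(inherits(cfg, "loss_config"))
  ramp <- max(1, floor(cfg$alpha_ramp_frac * n_epochs))
  cfg$alpha_max * min(1, (epoch - 1) / ramp)
}

#' Composite segmentation loss
#'
#' `alpha * SDL + (1 - alpha) * L_regional` with the epoch-scheduled alpha.
#'
#' @inheritParams sdl_loss
#' @param cfg a [loss_config()].
#' @param epoch,n_epochs position in the training schedule (determines the
#'   scheduled alpha); defaults evaluate at the fully ramped `alpha_max`.
#' @export
composite_loss <- function(pred, mask, cfg, epoch = NULL, n_epochs = NULL) {
  stopifnot(inherits(cfg, "loss_config"))
  a <- if (is.null(epoch)) cfg$alpha_max else alpha_at(cfg, epoch, n_epochs)
  a * sdl_loss(pred, mask) +
    (1 - a) * regional_loss(pred, mask, cfg$regional)
}

#' Cascaded dual-stage loss
#'
#' Weighted sum of the composite loss over the two supervised stage
#' outputs: `w0 * Ls(mid) + w1 * Ls(end)`.
#'
#' @param preds list with elements `mid` and `end`, each a
#'   foreground-probability matrix.
#' @inheritParams composite_loss
#' @export
cascaded_loss <- function(preds, mask, cfg, epoch = NULL, n_epochs = NULL) {
  stopifnot(is.list(preds), !is.null(preds$mid), !is.null(preds$end))
  cfg$w0 * composite_loss(preds$mid, mask, cfg, epoch, n_epochs) +
    cfg$w1 * composite_loss(preds$end, mask, cfg, epoch, n_epochs)
}
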