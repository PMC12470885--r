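# S3 methods for the model and fit objects.

#' @export
print.dsae_net <- function(x, ...) {
  cat(sprintf("DSAE-Net cascade  (k = %d, m = %d)\n", x$k, x$m))
  cat(sprintf("  input channels : %d (+%d handed to stage 2)\n",
              x$in_channels, x$stage2_extra))
  cat(sprintf("  classes        : %d\n", x$num_classes))
  if (!x$cmfa) cat("  ablation       : CMFA replaced by plain convs\n")
  if (!x$cag) cat("  ablation       : coordinate attention gates removed\n")
  np <- count_parameters(x)
  cat(sprintf("  parameters     : %s (%.2f M)\n",
              format(np, big.mark = ","), np / 1e6))
  invisible(x)
}

#' @export
print.cae_unet <- function(x, ...) {
  cat(sprintf("CAE-UNet  (k = %d, m = %d)\n", x$k, x$m))
  np <- count_parameters(x)
  cat(sprintf("  parameters : %s (%.2f M)\n",
              format(np, big.mark = ","), np / 1e6))
  invisible(x)
}

#' @export
print.unet_baseline <- function(x, ...) {
  np <- count_parameters(x)
  cat(sprintf("U-Net baseline (depth %d, top width %d): %.2f M parameters\n",
              x$k, x$m, np / 1e6))
  invisible(x)
}

#' @export
print.dsae_fit <- function(x, ...) {
  cat(sprintf("DSAE-Net fit  (k = %d, m = %d)\n", x$net$k, x$net$m))
  cat(sprintf("  %d training / %d validation images, %d epochs (batch %d)\n",
              x$n_train, x$n_val, x$train_config$epochs,
              x$train_config$batch_size))
  cat(sprintf("  loss: %s, alpha_max = %.2f, stage weights (%.2f, %.2f)\n",
              x$loss_config$regional, x$loss_config$alpha_max,
              x$loss_config$w0, x$loss_config$w1))
  if (!is.null(x$best$state))
    cat(sprintf("  retained checkpoint: cycle %d, val AUC %.4f, Dice %.4f\n",
                x$best$cycle, x$best$auc, x$best$val$dice))
  invisible(x)
}

#' @export
summary.dsae_fit <- function(object, ...) {
  h <- object$history
  cv <- h[!is.na(h$val_auc), ]
  out <- list(epochs = nrow(h),
              final_loss = h$loss[nrow(h)],
              best_cycle = object$best$cycle,
              best_val = object$best$val,
              val_trace = cv[, c("epoch", "val_auc", "val_dice",
                                 "val_miou")])
  class(out) <- "summary.dsae_fit"
  out
}

#' @export
print.summary.dsae_fit <- function(x, ...) {
  cat(sprintf("training: %d epochs, final loss %.4f\n",
              x$epochs, x$final_loss))
  cat(sprintf("best cycle %d: val AUC %.4f, Dice %.4f, mIoU %.4f\n",
              x$best_cycle, x$best_val$auc, x$best_val$dice,
              x$best_val$miou))
  cat("validation trace:\n")
  print(x$val_trace, row.names = FALSE)
  invisible(x)
}

#' Predict vessel probability / mask for new images
#'
#' @param object a `"dsae_fit"`.
#' @param newdata one (H, W, 3) image array or a list of such arrays (a
#'   `list(image = ...)` pair entry is also accepted).
#' @param type `"prob"` for the foreground-probability map, `"mask"` for
#'   the binarised segmentation.
#' @param tta use flip test-time augmentation.
#' @param threshold binarisation threshold for `type = "mask"`.
#' @param ... unused.
#' @return a matrix (or list of matrices) matching the input size.
#' @export
predict.dsae_fit <- function(object, newdata, type = c("prob", "mask"),
                             tta = TRUE, threshold = 0.5, ...) {
  type <- match.arg(type)
  one <- function(img) {
    if (is.list(img)) img <- img$image
    p <- tta_predict(object$net, img, tta = tta)
    if (type == "mask") (p >= threshold) * 1 else p
  }
  if (is.list(newdata) && !is.null(dim(newdata$image %||% NULL)))
    return(one(newdata))
  if (is.list(newdata)) return(lapply(newdata, one))
  one(newdata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.dsae_fit <- function(object, ...) {
  ps <- collect_params(unclass(object$net))
  lapply(ps, function(p) p$val)
}

#' Residual maps (truth minus predicted probability)
#'
#' @param object a `"dsae_fit"`.
#' @param pairs list of `list(image, mask)` entries.
#' @param ... unused.
#' @export
residuals.dsae_fit <- function(object, pairs, ...) {
  lapply(pairs, function(pr) pr$mask - tta_predict(object$net, pr$image))
}

#' Plot the training history
#'
#' Left axis: per-epoch training loss; right points: validation AUC and
#' Dice at cycle ends.
#'
#' @param x a `"dsae_fit"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dsae_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  cv <- h[!is.na(h$val_dice), ]
  if (nrow(cv)) {
    graphics::par(new = TRUE)
    graphics::plot(cv$epoch, cv$val_dice, type = "b", pch = 19, col = 2,
                   axes = FALSE, xlab = "", ylab = "",
                   ylim = c(0, 1), xlim = range(h$epoch))
    graphics::axis(4, col.axis = 2)
    graphics::mtext("validation Dice", side = 4, line = 2.5, col = 2)
  }
  invisible(x)
}

#' @export
print.sdl_ablation <- function(x, ...) {
  cat("loss ablation runs:\n")
  for (nm in names(x$runs)) {
    r <- x$runs[[nm]]
    cat(sprintf("  %-10s final val mIoU %.4f, step variance %.3e\n",
                nm, r$final_miou, r$curve_var))
  }
  invisible(x)
}

#' @export
plot.sdl_ablation <- function(x, ...) {
  runs <- x$runs
  epc <- x$train_config$epochs_per_cycle
  ylim <- range(unlist(lapply(runs, `[[`, "miou_curve")))
  graphics::plot(NULL, xlim = c(1, x$train_config$epochs), ylim = ylim,
                 xlab = "epoch", ylab = "validation mIoU", ...)
  i <- 0
  for (nm in names(runs)) {
    i <- i + 1
    cv <- runs[[nm]]$miou_curve
    graphics::lines(seq_along(cv) * epc, cv, col = i, lwd = 2)
  }
  graphics::legend("bottomright", legend = names(runs),
                   col = seq_along(runs), lwd = 2, bty = "n")
  invisible(x)
}
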