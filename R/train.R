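# Training protocol: Adam with cosine-annealed learning rate, per-batch
# augmentation, dual supervision through the cascaded loss, cyclic
# checkpoint retention by validation AUC, and flip test-time augmentation.

#' Training configuration
#'
#' @param epochs total training epochs.
#' @param cycles number of checkpoint-evaluation cycles; must divide
#'   `epochs` (so `cycles * epochs_per_cycle = epochs`).
#' @param batch_size images per optimisation step.
#' @param lr_init,lr_final cosine annealing endpoints of the learning rate.
#' @param input_size square crop size (pixels) fed to the network.
#' @param augment enable random resize-crop, flips and colour jitter.
#' @param warm_restarts restart the cosine schedule at each cycle instead
#'   of a single full-length anneal.
#' @param seed RNG seed for batching, augmentation and initialisation.
#' @return object of class `"train_config"`.
#' @export
train_config <- function(epochs = 200, cycles = 20, batch_size = 4,
                         lr_init = 1e-2, lr_final = 1e-8,
                         input_size = 512, augment = TRUE,
                         warm_restarts = FALSE, seed = 1) {
  if (epochs %% cycles != 0)
    stop("cycles must divide epochs (cycles * epochs_per_cycle = epochs)")
  structure(list(epochs = as.integer(epochs), cycles = as.integer(cycles),
                 epochs_per_cycle = as.integer(epochs / cycles),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_final = lr_final,
                 input_size = as.integer(input_size), augment = augment,
                 warm_restarts = warm_restarts, seed = as.integer(seed)),
            class = "train_config")
}

#' Cosine-annealed learning rate at a given epoch
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch.
#' @export
lr_at <- function(cfg, epoch) {
  if (cfg$warm_restarts) {
    t <- (epoch - 1) %% cfg$epochs_per_cycle
    T <- max(1, cfg$epochs_per_cycle - 1)
  } else {
    t <- epoch - 1
    T <- max(1, cfg$epochs - 1)
  }
  cfg$lr_final + 0.5 * (cfg$lr_init - cfg$lr_final) * (1 + cos(pi * t / T))
}

# ------------------------------------------------------------------ Adam ---

adam_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$m <- lapply(params, function(p) array(0, dim(as.array(p$val))))
  e$v <- lapply(params, function(p) array(0, dim(as.array(p$val))))
  e$t <- 0L
  e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e
}

adam_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    p$val <- p$val - lr * (opt$m[[i]] / bc1) /
      (sqrt(opt$v[[i]] / bc2) + opt$eps)
    p$grad <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ----------------------------------------------------- model state (I/O) ---

collect_bn <- function(x) {
  if (inherits(x, "bn_layer")) return(list(x))
  if (is.list(x) && !is_dtensor(x))
    return(do.call(c, lapply(x, collect_bn)))
  list()
}

get_state <- function(net) {
  ps <- collect_params(unclass(net))
  bns <- collect_bn(unclass(net))
  list(params = lapply(ps, function(p) p$val),
       bn = lapply(bns, function(b) list(rmean = b$rmean, rvar = b$rvar)))
}

set_state <- function(net, state) {
  ps <- collect_params(unclass(net))
  bns <- collect_bn(unclass(net))
  stopifnot(length(ps) == length(state$params),
            length(bns) == length(state$bn))
  for (i in seq_along(ps)) ps[[i]]$val <- state$params[[i]]
  for (i in seq_along(bns)) {
    bns[[i]]$rmean <- state$bn[[i]]$rmean
    bns[[i]]$rvar <- state$bn[[i]]$rvar
  }
  invisible(net)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the weights together with the (k, m)
#' configuration; a JSON sidecar records the parameter count, operation
#' count, input size and seed metadata.
#'
#' @param net a [dsae_net()].
#' @param path checkpoint file (`.rds`).
#' @param input_size input size recorded in the sidecar profile.
#' @export
save_checkpoint <- function(net, path, input_size = c(512, 512)) {
  ck <- list(config = list(k = net$k, m = net$m,
                           in_channels = net$in_channels,
                           num_classes = net$num_classes,
                           stage2_extra = net$stage2_extra,
                           cmfa = net$cmfa, cag = net$cag,
                           seed = net$seed),
             state = get_state(net))
  saveRDS(ck, path)
  prof <- model_profile(net, input_size)
  jsonlite::write_json(list(n_params = prof$n_params, flops = prof$flops,
                            input_size = input_size,
                            config = ck$config),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$config
  net <- dsae_net(cfg$k, cfg$m, cfg$in_channels, cfg$num_classes,
                  cfg$stage2_extra, cfg$cmfa, cfg$cag, cfg$seed)
  set_state(net, ck$state)
  net
}

# ------------------------------------------------------------ augmentation ---

hue_rotation_matrix <- function(theta) {
  # rotation about the achromatic axis (YIQ hue rotation)
  u <- cos(theta); w <- sin(theta)
  matrix(c(0.299 + 0.701 * u + 0.168 * w,
           0.587 - 0.587 * u + 0.330 * w,
           0.114 - 0.114 * u - 0.497 * w,
           0.299 - 0.299 * u - 0.328 * w,
           0.587 + 0.413 * u + 0.035 * w,
           0.114 - 0.114 * u + 0.292 * w,
           0.299 - 0.300 * u + 1.250 * w,
           0.587 - 0.588 * u - 1.050 * w,
           0.114 + 0.886 * u - 0.203 * w),
         3, 3, byrow = TRUE)
}

resize_image <- function(img, H2, W2) {
  a <- array(img, c(dim(img)[1], dim(img)[2], dim(img)[3], 1))
  array(resize_bilinear_fw(a, as.integer(H2), as.integer(W2)),
        c(H2, W2, dim(img)[3]))
}

resize_mask <- function(mask, H2, W2) {
  a <- array(mask, c(nrow(mask), ncol(mask), 1, 1))
  (matrix(resize_bilinear_fw(a, as.integer(H2), as.integer(W2)),
          H2, W2) >= 0.5) * 1
}

# Random resize-crop + flips + colour jitter for one (image, mask) pair.
augment_pair <- function(img, mask, size, jitter = 0.2,
                         scale = c(0.8, 1.2)) {
  H <- dim(img)[1]; W <- dim(img)[2]
  s <- stats::runif(1, scale[1], scale[2])
  cs <- max(16L, min(round(size / s), min(H, W)))
  y0 <- sample.int(H - cs + 1L, 1L)
  x0 <- sample.int(W - cs + 1L, 1L)
  img <- img[y0 + seq_len(cs) - 1L, x0 + seq_len(cs) - 1L, , drop = FALSE]
  mask <- mask[y0 + seq_len(cs) - 1L, x0 + seq_len(cs) - 1L]
  if (cs != size) {
    img <- resize_image(img, size, size)
    mask <- resize_mask(mask, size, size)
  }
  if (stats::runif(1) < 0.5) {
    img <- img[rev(seq_len(size)), , , drop = FALSE]
    mask <- mask[rev(seq_len(size)), ]
  }
  if (stats::runif(1) < 0.5) {
    img <- img[, rev(seq_len(size)), , drop = FALSE]
    mask <- mask[, rev(seq_len(size))]
  }
  # brightness / contrast / saturation / hue
  img <- img * stats::runif(1, 1 - jitter, 1 + jitter)
  mu <- mean(img)
  img <- (img - mu) * stats::runif(1, 1 - jitter, 1 + jitter) + mu
  gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  sf <- stats::runif(1, 1 - jitter, 1 + jitter)
  for (ch in 1:3) img[, , ch] <- gray + (img[, , ch] - gray) * sf
  th <- stats::runif(1, -jitter, jitter)
  M <- hue_rotation_matrix(th)
  flat <- matrix(img, ncol = 3)
  img <- array(flat %*% t(M), dim(img))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask)
}

center_pair <- function(img, mask, size) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H != size || W != size) {
    img <- resize_image(img, size, size)
    mask <- resize_mask(mask, size, size)
  }
  list(image = img, mask = mask)
}

# ------------------------------------------------------- batched loss ---

onehot_batch <- function(masks, num_classes = 2) {
  d <- dim(masks)  # (H, W, N)
  oh <- array(0, c(d[1], d[2], num_classes, d[3]))
  oh[, , 1, ] <- 1 - masks
  oh[, , 2, ] <- masks
  oh
}

# Differentiable composite loss for one stage on a batch.
stage_loss_ad <- function(logits, probs, oh, sdl_w, alpha, regional) {
  npix <- prod(dim(oh))  / dim(oh)[3]   # H * W * N
  reg <- if (regional == "ce") {
    ls <- op_logsoftmax_c(logits)
    s_mul(op_dot_const(ls, oh), -1 / npix)
  } else {
    fg <- op_slice_c(probs, 2L)
    inter <- op_dot_const(fg, oh[, , 2, , drop = FALSE])
    tot <- s_add(op_sum(fg), sum(oh[, , 2, ]))
    s_sub(1, s_div(s_mul(inter, 2), s_add(tot, 1e-7)))
  }
  if (alpha > 0) {
    fg <- op_slice_c(probs, 2L)
    sdl <- s_mul(op_dot_const(fg, sdl_w), 1 / npix)
    s_add(s_mul(sdl, alpha), s_mul(reg, 1 - alpha))
  } else {
    reg
  }
}

# --------------------------------------------------------------- fitting ---

#' Fit DSAE-Net to a vessel segmentation dataset
#'
#' The main model-fitting entry point.  Optimises the cascaded dual-stage
#' objective (composite regional + Skeleton Distance Loss on both stage
#' outputs) with Adam under a cosine-annealed learning rate, evaluates the
#' validation AUC at the end of each cycle and retains the best
#' checkpoint.
#'
#' @param data a dataset directory (layout as written by
#'   [make_dataset()]), a [dataset_layout()], or a list with elements
#'   `train` and `val`, each a list of `list(image, mask)` pairs.
#' @param net a [dsae_net()]; default builds the (3, 8) cascade.
#' @param loss a [loss_config()].
#' @param train a [train_config()].
#' @param verbose print per-cycle progress.
#' @return an object of class `"dsae_fit"` with the trained network,
#'   per-epoch history, and the retained best checkpoint.
#' @export
dsae_fit <- function(data, net = NULL, loss = loss_config(),
                     train = train_config(), verbose = TRUE) {
  pairs <- resolve_pairs(data)
  if (!length(pairs$train)) stop("empty training split")
  if (!length(pairs$val)) stop("empty validation split")
  if (is.null(net)) net <- dsae_net(seed = train$seed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(train$seed)

  params <- collect_params(unclass(net))
  opt <- adam_new(params)
  ntr <- length(pairs$train)
  steps <- max(1L, ntr %/% train$batch_size)
  hist <- data.frame(epoch = integer(), lr = numeric(), loss = numeric(),
                     alpha = numeric(), val_auc = numeric(),
                     val_dice = numeric(), val_miou = numeric())
  best <- list(auc = -Inf, state = NULL, cycle = NA_integer_,
               val = NULL)
  sz <- train$input_size

  for (epoch in seq_len(train$epochs)) {
    lr <- lr_at(train, epoch)
    al <- alpha_at(loss, epoch, train$epochs)
    perm <- sample.int(ntr)
    eloss <- 0
    for (s in seq_len(steps)) {
      idx <- perm[((s - 1L) * train$batch_size + 1L):
                    min(ntr, s * train$batch_size)]
      B <- length(idx)
      xb <- array(0, c(sz, sz, dim(pairs$train[[1]]$image)[3], B))
      mb <- array(0, c(sz, sz, B))
      for (j in seq_len(B)) {
        pr <- pairs$train[[idx[j]]]
        aug <- if (train$augment)
          augment_pair(pr$image, pr$mask, sz)
        else center_pair(pr$image, pr$mask, sz)
        xb[, , , j] <- aug$image
        mb[, , j] <- aug$mask
      }
      oh <- onehot_batch(mb, net$num_classes)
      sdl_w <- array(0, c(sz, sz, 1, B))
      if (al > 0)
        for (j in seq_len(B))
          sdl_w[, , 1, j] <- suppressWarnings(sdl_weight_map(mb[, , j]))
      tape_begin()
      out <- forward_dsae(net, xb, training = TRUE)
      l_mid <- stage_loss_ad(out$logits_mid, out$mid, oh, sdl_w, al,
                             loss$regional)
      l_end <- stage_loss_ad(out$logits_end, out$end, oh, sdl_w, al,
                             loss$regional)
      total <- s_add(s_mul(l_mid, loss$w0), s_mul(l_end, loss$w1))
      backward(total)
      tape_end()
      adam_step(opt, lr)
      eloss <- eloss + total$val
    }
    row <- data.frame(epoch = epoch, lr = lr, loss = eloss / steps,
                      alpha = al, val_auc = NA_real_,
                      val_dice = NA_real_, val_miou = NA_real_)
    if (epoch %% train$epochs_per_cycle == 0) {
      vm <- validate_net(net, pairs$val, sz)
      row$val_auc <- vm$auc; row$val_dice <- vm$dice
      row$val_miou <- vm$miou
      if (!is.na(vm$auc) && vm$auc > best$auc) {
        best <- list(auc = vm$auc, state = get_state(net),
                     cycle = epoch %/% train$epochs_per_cycle, val = vm)
      }
      if (verbose)
        message(sprintf(
          "epoch %3d  lr %.2e  loss %.4f  val AUC %.4f dice %.4f",
          epoch, lr, row$loss, vm$auc, vm$dice))
    }
    hist <- rbind(hist, row)
  }
  if (!is.null(best$state)) set_state(net, best$state)
  structure(list(net = net, history = hist, best = best,
                 loss_config = loss, train_config = train,
                 n_train = ntr, n_val = length(pairs$val)),
            class = "dsae_fit")
}

resolve_pairs <- function(data) {
  if (is.character(data)) data <- dataset_layout(data)
  if (inherits(data, "dataset_layout")) {
    tr <- load_pairs(data, "train")
    vl <- if ("val" %in% data$splits) load_pairs(data, "val") else list()
    return(list(train = tr, val = vl))
  }
  stopifnot(is.list(data))
  list(train = data$train, val = data$val)
}

# Validation metrics (mean over images) at native image size.
validate_net <- function(net, pairs, size) {
  aucs <- dices <- mious <- numeric(0)
  for (pr in pairs) {
    p <- predict_prob(net, pr$image)
    m <- seg_metrics(p$end, pr$mask)
    aucs <- c(aucs, m$auc); dices <- c(dices, m$dice)
    mious <- c(mious, m$miou)
  }
  list(auc = mean(aucs, na.rm = TRUE), dice = mean(dices),
       miou = mean(mious))
}

# -------------------------------------------------------------- inference ---

pad_to_multiple <- function(img, mult) {
  H <- dim(img)[1]; W <- dim(img)[2]
  H2 <- ceiling(H / mult) * mult
  W2 <- ceiling(W / mult) * mult
  if (H2 == H && W2 == W) return(list(img = img, H = H, W = W))
  ridx <- c(seq_len(H), rev(seq_len(H)))[seq_len(H2)]   # reflection
  cidx <- c(seq_len(W), rev(seq_len(W)))[seq_len(W2)]
  list(img = img[ridx, cidx, , drop = FALSE], H = H, W = W)
}

# Forward one image; returns list(mid, end) foreground-probability maps.
predict_prob <- function(net, image) {
  mult <- 2^(net$k - 1)
  pd <- pad_to_multiple(image, mult)
  x <- array(pd$img, c(dim(pd$img)[1], dim(pd$img)[2], dim(pd$img)[3], 1))
  out <- forward_dsae(net, x, training = FALSE)
  fg_end <- out$end$val[seq_len(pd$H), seq_len(pd$W), 2, 1]
  fg_mid <- out$mid$val[seq_len(pd$H), seq_len(pd$W), 2, 1]
  list(mid = matrix(fg_mid, pd$H, pd$W), end = matrix(fg_end, pd$H, pd$W))
}

#' Predict with flip test-time augmentation
#'
#' Averages the foreground-probability maps over the four flip variants
#' (identity, horizontal, vertical, both), each inverse-transformed back
#' to the original frame before averaging.
#'
#' @param net a trained [dsae_net()].
#' @param image (H, W, 3) array in \[0, 1\].
#' @param tta average over flips (set `FALSE` for a single forward pass).
#' @return foreground-probability matrix (H, W).
#' @export
tta_predict <- function(net, image, tta = TRUE) {
  if (!tta) return(predict_prob(net, image)$end)
  H <- dim(image)[1]; W <- dim(image)[2]
  acc <- matrix(0, H, W)
  for (fh in c(FALSE, TRUE))
    for (fv in c(FALSE, TRUE)) {
      img <- image
      if (fh) img <- img[rev(seq_len(H)), , , drop = FALSE]
      if (fv) img <- img[, rev(seq_len(W)), , drop = FALSE]
      p <- predict_prob(net, img)$end
      if (fh) p <- p[rev(seq_len(H)), ]
      if (fv) p <- p[, rev(seq_len(W))]
      acc <- acc + p
    }
  acc / 4
}

# ---------------------------------------------------------- SDL ablation ---

#' Loss-function ablation: regional losses with and without SDL
#'
#' Trains the cascade under cross-entropy and Dice regional losses, each
#' with and without the Skeleton Distance Loss term, under identical
#' seeds, and records the validation mean-IoU trajectory of every run.
#' With `alphas` given, runs an alpha sensitivity sweep instead.
#'
#' @param data as in [dsae_fit()].
#' @param train a [train_config()].
#' @param net_args arguments passed to [dsae_net()].
#' @param alpha_max SDL weight used by the `+SDL` variants.
#' @param alphas optional numeric vector for an alpha sweep (e.g.
#'   `c(0, 0.3, 0.7, 1.0)`); values above 0.7 run in sensitivity mode.
#' @param verbose print progress.
#' @return object of class `"sdl_ablation"`: per-variant histories and
#'   epoch-to-epoch variance statistics of the validation mIoU curves.
#' @export
run_sdl_ablation <- function(data, train = train_config(),
                             net_args = list(), alpha_max = 0.7,
                             alphas = NULL, verbose = FALSE) {
  variants <- if (is.null(alphas)) {
    list(ce = loss_config(0, "ce"),
         `ce+sdl` = loss_config(alpha_max, "ce"),
         dice = loss_config(0, "dice"),
         `dice+sdl` = loss_config(alpha_max, "dice"))
  } else {
    vs <- lapply(alphas, function(a)
      loss_config(a, "ce", sensitivity = a > 0.7))
    names(vs) <- paste0("alpha=", format(alphas))
    vs
  }
  pairs <- resolve_pairs(data)
  runs <- list()
  for (nm in names(variants)) {
    net <- do.call(dsae_net, c(net_args, list(seed = train$seed)))
    fit <- dsae_fit(pairs, net = net, loss = variants[[nm]],
                    train = train, verbose = verbose)
    curve <- fit$history$val_miou[!is.na(fit$history$val_miou)]
    runs[[nm]] <- list(history = fit$history, miou_curve = curve,
                       final_miou = curve[length(curve)],
                       curve_var = stats::var(diff(curve)),
                       best = fit$best)
  }
  structure(list(runs = runs, train_config = train), class = "sdl_ablation")
}
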