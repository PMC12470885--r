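# Differentiable operations on dtensors.  Values are arrays with
# dim (H, W, C, N); scalars are length-1 numerics.

val_of <- function(x) if (is_dtensor(x)) x$val else x

# ----------------------------------------------------------- convolution ---

op_conv <- function(x, w, b = NULL, pad = NULL, groups = 1L) {
  k <- dim(w$val)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  bv <- if (is.null(b)) NULL else as.numeric(b$val)
  y <- conv2d_fw(x$val, w$val, bv, pad, groups)
  parents <- list(x, w)
  if (!is.null(b)) parents <- c(parents, list(b))
  new_dtensor(y, parents, function(g) {
    gr <- conv2d_bw(x$val, w$val, g, pad, groups, !is.null(b))
    accum_grad(x, gr$dx)
    accum_grad(w, gr$dw)
    if (!is.null(b)) accum_grad(b, gr$db)
  })
}

op_convt2 <- function(x, w, b = NULL) {
  bv <- if (is.null(b)) NULL else as.numeric(b$val)
  y <- convt2_fw(x$val, w$val, bv)
  parents <- list(x, w)
  if (!is.null(b)) parents <- c(parents, list(b))
  new_dtensor(y, parents, function(g) {
    gr <- convt2_bw(x$val, w$val, g, !is.null(b))
    accum_grad(x, gr$dx)
    accum_grad(w, gr$dw)
    if (!is.null(b)) accum_grad(b, gr$db)
  })
}

# ----------------------------------------------------- pooling / resizing ---

op_maxpool2 <- function(x) {
  d <- dim(x$val)
  r <- maxpool2_fw(x$val)
  new_dtensor(r$y, list(x), function(g) {
    accum_grad(x, maxpool2_bw(g, r$idx, d[1], d[2]))
  })
}

op_up2 <- function(x) {
  d <- dim(x$val)
  y <- resize_bilinear_fw(x$val, 2L * d[1], 2L * d[2])
  new_dtensor(y, list(x), function(g) {
    accum_grad(x, resize_bilinear_bw(g, d[1], d[2]))
  })
}

# --------------------------------------------------------------- batchnorm ---

# layer is the bn layer environment (running stats are updated in place).
op_bn <- function(x, layer, training) {
  r <- bn_fw(x$val, as.numeric(layer$gamma$val), as.numeric(layer$beta$val),
             layer$rmean, layer$rvar, layer$momentum, training, layer$eps)
  if (training) {
    layer$rmean <- r$rmean
    layer$rvar <- r$rvar
  }
  mu <- r$mean; invstd <- r$invstd
  new_dtensor(r$y, list(x, layer$gamma, layer$beta), function(g) {
    gr <- bn_bw(x$val, as.numeric(layer$gamma$val), mu, invstd, g)
    accum_grad(x, gr$dx)
    accum_grad(layer$gamma, gr$dgamma)
    accum_grad(layer$beta, gr$dbeta)
  })
}

# ------------------------------------------------------------- elementwise ---

op_relu <- function(x) {
  y <- relu_fw(x$val)
  new_dtensor(y, list(x), function(g) accum_grad(x, relu_bw(x$val, g)))
}

op_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$val))
  new_dtensor(y, list(x), function(g) accum_grad(x, g * y * (1 - y)))
}

op_add <- function(a, b) {
  new_dtensor(a$val + b$val, list(a, b), function(g) {
    accum_grad(a, g)
    accum_grad(b, g)
  })
}

op_mul <- function(a, b) {
  new_dtensor(a$val * b$val, list(a, b), function(g) {
    accum_grad(a, g * b$val)
    accum_grad(b, g * a$val)
  })
}

# ------------------------------------------------------- channel plumbing ---

op_concat_c <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$val))
  cs <- vapply(ds, `[`, 0, 3L)
  d <- ds[[1]]
  y <- array(0, c(d[1], d[2], sum(cs), d[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    y[, , off + seq_len(cs[i]), ] <- xs[[i]]$val
    off <- off + cs[i]
  }
  new_dtensor(y, xs, function(g) {
    off <- 0L
    for (i in seq_along(xs)) {
      accum_grad(xs[[i]],
                 array(g[, , off + seq_len(cs[i]), , drop = FALSE],
                       ds[[i]]))
      off <- off + cs[i]
    }
  })
}

op_slice_c <- function(x, channels) {
  d <- dim(x$val)
  y <- x$val[, , channels, , drop = FALSE]
  new_dtensor(y, list(x), function(g) {
    gx <- array(0, d)
    gx[, , channels, ] <- g
    accum_grad(x, gx)
  })
}

# --------------------------------------------------------------- softmax ---

# Softmax over the channel dimension.
op_softmax_c <- function(x) {
  d <- dim(x$val)
  v <- aperm(x$val, c(1, 2, 4, 3))
  dim(v) <- c(d[1] * d[2] * d[4], d[3])
  m <- v[, 1]
  if (d[3] > 1) for (j in 2:d[3]) m <- pmax(m, v[, j])
  e <- exp(v - m)
  s <- rowSums(e)
  p <- e / s
  y <- p
  dim(y) <- c(d[1], d[2], d[4], d[3])
  y <- aperm(y, c(1, 2, 4, 3))
  new_dtensor(y, list(x), function(g) {
    gm <- aperm(g, c(1, 2, 4, 3))
    dim(gm) <- c(d[1] * d[2] * d[4], d[3])
    gp <- gm * p
    dot <- rowSums(gp)
    dx <- gp - p * dot
    dim(dx) <- c(d[1], d[2], d[4], d[3])
    accum_grad(x, aperm(dx, c(1, 2, 4, 3)))
  })
}

# Log-softmax over the channel dimension (for cross-entropy).
op_logsoftmax_c <- function(x) {
  d <- dim(x$val)
  v <- aperm(x$val, c(1, 2, 4, 3))
  dim(v) <- c(d[1] * d[2] * d[4], d[3])
  m <- v[, 1]
  if (d[3] > 1) for (j in 2:d[3]) m <- pmax(m, v[, j])
  e <- exp(v - m)
  lse <- m + log(rowSums(e))
  y <- v - lse
  p <- exp(y)
  out <- y
  dim(out) <- c(d[1], d[2], d[4], d[3])
  out <- aperm(out, c(1, 2, 4, 3))
  new_dtensor(out, list(x), function(g) {
    gm <- aperm(g, c(1, 2, 4, 3))
    dim(gm) <- c(d[1] * d[2] * d[4], d[3])
    dx <- gm - p * rowSums(gm)
    dim(dx) <- c(d[1], d[2], d[4], d[3])
    accum_grad(x, aperm(dx, c(1, 2, 4, 3)))
  })
}

# Softmax over window positions for contextual attention: channels are laid
# out as j + k2 * c; normalise over the k2 window positions per channel c.
op_softmax_window <- function(x, k2) {
  y <- softmax_window_fw(x$val, k2)
  new_dtensor(y, list(x), function(g) {
    accum_grad(x, softmax_window_bw(y, g, k2))
  })
}

# Attention-weighted aggregation of values over a k x k window.
op_cot_agg <- function(v, att, k) {
  y <- cot_agg_fw(v$val, att$val, k)
  new_dtensor(y, list(v, att), function(g) {
    gr <- cot_agg_bw(v$val, att$val, g, k)
    accum_grad(v, gr$dv)
    accum_grad(att, gr$datt)
  })
}

# --------------------------------------------- directional pooling (CAG) ---

# Mean over the W axis -> (H, 1, C, N)
op_mean_w <- function(x) {
  d <- dim(x$val)
  y <- rowMeans(aperm(x$val, c(1, 3, 4, 2)), dims = 3)
  dim(y) <- c(d[1], 1L, d[3], d[4])
  new_dtensor(y, list(x), function(g) {
    gx <- array(g / d[2], c(d[1], 1L, d[3], d[4]))
    accum_grad(x, array(gx[, rep(1, d[2]), , , drop = FALSE], d))
  })
}

# Mean over the H axis -> (1, W, C, N)
op_mean_h <- function(x) {
  d <- dim(x$val)
  y <- rowMeans(aperm(x$val, c(2, 3, 4, 1)), dims = 3)
  dim(y) <- c(1L, d[2], d[3], d[4])
  new_dtensor(y, list(x), function(g) {
    gx <- array(g / d[1], c(1L, d[2], d[3], d[4]))
    accum_grad(x, array(gx[rep(1, d[1]), , , , drop = FALSE], d))
  })
}

# y[h,w,c,n] = x[h,w,c,n] * gh[h,1,c,n] * gw[1,w,c,n]
op_gate_hw <- function(x, gh, gw) {
  d <- dim(x$val)
  if (dim(gh$val)[1] != d[1] || dim(gw$val)[2] != d[2])
    stop("spatial size mismatch between skip and gate")
  GH <- array(gh$val[, rep(1, d[2]), , , drop = FALSE], d)
  GW <- array(gw$val[rep(1, d[1]), , , , drop = FALSE], d)
  y <- x$val * GH * GW
  new_dtensor(y, list(x, gh, gw), function(g) {
    accum_grad(x, g * GH * GW)
    dgh <- rowSums(aperm(g * x$val * GW, c(1, 3, 4, 2)), dims = 3)
    dim(dgh) <- dim(gh$val)
    accum_grad(gh, dgh)
    dgw <- rowSums(aperm(g * x$val * GH, c(2, 3, 4, 1)), dims = 3)
    dim(dgw) <- dim(gw$val)
    accum_grad(gw, dgw)
  })
}

# ------------------------------------------------------ scalar reductions ---

op_sum <- function(x) {
  d <- dim(x$val)
  new_dtensor(sum(x$val), list(x), function(g) {
    accum_grad(x, array(g, d))
  })
}

op_mean <- function(x) {
  d <- dim(x$val)
  n <- length(x$val)
  new_dtensor(sum(x$val) / n, list(x), function(g) {
    accum_grad(x, array(g / n, d))
  })
}

# sum(x * w) for a fixed (non-differentiated) weight array w
op_dot_const <- function(x, w) {
  new_dtensor(sum(x$val * w), list(x), function(g) {
    accum_grad(x, g * w)
  })
}

# -------------------------------------------------------- scalar algebra ---

s_add <- function(a, b) {
  av <- val_of(a); bv <- val_of(b)
  ps <- Filter(is_dtensor, list(a, b))
  new_dtensor(av + bv, ps, function(g) {
    if (is_dtensor(a)) accum_grad(a, g)
    if (is_dtensor(b)) accum_grad(b, g)
  })
}

s_mul <- function(a, b) {
  av <- val_of(a); bv <- val_of(b)
  ps <- Filter(is_dtensor, list(a, b))
  new_dtensor(av * bv, ps, function(g) {
    if (is_dtensor(a)) accum_grad(a, g * bv)
    if (is_dtensor(b)) accum_grad(b, g * av)
  })
}

s_div <- function(a, b) {
  av <- val_of(a); bv <- val_of(b)
  ps <- Filter(is_dtensor, list(a, b))
  new_dtensor(av / bv, ps, function(g) {
    if (is_dtensor(a)) accum_grad(a, g / bv)
    if (is_dtensor(b)) accum_grad(b, -g * av / bv^2)
  })
}

s_sub <- function(a, b) s_add(a, s_mul(b, -1))

# Swap the H and W axes.
op_transpose_hw <- function(x) {
  y <- aperm(x$val, c(2, 1, 3, 4))
  new_dtensor(y, list(x), function(g) {
    accum_grad(x, aperm(g, c(2, 1, 3, 4)))
  })
}

# Concatenate along the H (first) axis.
op_concat_h <- function(xs) {
  ds <- lapply(xs, function(x) dim(x$val))
  hs <- vapply(ds, `[`, 0, 1L)
  d <- ds[[1]]
  y <- array(0, c(sum(hs), d[2], d[3], d[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    y[off + seq_len(hs[i]), , , ] <- xs[[i]]$val
    off <- off + hs[i]
  }
  new_dtensor(y, xs, function(g) {
    off <- 0L
    for (i in seq_along(xs)) {
      accum_grad(xs[[i]],
                 array(g[off + seq_len(hs[i]), , , , drop = FALSE],
                       ds[[i]]))
      off <- off + hs[i]
    }
  })
}

op_slice_h <- function(x, rows) {
  d <- dim(x$val)
  y <- x$val[rows, , , , drop = FALSE]
  new_dtensor(y, list(x), function(g) {
    gx <- array(0, d)
    gx[rows, , , ] <- g
    accum_grad(x, gx)
  })
}

# Softmax over all spatial positions, per channel and image.
op_softmax_spatial <- function(x) {
  d <- dim(x$val)
  v <- x$val
  dim(v) <- c(d[1] * d[2], d[3] * d[4])
  m <- apply(v, 2, max)
  e <- exp(sweep(v, 2, m))
  s <- colSums(e)
  p <- sweep(e, 2, s, "/")
  y <- p
  dim(y) <- d
  new_dtensor(y, list(x), function(g) {
    gm <- g
    dim(gm) <- c(d[1] * d[2], d[3] * d[4])
    gp <- gm * p
    dot <- colSums(gp)
    dx <- gp - sweep(p, 2, dot, "*")
    dim(dx) <- d
    accum_grad(x, dx)
  })
}

# Global average pool -> (1, 1, C, N)
op_mean_hw <- function(x) {
  d <- dim(x$val)
  y <- colMeans(x$val, dims = 2)
  dim(y) <- c(1L, 1L, d[3], d[4])
  new_dtensor(y, list(x), function(g) {
    gg <- array(g / (d[1] * d[2]), c(d[3], d[4]))
    accum_grad(x, array(rep(as.vector(gg), each = d[1] * d[2]), d))
  })
}

# y[h,w,c,n] = x[h,w,c,n] * s[1,1,c,n]
op_chan_mul <- function(x, s) {
  d <- dim(x$val)
  S <- array(rep(as.vector(s$val), each = d[1] * d[2]), d)
  y <- x$val * S
  new_dtensor(y, list(x, s), function(g) {
    accum_grad(x, g * S)
    ds <- colSums(g * x$val, dims = 2)
    dim(ds) <- dim(s$val)
    accum_grad(s, ds)
  })
}

# Radix-2 softmax over a (1, 1, 2C, N) excitation: channels are split into
# two halves and normalised pairwise; returns the two weight tensors.
op_softmax_radix2 <- function(x) {
  d <- dim(x$val)
  C <- d[3] %/% 2L
  a <- x$val[, , seq_len(C), , drop = FALSE]
  b <- x$val[, , C + seq_len(C), , drop = FALSE]
  m <- pmax(a, b)
  ea <- exp(a - m); eb <- exp(b - m)
  s <- ea + eb
  w1v <- ea / s; w2v <- eb / s
  w1 <- new_dtensor(w1v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , seq_len(C), ] <- g * w1v * w2v
    gx[, , C + seq_len(C), ] <- -g * w1v * w2v
    accum_grad(x, gx)
  })
  w2 <- new_dtensor(w2v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , seq_len(C), ] <- -g * w1v * w2v
    gx[, , C + seq_len(C), ] <- g * w1v * w2v
    accum_grad(x, gx)
  })
  list(w1 = w1, w2 = w2)
}
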