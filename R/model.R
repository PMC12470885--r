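# DSAE-Net: dual-stage cascade of attention-enhanced encoder-decoders.
#
# The architecture family is governed by the tuple (k, m): k resolution
# levels with m * 2^i channels at level i.  Encoder levels use the CMFA
# residual unit (channel-split + contextual-transformer attention);
# decoder levels use coordinate-attention-gated skip fusion followed by a
# residual convolution block.  Block internals that the architecture
# family leaves open are frozen in `dsae_design()` and were calibrated
# jointly against the printed parameter/operation grid of the (k, m)
# family; see the methods vignette.

#' Frozen block-internal design constants
#'
#' These constants pin down every block detail the (k, m) parameterisation
#' leaves open: the contextual-transformer internals, the width of the
#' attention bottlenecks, the decoder block depth, and the up-sampling
#' operator.  A single set of values reproduces the printed parameter
#' grid of the whole architecture family; they are not meant to be tuned.
#'
#' @return named list of design constants.
#' @export
dsae_design <- function() {
  list(
    cot_groups    = 2L,     # groups of the contextual key convolution
    cot_factor    = 1L,     # attention bottleneck reduction (1 = width 2d)
    cot_full      = FALSE,  # attention map of width d, spatial softmax
    cot_attn_bn   = FALSE,  # no BN inside the attention embed
    cot_attn_bias = FALSE,  # no bias on the final attention projection
    cot_se        = 0L,     # no squeeze-excitation fusion stage
    attn_floor    = 8L,     # min width of the attention bottleneck
    attn_cap      = Inf,    # max width of the attention bottleneck
    cmfa_bias     = FALSE,  # no biases on CMFA projection/fusion convs
    inner_bn      = FALSE,  # no BN after the two 3x3 convs in CMFA
    short         = FALSE,  # no 1x1 shortcut when in/out widths differ
    fuse_k        = 1L,     # kernel of the CMFA fusion conv
    up            = "tr",   # 2x2 stride-2 transposed-conv upsampling
    up_pre        = FALSE,  # (only relevant for bilinear upsampling)
    dec_cmfa      = TRUE,   # decoder residual block is a CMFA pair
    rc_convs      = 1L,     # (plain decoder fallback depth)
    stem          = FALSE,  # no full-resolution stem conv
    cag_in        = "gate", # CA computed on the gate (upsampled) signal
    cag_r         = 2L,     # CA bottleneck reduction
    cag_floor     = 4L,     # min CA bottleneck width
    cag_cap       = 32L,    # max CA bottleneck width
    cag_pre       = TRUE,   # 3x3 mixing conv on the gate before pooling
    out_k         = 1L,     # kernel of the classification head
    s2x           = 1L,     # stage-2 extra channels (fg probability)
    bn_macs       = TRUE    # count batch-norm in the operation profile
  )
}

clampi <- function(v, lo, hi) max(lo, min(v, hi))

# ------------------------------------------------------------------ CoT ---

build_cot <- function(d, dg) {
  g <- dg$cot_groups
  g <- max(1L, min(g, d))
  while (d %% g != 0) g <- g - 1L
  mid <- as.integer(clampi(max(1, (2 * d) %/% dg$cot_factor),
                           dg$attn_floor, dg$attn_cap))
  att_out <- if (dg$cot_full) 9L * d else d
  mod <- list(type = "cot", d = d,
              key = mk_conv(3, d, d, bias = FALSE, groups = g),
              key_bn = mk_bn(d),
              value = mk_conv(1, d, d, bias = FALSE),
              value_bn = mk_bn(d),
              attn1 = mk_conv(1, 2 * d, mid, bias = FALSE),
              attn1_bn = if (dg$cot_attn_bn) mk_bn(mid),
              attn2 = mk_conv(1, mid, att_out, bias = dg$cot_attn_bias))
  if (dg$cot_se > 0) {
    ach <- as.integer(max(dg$cot_se, (2 * d) %/% 4))
    mod$se1 <- mk_conv(1, d, ach, bias = TRUE)
    mod$se_bn <- mk_bn(ach)
    mod$se2 <- mk_conv(1, ach, 2 * d, bias = TRUE)
  }
  mod
}

fw_cot <- function(ctx, x, mod, dg) {
  k1 <- apply_relu(ctx, apply_bn(ctx, apply_conv(ctx, x, mod$key),
                                 mod$key_bn))
  v <- apply_bn(ctx, apply_conv(ctx, x, mod$value), mod$value_bn)
  y <- apply_concat(ctx, list(k1, x))
  a <- apply_conv(ctx, y, mod$attn1)
  if (!is.null(mod$attn1_bn)) a <- apply_bn(ctx, a, mod$attn1_bn)
  a <- apply_relu(ctx, a)
  a <- apply_conv(ctx, a, mod$attn2)
  if (ctx$count) {
    dyn <- c(a[1], a[2], mod$d, a[4])
  } else if (dg$cot_full) {
    att <- op_softmax_window(a, 9L)
    dyn <- op_cot_agg(v, att, 3L)
  } else {
    att <- op_softmax_spatial(a)
    dyn <- op_mul(v, att)
  }
  out <- apply_add(ctx, k1, dyn)
  if (!is.null(mod$se1)) {
    if (ctx$count) {
      force(out)
      # squeeze-excitation works on pooled 1x1 maps
      d <- mod$d
      ach <- mod$se1$cout
      ctx$macs <- ctx$macs + d * ach + ach * 2 * d
      return(out)
    }
    s <- op_mean_hw(out)
    a2 <- apply_relu(ctx, apply_bn(ctx, apply_conv(ctx, s, mod$se1),
                                   mod$se_bn))
    a2 <- apply_conv(ctx, a2, mod$se2)
    ws <- op_softmax_radix2(a2)
    out <- op_add(op_chan_mul(k1, ws$w1), op_chan_mul(dyn, ws$w2))
  }
  out
}

# ----------------------------------------------------------------- CMFA ---

build_cmfa <- function(cin, cout, dg) {
  d <- max(1L, as.integer(ceiling(cout / 2)))
  list(type = "cmfa", d = d, cin = cin, cout = cout,
       proj = mk_conv(1, cin, 2L * d, bias = dg$cmfa_bias),
       conv1 = mk_conv(3, d, d, bias = dg$cmfa_bias),
       conv2 = mk_conv(3, d, d, bias = dg$cmfa_bias),
       bn1 = if (dg$inner_bn) mk_bn(d),
       bn2 = if (dg$inner_bn) mk_bn(d),
       cot = build_cot(d, dg),
       fuse = mk_conv(dg$fuse_k, 3L * d, cout, bias = dg$cmfa_bias))
}

fw_cmfa <- function(ctx, x, mod, dg) {
  d <- mod$d
  p <- apply_conv(ctx, x, mod$proj)
  f1 <- apply_slice(ctx, p, seq_len(d))
  f2 <- apply_slice(ctx, p, d + seq_len(d))
  z <- apply_conv(ctx, f2, mod$conv1)
  if (!is.null(mod$bn1)) z <- apply_bn(ctx, z, mod$bn1)
  z <- apply_relu(ctx, z)
  z <- apply_conv(ctx, z, mod$conv2)
  if (!is.null(mod$bn2)) z <- apply_bn(ctx, z, mod$bn2)
  z <- apply_relu(ctx, z)
  f3 <- fw_cot(ctx, z, mod$cot, dg)
  cc <- apply_concat(ctx, list(f1, f2, f3))
  apply_conv(ctx, cc, mod$fuse)
}

apply_slice <- function(ctx, x, channels) {
  force(x)
  if (ctx$count) return(c(x[1], x[2], length(channels), x[4]))
  op_slice_c(x, channels)
}

# -------------------------------------------------------- residual units ---

build_enc_unit <- function(cin, cout, dg, use_cmfa) {
  if (use_cmfa) {
    list(type = "enc_cmfa", cin = cin, cout = cout,
         m1 = build_cmfa(cin, cout, dg), bn1 = mk_bn(cout),
         m2 = build_cmfa(cout, cout, dg), bn2 = mk_bn(cout),
         sc = if (dg$short && cin != cout)
                mk_conv(1, cin, cout, bias = FALSE))
  } else {
    list(type = "enc_plain", cin = cin, cout = cout,
         c1 = mk_conv(3, cin, cout, bias = FALSE), bn1 = mk_bn(cout),
         c2 = mk_conv(3, cout, cout, bias = FALSE), bn2 = mk_bn(cout))
  }
}

fw_enc_unit <- function(ctx, x, mod, dg) {
  if (mod$type %in% c("enc_cmfa", "dec_cmfa")) {
    b <- apply_relu(ctx, apply_bn(ctx, fw_cmfa(ctx, x, mod$m1, dg),
                                  mod$bn1))
    b <- apply_bn(ctx, fw_cmfa(ctx, b, mod$m2, dg), mod$bn2)
    if (!is.null(mod$sc)) {
      b <- apply_add(ctx, b, apply_conv(ctx, x, mod$sc))
    } else if (mod$cin == mod$cout) {
      b <- apply_add(ctx, b, x)
    }
    apply_relu(ctx, b)
  } else {
    b <- apply_relu(ctx, apply_bn(ctx, apply_conv(ctx, x, mod$c1),
                                  mod$bn1))
    apply_relu(ctx, apply_bn(ctx, apply_conv(ctx, b, mod$c2), mod$bn2))
  }
}

build_dec_unit <- function(cin, cout, dg, use_cmfa, use_cag) {
  if (use_cag && use_cmfa && dg$dec_cmfa) {
    mod <- build_enc_unit(cin, cout, dg, TRUE)
    mod$type <- "dec_cmfa"
    return(mod)
  }
  if (use_cag) {
    convs <- list(mk_conv(3, cin, cout, bias = FALSE))
    bns <- list(mk_bn(cout))
    if (dg$rc_convs > 1)
      for (i in seq_len(dg$rc_convs - 1L)) {
        convs[[i + 1L]] <- mk_conv(3, cout, cout, bias = FALSE)
        bns[[i + 1L]] <- mk_bn(cout)
      }
    list(type = "dec_res", cin = cin, cout = cout, convs = convs, bns = bns,
         sc = if (dg$short) mk_conv(1, cin, cout, bias = FALSE))
  } else {
    list(type = "dec_plain", cin = cin, cout = cout,
         c1 = mk_conv(3, cin, cout, bias = FALSE), bn1 = mk_bn(cout),
         c2 = mk_conv(3, cout, cout, bias = FALSE), bn2 = mk_bn(cout))
  }
}

fw_dec_unit <- function(ctx, x, mod, dg) {
  if (mod$type == "dec_cmfa") return(fw_enc_unit(ctx, x, mod, dg))
  if (mod$type == "dec_res") {
    b <- x
    for (i in seq_along(mod$convs)) {
      b <- apply_bn(ctx, apply_conv(ctx, b, mod$convs[[i]]), mod$bns[[i]])
      if (i < length(mod$convs)) b <- apply_relu(ctx, b)
    }
    if (!is.null(mod$sc)) b <- apply_add(ctx, b, apply_conv(ctx, x, mod$sc))
    apply_relu(ctx, b)
  } else {
    b <- apply_relu(ctx, apply_bn(ctx, apply_conv(ctx, x, mod$c1),
                                  mod$bn1))
    apply_relu(ctx, apply_bn(ctx, apply_conv(ctx, b, mod$c2), mod$bn2))
  }
}

# ------------------------------------------------------------------ CAG ---

build_cag <- function(skip_c, gate_c, dg) {
  cin <- if (dg$cag_in == "concat") skip_c + gate_c else gate_c
  mid <- as.integer(clampi(if (dg$cag_r > 0) cin %/% dg$cag_r else cin,
                           dg$cag_floor, dg$cag_cap))
  list(type = "cag", skip_c = skip_c, gate_c = gate_c, cin = cin,
       pre = if (dg$cag_pre) mk_conv(3, cin, cin, bias = FALSE),
       pre_bn = if (dg$cag_pre) mk_bn(cin),
       squeeze = mk_conv(1, cin, mid, bias = FALSE),
       squeeze_bn = mk_bn(mid),
       gate_h = mk_conv(1, mid, skip_c, bias = TRUE),
       gate_w = mk_conv(1, mid, skip_c, bias = TRUE))
}

fw_cag <- function(ctx, skip, gate, mod, dg) {
  sig <- if (dg$cag_in == "concat") apply_concat(ctx, list(skip, gate))
         else gate
  if (!is.null(mod$pre))
    sig <- apply_relu(ctx, apply_bn(ctx, apply_conv(ctx, sig, mod$pre),
                                    mod$pre_bn))
  if (ctx$count) {
    H <- sig[1]; W <- sig[2]
    strip <- c(H + W, 1, sig[3], sig[4])
    strip <- apply_conv(ctx, strip, mod$squeeze)
    strip <- apply_bn(ctx, strip, mod$squeeze_bn)
    hpart <- c(H, 1, strip[3], strip[4])
    wpart <- c(W, 1, strip[3], strip[4])
    apply_conv(ctx, hpart, mod$gate_h)
    apply_conv(ctx, wpart, mod$gate_w)
    return(apply_concat(ctx, list(skip, gate)))
  }
  H <- dim(sig$val)[1]; W <- dim(sig$val)[2]
  xh <- op_mean_w(sig)                       # (H, 1, c, N)
  xw <- op_transpose_hw(op_mean_h(sig))      # (W, 1, c, N)
  strip <- op_concat_h(list(xh, xw))         # (H + W, 1, c, N)
  strip <- apply_relu(ctx, apply_bn(ctx, apply_conv(ctx, strip,
                                                    mod$squeeze),
                                    mod$squeeze_bn))
  hpart <- op_slice_h(strip, seq_len(H))
  wpart <- op_slice_h(strip, H + seq_len(W))
  gh <- apply_sigmoid(ctx, apply_conv(ctx, hpart, mod$gate_h))
  gw <- apply_sigmoid(ctx, apply_conv(ctx, op_transpose_hw(wpart),
                                      mod$gate_w))
  gated <- op_gate_hw(skip, gh, gw)
  op_concat_c(list(gated, gate))
}

# ---------------------------------------------------------------- stages ---

build_stage <- function(k, m, in_channels, num_classes, dg,
                        use_cmfa = TRUE, use_cag = TRUE) {
  C <- as.integer(m * 2^(0:(k - 1)))
  enc <- vector("list", k)
  prev <- in_channels
  stem <- NULL
  if (dg$stem) {
    stem <- list(conv = mk_conv(3, in_channels, m, bias = FALSE),
                 bn = mk_bn(m))
    prev <- m
  }
  for (i in seq_len(k)) {
    enc[[i]] <- build_enc_unit(prev, C[i], dg, use_cmfa)
    prev <- C[i]
  }
  dec <- vector("list", k - 1)
  for (i in seq(k - 1, 1)) {            # decoder level i (1-based)
    up <- switch(dg$up,
      b1 = mk_conv(1, C[i + 1], C[i], bias = TRUE),
      b3 = mk_conv(3, C[i + 1], C[i], bias = TRUE),
      tr = mk_convt2(C[i + 1], C[i], bias = TRUE),
      bl = NULL)
    u_c <- if (dg$up == "bl") C[i + 1] else C[i]
    cag <- if (use_cag) build_cag(C[i], u_c, dg)
    unit <- if (use_cag)
      build_dec_unit(C[i] + u_c, C[i], dg, use_cmfa, TRUE)
    else
      build_dec_unit(C[i] + u_c, C[i], dg, use_cmfa, FALSE)
    dec[[i]] <- list(up = up, cag = cag, unit = unit)
  }
  out <- mk_conv(dg$out_k, C[1], num_classes, bias = TRUE)
  list(k = k, m = m, C = C, in_channels = in_channels,
       num_classes = num_classes, stem = stem, enc = enc, dec = dec,
       out = out, use_cmfa = use_cmfa, use_cag = use_cag)
}

fw_stage <- function(ctx, x, st, dg) {
  if (!is.null(st$stem))
    x <- apply_relu(ctx, apply_bn(ctx, apply_conv(ctx, x, st$stem$conv),
                                  st$stem$bn))
  skips <- vector("list", st$k)
  for (i in seq_len(st$k)) {
    if (i > 1) x <- apply_pool(ctx, x)
    x <- fw_enc_unit(ctx, x, st$enc[[i]], dg)
    skips[[i]] <- x
  }
  for (i in seq(st$k - 1, 1)) {
    lv <- st$dec[[i]]
    if (dg$up == "tr") {
      x <- apply_convt2(ctx, x, lv$up)
    } else {
      if (dg$up_pre && !is.null(lv$up)) {
        x <- apply_conv(ctx, x, lv$up)
        x <- apply_up2(ctx, x)
      } else {
        x <- apply_up2(ctx, x)
        if (!is.null(lv$up)) x <- apply_conv(ctx, x, lv$up)
      }
    }
    merged <- if (st$use_cag)
      fw_cag(ctx, skips[[i]], x, lv$cag, dg)
    else
      apply_concat(ctx, list(skips[[i]], x))
    x <- fw_dec_unit(ctx, merged, lv$unit, dg)
  }
  apply_conv(ctx, x, st$out)
}

# -------------------------------------------------------------- networks ---

#' Build a single-stage CAE-UNet
#'
#' One attention-enhanced encoder-decoder from the (k, m) family: k
#' resolution levels, `m * 2^i` channels at level i, CMFA residual units
#' in the encoder, coordinate-attention-gated skip fusion in the decoder,
#' and a 1x1 classification head.
#'
#' @param k network depth (number of resolution levels, >= 2).
#' @param m channel count of the top level (>= 1).
#' @param in_channels input image channels (3 for RGB fundus).
#' @param num_classes output classes (2: vessel / background).
#' @param cmfa,cag ablation switches: replace the CMFA units by plain
#'   double convolutions and/or remove the coordinate attention gates.
#' @param seed seed for the weight initialisation.
#' @return object of class `"cae_unet"`.
#' @export
cae_unet <- function(k = 3, m = 8, in_channels = 3, num_classes = 2,
                     cmfa = TRUE, cag = TRUE, seed = 1) {
  if (k < 2) stop("depth k must be at least 2")
  if (m < 1) stop("top width m must be at least 1")
  dg <- dsae_design()
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  st <- build_stage(k, m, in_channels, num_classes, dg, cmfa, cag)
  structure(list(stage = st, k = k, m = m, in_channels = in_channels,
                 num_classes = num_classes, design = dg, seed = seed),
            class = "cae_unet")
}

#' Build the dual-stage DSAE-Net cascade
#'
#' Two independent CAE-UNets: the first consumes the raw image; the second
#' consumes the image concatenated with the stage-1 foreground probability
#' map and refines the prediction.  Both stage outputs are supervised
#' during training; inference keeps the refined stage-2 output.
#'
#' @inheritParams cae_unet
#' @param stage2_extra channels appended to the stage-2 input (the
#'   foreground-probability channels handed over from stage 1).
#' @return object of class `"dsae_net"`.
#' @export
dsae_net <- function(k = 3, m = 8, in_channels = 3, num_classes = 2,
                     stage2_extra = 1, cmfa = TRUE, cag = TRUE, seed = 1) {
  if (k < 2) stop("depth k must be at least 2")
  if (m < 1) stop("top width m must be at least 1")
  dg <- dsae_design()
  dg$s2x <- as.integer(stage2_extra)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  s1 <- build_stage(k, m, in_channels, num_classes, dg, cmfa, cag)
  s2 <- build_stage(k, m, in_channels + dg$s2x, num_classes, dg, cmfa, cag)
  structure(list(stage1 = s1, stage2 = s2, k = k, m = m,
                 in_channels = in_channels, num_classes = num_classes,
                 stage2_extra = dg$s2x, design = dg, seed = seed,
                 cmfa = cmfa, cag = cag),
            class = "dsae_net")
}

# Forward pass.  x: (H, W, C, N) array.  Returns dtensors when a tape is
# active, otherwise plain arrays.  `mid`/`end` are softmax probability
# maps; the logits are returned alongside for the loss.
forward_dsae <- function(net, x, training = FALSE) {
  ctx <- new_run_ctx(training)
  dg <- net$design
  xt <- if (is_dtensor(x)) x else ad_const(x)
  l1 <- fw_stage(ctx, xt, net$stage1, dg)
  p1 <- op_softmax_c(l1)
  nfg <- net$stage2_extra
  fg <- op_slice_c(p1, net$num_classes + 1 - seq_len(nfg))
  x2 <- op_concat_c(list(xt, fg))
  l2 <- fw_stage(ctx, x2, net$stage2, dg)
  p2 <- op_softmax_c(l2)
  list(mid = p1, end = p2, logits_mid = l1, logits_end = l2)
}

forward_cae <- function(net, x, training = FALSE) {
  ctx <- new_run_ctx(training)
  xt <- if (is_dtensor(x)) x else ad_const(x)
  l <- fw_stage(ctx, xt, net$stage, net$design)
  list(logits = l, prob = op_softmax_c(l))
}

# ------------------------------------------------------------- baseline ---

#' Classic U-Net baseline
#'
#' The frozen reference construction: double 3x3 convolutions with biases
#' and no batch norm, 2x2 max-pooling, 2x2 transposed-convolution
#' upsampling, skip concatenation, and feature widths `(m / 2) * 2^i`.
#' Under this construction the (5, 64) baseline totals 7.76 M trainable
#' parameters, the reference count the cascade is compared against.
#'
#' @inheritParams cae_unet
#' @export
unet_baseline <- function(k = 5, m = 64, in_channels = 3, num_classes = 2,
                          seed = 1) {
  if (m %% 2 != 0) stop("baseline width m must be even")
  b <- m %/% 2L
  C <- as.integer(b * 2^(0:(k - 1)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  enc <- vector("list", k)
  prev <- in_channels
  for (i in seq_len(k)) {
    enc[[i]] <- list(c1 = mk_conv(3, prev, C[i], bias = TRUE),
                     c2 = mk_conv(3, C[i], C[i], bias = TRUE))
    prev <- C[i]
  }
  dec <- vector("list", k - 1)
  for (i in seq(k - 1, 1)) {
    dec[[i]] <- list(up = mk_convt2(C[i + 1], C[i], bias = TRUE),
                     c1 = mk_conv(3, 2L * C[i], C[i], bias = TRUE),
                     c2 = mk_conv(3, C[i], C[i], bias = TRUE))
  }
  out <- mk_conv(1, C[1], num_classes, bias = TRUE)
  structure(list(k = k, m = m, C = C, enc = enc, dec = dec, out = out,
                 in_channels = in_channels, num_classes = num_classes),
            class = "unet_baseline")
}

fw_unet <- function(ctx, x, net) {
  skips <- vector("list", net$k)
  for (i in seq_len(net$k)) {
    if (i > 1) x <- apply_pool(ctx, x)
    x <- apply_relu(ctx, apply_conv(ctx, x, net$enc[[i]]$c1))
    x <- apply_relu(ctx, apply_conv(ctx, x, net$enc[[i]]$c2))
    skips[[i]] <- x
  }
  for (i in seq(net$k - 1, 1)) {
    x <- apply_convt2(ctx, x, net$dec[[i]]$up)
    x <- apply_concat(ctx, list(skips[[i]], x))
    x <- apply_relu(ctx, apply_conv(ctx, x, net$dec[[i]]$c1))
    x <- apply_relu(ctx, apply_conv(ctx, x, net$dec[[i]]$c2))
  }
  apply_conv(ctx, x, net$out)
}

# ------------------------------------------------------------ profiling ---

collect_params <- function(x) {
  if (is_dtensor(x)) {
    if (isTRUE(x$is_param)) return(list(x))
    return(list())
  }
  if (inherits(x, "bn_layer")) return(list(x$gamma, x$beta))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

#' Count trainable parameters
#'
#' Exact number of trainable scalars (convolution weights and biases,
#' batch-norm scale and shift) of a built network.  Identical across
#' repeated construction with the same configuration.
#'
#' @param net a [dsae_net()], [cae_unet()] or [unet_baseline()] object.
#' @export
count_parameters <- function(net) {
  ps <- collect_params(unclass(net))
  sum(vapply(ps, function(p) length(p$val), 0))
}

#' Count forward-pass operations
#'
#' Exact multiply-accumulate count of one forward pass at the given input
#' size, obtained by running the network's own forward graph in counting
#' mode.  Convention: one fused multiply-accumulate counts as one
#' operation; convolutions (including their biases), transposed
#' convolutions and batch normalisation are counted, parameter-free
#' resampling and elementwise nonlinearities are not.
#'
#' @param net a built network.
#' @param input_size integer (H, W) spatial size (one number for square).
#' @return operation count (a plain double).
#' @export
count_flops <- function(net, input_size = c(512, 512)) {
  if (length(input_size) == 1) input_size <- rep(input_size, 2)
  H <- input_size[1]; W <- input_size[2]
  if (inherits(net, "unet_baseline")) {
    ctx <- new_count_ctx(bn_macs = FALSE)
    fw_unet(ctx, c(H, W, net$in_channels, 1), net)
    return(ctx$macs)
  }
  dg <- net$design
  ctx <- new_count_ctx(bn_macs = dg$bn_macs)
  if (inherits(net, "cae_unet")) {
    fw_stage(ctx, c(H, W, net$in_channels, 1), net$stage, dg)
    return(ctx$macs)
  }
  fw_stage(ctx, c(H, W, net$in_channels, 1), net$stage1, dg)
  fw_stage(ctx, c(H, W, net$in_channels + net$stage2_extra, 1),
           net$stage2, dg)
  ctx$macs
}

#' Model profile: parameters and operations
#'
#' @inheritParams count_flops
#' @return list with `n_params`, `flops` (multiply-accumulates at
#'   `input_size`), and the configuration.
#' @export
model_profile <- function(net, input_size = c(512, 512)) {
  list(n_params = count_parameters(net),
       flops = count_flops(net, input_size),
       k = net$k, m = net$m, input_size = input_size)
}
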