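# Architecture construction, shape algebra and profiling.

ns <- asNamespace("dsaenet")

test_that("minimal configurations build and preserve spatial size", {
  net <- dsae_net(2, 1, in_channels = 1, num_classes = 2, seed = 1)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  out <- ns$forward_dsae(net, x)
  expect_equal(dim(out$end$val), c(16, 16, 2, 1))
  expect_equal(dim(out$mid$val), c(16, 16, 2, 1))

  net38 <- dsae_net(3, 8, seed = 2)
  x <- array(rnorm(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  out <- ns$forward_dsae(net38, x)
  expect_equal(dim(out$end$val), c(32, 32, 2, 2))

  expect_error(dsae_net(1, 8), "depth")
  expect_error(dsae_net(3, 0), "width")
})

test_that("per-pixel class vectors sum to one after normalisation", {
  net <- dsae_net(2, 2, seed = 3)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  out <- ns$forward_dsae(net, x)
  for (p in list(out$mid$val, out$end$val)) {
    sums <- p[, , 1, ] + p[, , 2, ]
    expect_equal(sums, matrix(1, 8, 8), tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("stage-2 consumes the image plus the handed-over probabilities", {
  net <- dsae_net(3, 8, seed = 1)
  expect_equal(net$stage2$in_channels,
               net$in_channels + net$stage2_extra)
  # the first stage-2 encoder unit's first conv sees that width
  expect_equal(net$stage2$enc[[1]]$m1$proj$cin, 3 + net$stage2_extra)
})

test_that("construction is deterministic given configuration and seed", {
  a <- dsae_net(3, 4, seed = 42)
  b <- dsae_net(3, 4, seed = 42)
  expect_equal(count_parameters(a), count_parameters(b))
  pa <- ns$collect_params(unclass(a)); pb <- ns$collect_params(unclass(b))
  for (i in seq_along(pa)) expect_identical(pa[[i]]$val, pb[[i]]$val)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  expect_identical(ns$forward_dsae(a, x)$end$val,
                   ns$forward_dsae(b, x)$end$val)
})

test_that("forward passes are deterministic in evaluation mode", {
  net <- cae_unet(2, 4, seed = 5)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  o1 <- ns$forward_cae(net, x)$prob$val
  o2 <- ns$forward_cae(net, x)$prob$val
  expect_identical(o1, o2)
})

test_that("parameter count grows monotonically in depth and width", {
  p <- function(k, m) count_parameters(dsae_net(k, m))
  expect_lt(p(2, 4), p(3, 4))
  expect_lt(p(3, 4), p(4, 4))
  expect_lt(p(3, 4), p(3, 8))
  expect_lt(p(3, 8), p(3, 16))
})

test_that("count_parameters counts exactly the trainable scalars", {
  cv <- ns$mk_conv(3, 1, 1, bias = TRUE)
  expect_equal(sum(vapply(ns$collect_params(cv),
                          function(p) length(p$val), 0)), 10)
})

test_that("count_flops matches hand counts on elementary layers", {
  # a single 1x1 conv, 1 -> 1 channel, no bias, on a 2x2 input
  cv <- ns$mk_conv(1, 1, 1, bias = FALSE)
  ctx <- ns$new_count_ctx()
  ns$apply_conv(ctx, c(2, 2, 1, 1), cv)
  expect_equal(ctx$macs, 4)

  # 3x3 conv with bias, 2 -> 5 channels on 8x8: (9*2*5 + 5) * 64
  cv <- ns$mk_conv(3, 2, 5, bias = TRUE)
  ctx <- ns$new_count_ctx()
  ns$apply_conv(ctx, c(8, 8, 2, 1), cv)
  expect_equal(ctx$macs, (9 * 2 * 5 + 5) * 64)
})

test_that("CMFA preserves spatial size and splits channels evenly", {
  dg <- dsae_design()
  set.seed(1)
  mod <- ns$build_cmfa(8, 8, dg)
  x <- ns$ad_const(array(rnorm(32 * 32 * 8), c(32, 32, 8, 1)))
  y <- ns$fw_cmfa(ns$new_run_ctx(), x, mod, dg)
  expect_equal(dim(y$val), c(32, 32, 8, 1))

  # concatenated pre-fusion width is 3/2 of the post-projection width
  expect_equal(mod$fuse$cin, 3 * mod$d)
  expect_equal(mod$proj$cout, 2 * mod$d)
  expect_equal(mod$fuse$cin / mod$proj$cout, 3 / 2)

  # zero input stays finite through the attention normalisation
  x0 <- ns$ad_const(array(0, c(16, 16, 8, 1)))
  y0 <- ns$fw_cmfa(ns$new_run_ctx(), x0, mod, dg)
  expect_true(all(is.finite(y0$val)))
})

test_that("output size equals input size when divisible by 2^(k-1)", {
  for (k in 2:3) {
    net <- dsae_net(k, 4, seed = k)
    s <- 8 * 2^(k - 1)
    x <- array(rnorm(s * s * 3), c(s, s, 3, 1))
    out <- ns$forward_dsae(net, x)
    expect_equal(dim(out$end$val)[1:2], c(s, s))
  }
})

test_that("every parameter of both stages receives gradient signal", {
  net <- dsae_net(2, 2, seed = 9)
  x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  mask <- array(random_mask(8, 16, p = 0.3, seed = 1), c(8, 8, 2))
  oh <- ns$onehot_batch(mask)
  w <- array(suppressWarnings(vapply(1:2, function(j)
    dsaenet:::sdl_weight_map(mask[, , j]), matrix(0, 8, 8))),
    c(8, 8, 1, 2))
  ns$tape_begin()
  out <- ns$forward_dsae(net, x, training = TRUE)
  lm <- ns$stage_loss_ad(out$logits_mid, out$mid, oh, w, 0.5, "ce")
  le <- ns$stage_loss_ad(out$logits_end, out$end, oh, w, 0.5, "ce")
  L <- ns$s_add(ns$s_mul(lm, 0.5), ns$s_mul(le, 0.5))
  ns$backward(L)
  ns$tape_end()
  params <- ns$collect_params(unclass(net))
  got <- vapply(params, function(p)
    !is.null(p$grad) && any(p$grad != 0), TRUE)
  expect_true(all(got))
})

test_that("the model profile is reproducible and self-consistent", {
  net <- dsae_net(3, 4, seed = 1)
  pr <- model_profile(net, 64)
  expect_equal(pr$n_params, count_parameters(net))
  expect_equal(pr$flops, count_flops(net, c(64, 64)))
  expect_equal(count_flops(net, 128) / count_flops(net, 64), 4,
               tolerance = 0.01)
})
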