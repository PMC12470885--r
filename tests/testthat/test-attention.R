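# Contextual-transformer attention and the coordinate attention gate.

ns <- asNamespace("dsaenet")

test_that("contextual attention is shape-preserving and deterministic", {
  dg <- dsae_design()
  set.seed(2)
  mod <- ns$build_cot(4, dg)
  x <- ns$ad_const(array(rnorm(16 * 16 * 4), c(16, 16, 4, 1)))
  y1 <- ns$fw_cot(ns$new_run_ctx(), x, mod, dg)
  y2 <- ns$fw_cot(ns$new_run_ctx(), x, mod, dg)
  expect_equal(dim(y1$val), c(16, 16, 4, 1))
  expect_identical(y1$val, y2$val)     # bitwise deterministic in eval mode
})

test_that("equal attention logits reduce to uniform value weighting", {
  dg <- dsae_design()
  set.seed(3)
  mod <- ns$build_cot(4, dg)
  # zero the final attention projection: logits become constant
  mod$attn2$w$val[] <- 0
  x <- ns$ad_const(array(rnorm(12 * 12 * 4), c(12, 12, 4, 1)))
  ctx <- ns$new_run_ctx()
  out <- ns$fw_cot(ctx, x, mod, dg)
  # reconstruct the static branch and the value map
  k1 <- ns$apply_relu(ctx, ns$apply_bn(ctx, ns$apply_conv(ctx, x, mod$key),
                                       mod$key_bn))
  v <- ns$apply_bn(ctx, ns$apply_conv(ctx, x, mod$value), mod$value_bn)
  # constant logits: softmax assigns uniform weight to every position, so
  # the dynamic branch is the uniformly weighted value map
  expect_equal(out$val, k1$val + v$val / (12 * 12), tolerance = 1e-12)
})

test_that("gates forced open make the CAG an identity on the skip path", {
  dg <- dsae_design()
  set.seed(4)
  mod <- ns$build_cag(8, 8, dg)
  mod$gate_h$w$val[] <- 0
  mod$gate_h$b$val[] <- 50    # sigmoid -> 1
  mod$gate_w$w$val[] <- 0
  mod$gate_w$b$val[] <- 50
  skip <- ns$ad_const(array(rnorm(16 * 16 * 8), c(16, 16, 8, 1)))
  gate <- ns$ad_const(array(rnorm(16 * 16 * 8), c(16, 16, 8, 1)))
  out <- ns$fw_cag(ns$new_run_ctx(), skip, gate, mod, dg)
  # output is [gated skip, gate]; with unit gates the skip passes through
  expect_equal(out$val[, , 1:8, , drop = FALSE], skip$val,
               tolerance = 1e-10)
  expect_equal(out$val[, , 9:16, , drop = FALSE], gate$val)
  # channel contract: skip channels + gate channels
  expect_equal(dim(out$val)[3], 16)
})

test_that("directional gates have rank-one spatial structure", {
  dg <- dsae_design()
  set.seed(5)
  mod <- ns$build_cag(4, 4, dg)
  skip <- ns$ad_const(array(abs(rnorm(12 * 12 * 4)) + 0.5,
                            c(12, 12, 4, 1)))
  gate <- ns$ad_const(array(rnorm(12 * 12 * 4), c(12, 12, 4, 1)))
  out <- ns$fw_cag(ns$new_run_ctx(), skip, gate, mod, dg)
  ratio <- out$val[, , 1, 1] / skip$val[, , 1, 1]
  # ratio[h, w] = gh[h] * gw[w]: an outer product has one nonzero
  # singular value
  sv <- svd(ratio)$d
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("CAG rejects mismatched spatial sizes", {
  dg <- dsae_design()
  set.seed(6)
  mod <- ns$build_cag(4, 4, dg)
  skip <- ns$ad_const(array(rnorm(8 * 8 * 4), c(8, 8, 4, 1)))
  gate <- ns$ad_const(array(rnorm(4 * 4 * 4), c(4, 4, 4, 1)))
  expect_error(ns$fw_cag(ns$new_run_ctx(), skip, gate, mod, dg))
})
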