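# Skeletonisation, distance maps and the loss family.

test_that("skeletonization thins to one-pixel-wide medial curves", {
  # a 1-px diagonal is already thin: fixed point
  diagm <- diag(1, 9, 9)
  expect_equal(skeletonize(diagm), diagm)

  # a 3-px-wide horizontal bar reduces to its centreline row
  bar <- matrix(0, 9, 11)
  bar[4:6, 2:10] <- 1
  sk <- skeletonize(bar)
  expect_true(all(sk[c(1:3, 7:9), ] == 0))
  expect_true(sum(sk) > 0)
  # one pixel wide: no 2x2 all-foreground block
  blocks <- sk[-1, -1] + sk[-nrow(sk), -1] + sk[-1, -ncol(sk)] +
    sk[-nrow(sk), -ncol(sk)]
  expect_true(all(blocks < 4))
  # subset of the source foreground
  expect_true(all(bar[sk == 1] == 1))

  expect_equal(skeletonize(matrix(0, 5, 5)), matrix(0, 5, 5))
  expect_error(skeletonize(matrix(0.5, 3, 3)), "binary")
})

test_that("skeletons of random masks are thin subsets of the mask", {
  set.seed(11)
  for (i in 1:20) {
    m <- random_mask(24, 24, p = 0.3)
    sk <- skeletonize(m)
    expect_true(all(m[sk == 1] == 1))
    blocks <- sk[-1, -1] + sk[-24, -1] + sk[-1, -24] + sk[-24, -24]
    expect_true(all(blocks < 4))
  }
})

test_that("skeleton distance map is the exact Euclidean transform", {
  # single skeleton pixel at (3, 4): distance from (0, 0)-like corner
  sk <- matrix(0, 8, 8)
  sk[4, 5] <- 1   # 1-based (4, 5) = offset (3, 4) from pixel (1, 1)
  d <- skeleton_distance_map(sk)
  expect_equal(d[1, 1], 5)     # 3-4-5 triangle
  expect_equal(d[4, 5], 0)

  # full brute-force equality on a 7x7 grid with central pixel
  sk <- matrix(0, 7, 7); sk[4, 4] <- 1
  expect_equal(skeleton_distance_map(sk), brute_edt(sk))

  expect_warning(d0 <- skeleton_distance_map(matrix(0, 5, 5)), "empty")
  expect_equal(d0, matrix(0, 5, 5))
})

test_that("distance maps match the brute-force oracle on random grids", {
  set.seed(42)
  for (i in 1:12) {
    H <- sample(5:32, 1); W <- sample(5:32, 1)
    sk <- random_mask(H, W, p = 0.08)
    if (!any(sk == 1)) sk[sample(H, 1), sample(W, 1)] <- 1
    expect_equal(skeleton_distance_map(sk), brute_edt(sk),
                 tolerance = 1e-12)
  }
})

test_that("SDL is zero on skeleton-supported predictions and linear", {
  m <- square_mask(15, 7)
  sk <- skeletonize(m)

  expect_equal(sdl_loss(matrix(0, 15, 15), m), 0)
  expect_equal(sdl_loss(sk, m), 0)    # weights vanish exactly on K

  # 5x5 domain, single central skeleton pixel, pred == 1:
  # loss is the mean of the max-normalised brute-force distance map
  m5 <- matrix(0, 5, 5); m5[3, 3] <- 1
  d <- brute_edt(m5)
  expect_equal(sdl_loss(matrix(1, 5, 5), m5), mean(d / max(d)))

  # linearity in the prediction
  set.seed(3)
  p1 <- matrix(runif(225), 15); p2 <- matrix(runif(225), 15)
  expect_equal(sdl_loss(0.3 * p1 + 0.6 * p2, m),
               0.3 * sdl_loss(p1, m) + 0.6 * sdl_loss(p2, m))

  expect_error(sdl_loss(matrix(0, 4, 4), m), "shape")
})

test_that("SDL is non-negative and zero iff mass avoids positive weights", {
  set.seed(7)
  for (i in 1:50) {
    m <- random_mask(20, 20, p = 0.2)
    p <- matrix(runif(400), 20)
    l <- suppressWarnings(sdl_loss(p, m))
    expect_gte(l, 0)
  }
  # zero set: pred supported on {w == 0} gives 0, any mass outside > 0
  m <- square_mask(12, 5)
  w <- dsaenet:::sdl_weight_map(m)
  p0 <- (w == 0) * 1
  expect_equal(sdl_loss(p0, m), 0)
  p1 <- p0; p1[which(w > 0)[1]] <- 0.5
  expect_gt(sdl_loss(p1, m), 0)
})

test_that("boundary weight map is signed distance to the mask boundary", {
  m <- square_mask(15, 9)
  phi <- boundary_weight_map(m)
  bp <- boundary_points(m)
  expect_true(all(phi[bp] == 0))
  expect_equal(phi[8, 8], -4)          # centre of the filled 9x9 square
  expect_true(any(phi < 0))            # negative interior exists
  expect_true(all(phi[m == 0] >= 0))
  expect_true(all(phi[m == 1] <= 0))
})

test_that("boundary loss matches its two-integral definition", {
  m <- square_mask(15, 9)
  expect_equal(boundary_loss(m, m), 0)
  # pred == 0 leaves -mean(phi * g), non-negative since phi <= 0 on G
  phi <- boundary_weight_map(m)
  expect_equal(boundary_loss(matrix(0, 15, 15), m), -mean(phi * m))
  expect_gte(boundary_loss(matrix(0, 15, 15), m), 0)
  set.seed(5)
  p <- matrix(runif(225), 15)
  expect_equal(boundary_loss(p, m), mean(phi * p) - mean(phi * m))
})

test_that("SDL weights are non-negative where boundary weights go negative", {
  # the structural contrast between the two weighting schemes
  for (side in c(5, 7, 9)) {
    m <- square_mask(15, side)
    expect_true(any(boundary_weight_map(m) < 0))
    expect_true(all(dsaenet:::sdl_weight_map(m) >= 0))
  }
})

test_that("composite loss blends SDL and the regional loss by alpha", {
  m <- square_mask(11, 5)
  set.seed(9)
  p <- matrix(runif(121), 11)

  cfg0 <- loss_config(alpha_max = 0, regional = "ce")
  expect_equal(composite_loss(p, m, cfg0),
               dsaenet:::regional_loss(p, m, "ce"))

  cfg <- loss_config(alpha_max = 0.6, regional = "dice")
  expect_equal(composite_loss(p, m, cfg),
               0.6 * sdl_loss(p, m) +
                 0.4 * dsaenet:::regional_loss(p, m, "dice"))

  # perfect prediction: regional dice term vanishes, SDL term remains
  expect_equal(composite_loss(m, m, cfg),
               0.6 * sdl_loss(m, m), tolerance = 1e-6)

  # alpha cap: 1.0 only in sensitivity mode
  expect_error(loss_config(alpha_max = 1), "0.7")
  expect_silent(loss_config(alpha_max = 1, sensitivity = TRUE))
  expect_error(loss_config(alpha_max = -0.1), "alpha")
})

test_that("alpha schedule ramps linearly and never exceeds its cap", {
  cfg <- loss_config(alpha_max = 0.7, alpha_ramp_frac = 0.5)
  a <- vapply(1:40, function(e) alpha_at(cfg, e, 40), 0)
  expect_equal(a[1], 0)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a <= 0.7 + 1e-12))
  expect_equal(a[21], 0.7)   # fully ramped at half of training
  expect_equal(max(a), 0.7)
})

test_that("cascaded loss is the weighted sum of per-stage losses", {
  m <- square_mask(11, 5)
  set.seed(13)
  pm <- matrix(runif(121), 11); pe <- matrix(runif(121), 11)
  cfg <- loss_config(alpha_max = 0.5, regional = "ce", w0 = 0.3, w1 = 0.7)
  expect_equal(cascaded_loss(list(mid = pm, end = pe), m, cfg),
               0.3 * composite_loss(pm, m, cfg) +
                 0.7 * composite_loss(pe, m, cfg))
  cfg0 <- loss_config(alpha_max = 0.5, w0 = 0, w1 = 1)
  expect_equal(cascaded_loss(list(mid = pm, end = pe), m, cfg0),
               composite_loss(pe, m, cfg0))
  cfg5 <- loss_config(alpha_max = 0.5, w0 = 0.5, w1 = 0.5)
  expect_equal(cascaded_loss(list(mid = pm, end = pm), m, cfg5),
               composite_loss(pm, m, cfg5))
})
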