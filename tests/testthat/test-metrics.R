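# Pixel metrics against closed-form and brute-force oracles.

test_that("confusion counts match a per-pixel tally", {
  m <- random_mask(8, 8, p = 0.4, seed = 1)
  p <- random_mask(8, 8, p = 0.4, seed = 2)
  cc <- confusion(p, m)
  # brute-force loop oracle
  tp <- tn <- fp <- fn <- 0
  for (i in 1:8) for (j in 1:8) {
    if (p[i, j] == 1 && m[i, j] == 1) tp <- tp + 1
    if (p[i, j] == 0 && m[i, j] == 0) tn <- tn + 1
    if (p[i, j] == 1 && m[i, j] == 0) fp <- fp + 1
    if (p[i, j] == 0 && m[i, j] == 1) fn <- fn + 1
  }
  expect_equal(unclass(cc), list(tp = tp, tn = tn, fp = fp, fn = fn))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 64)

  same <- confusion(m, m)
  expect_equal(same$fp + same$fn, 0)
  inv <- confusion(1 - m, m)
  expect_equal(inv$tp + inv$tn, 0)
  expect_error(confusion(m * 0.5, m), "binary")
})

test_that("accuracy, Dice and MCC evaluate their closed forms", {
  cc <- structure(list(tp = 2, tn = 0, fp = 1, fn = 1), class = "confusion")
  expect_equal(dice(cc), 2 * 2 / (2 * 2 + 1 + 1))

  m <- random_mask(10, 10, p = 0.3, seed = 3)
  perfect <- confusion(m, m)
  expect_equal(accuracy(perfect), 1)
  expect_equal(dice(perfect), 1)
  expect_equal(mcc(perfect), 1)

  cc2 <- structure(list(tp = 8, tn = 80, fp = 2, fn = 10),
                   class = "confusion")
  expect_equal(accuracy(cc2), 88 / 100)
  expect_equal(mcc(cc2),
               (8 * 80 - 2 * 10) /
                 sqrt((8 + 2) * (8 + 10) * (80 + 2) * (80 + 10)))

  empty <- structure(list(tp = 0, tn = 25, fp = 0, fn = 0),
                     class = "confusion")
  expect_equal(dice(empty), 1)          # both masks empty
  expect_warning(z <- mcc(empty), "degenerate")
  expect_equal(z, 0)
})

test_that("metric bounds hold on random prediction/truth pairs", {
  set.seed(21)
  for (i in 1:30) {
    m <- random_mask(12, 12, p = runif(1, 0.1, 0.5))
    p <- random_mask(12, 12, p = runif(1, 0.1, 0.5))
    cc <- confusion(p, m)
    expect_true(accuracy(cc) >= 0 && accuracy(cc) <= 1)
    expect_true(dice(cc) >= 0 && dice(cc) <= 1)
    v <- suppressWarnings(mcc(cc))
    expect_true(v >= -1 && v <= 1)
  }
})

test_that("AUC equals the Mann-Whitney rank statistic", {
  g <- c(1, 1, 1, 0, 0, 0, 0, 0, 1, 0)
  s <- c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3, 0.15, 0.05, 0.95, 0.02)
  # brute-force pair counting (ties count half)
  pos <- s[g == 1]; neg <- s[g == 0]
  wins <- 0
  for (a in pos) for (b in neg)
    wins <- wins + (a > b) + 0.5 * (a == b)
  expect_equal(auc_roc(s, g), wins / (length(pos) * length(neg)))

  expect_equal(auc_roc(s, g), 1)            # perfectly separating here
  expect_equal(auc_roc(rep(0.5, 10), g), 0.5)
  expect_true(is.na(auc_roc(s, rep(1, 10))))

  set.seed(4)
  g2 <- rbinom(40, 1, 0.4); s2 <- round(runif(40), 1)  # with ties
  if (any(g2 == 1) && any(g2 == 0)) {
    pos <- s2[g2 == 1]; neg <- s2[g2 == 0]
    wins <- 0
    for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
    expect_equal(auc_roc(s2, g2), wins / (length(pos) * length(neg)))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  g <- rbinom(200, 1, 0.3)
  s <- runif(200) + 0.4 * g
  ref <- as.numeric(suppressMessages(pROC::auc(g, s,
                                               direction = "<")))
  expect_equal(auc_roc(s, g), ref, tolerance = 1e-10)
})

test_that("HD95 matches brute-force all-pairs percentile computation", {
  # identical masks
  m <- square_mask(12, 5)
  expect_equal(hd95(m, m), 0)

  # unit squares offset by one pixel
  a <- matrix(0, 10, 10); a[4:5, 4:5] <- 1
  b <- matrix(0, 10, 10); b[5:6, 4:5] <- 1
  expect_equal(hd95(a, b), 1.0)

  # random masks vs brute-force directed distances
  set.seed(31)
  for (i in 1:8) {
    ma <- random_mask(16, 16, p = 0.25)
    mb <- random_mask(16, 16, p = 0.25)
    A <- boundary_points(ma); B <- boundary_points(mb)
    if (!nrow(A) || !nrow(B)) next
    dAB <- apply(A, 1, function(q)
      sqrt(min((B[, 1] - q[1])^2 + (B[, 2] - q[2])^2)))
    dBA <- apply(B, 1, function(q)
      sqrt(min((A[, 1] - q[1])^2 + (A[, 2] - q[2])^2)))
    expect_equal(hd95(ma, mb),
                 unname(quantile(c(dAB, dBA), 0.95, type = 7)))
    expect_equal(hd95(ma, mb), hd95(mb, ma))   # symmetry
    expect_gte(hd95(ma, mb), 0)
  }

  # a single far outlier beyond the 95th percentile leaves HD95 unchanged
  base <- matrix(0, 40, 200); base[20, 10:180] <- 1
  shifted <- matrix(0, 40, 200); shifted[21, 10:180] <- 1
  h0 <- hd95(base, shifted)
  out <- shifted; out[40, 200] <- 1    # isolated far point
  expect_equal(hd95(base, out), h0, tolerance = 0.05)

  expect_true(is.na(hd95(matrix(0, 5, 5), m[1:5, 1:5])))
})

test_that("seg_metrics binarises at 0.5 and reports the full panel", {
  set.seed(6)
  g <- generate_vessel_tree(vessel_tree_params(image_size = c(48, 48),
                                               seed = 77))
  noisy <- pmin(pmax(g$mask + rnorm(48 * 48, 0, 0.2), 0), 1)
  sm <- seg_metrics(noisy, g$mask)
  expect_named(sm, c("acc", "auc", "dice", "mcc", "hd95", "miou"))
  expect_true(sm$dice > 0.5)           # mostly correct prediction
  expect_equal(sm$acc,
               accuracy(confusion((noisy >= 0.5) * 1, g$mask)))
})
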