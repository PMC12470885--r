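# Training protocol: schedules, optimiser behaviour, TTA, checkpoints.

ns <- asNamespace("dsaenet")

test_that("the cosine schedule anneals from lr_init to the floor", {
  tc <- train_config(epochs = 200, cycles = 20)
  lrs <- vapply(1:200, function(e) lr_at(tc, e), 0)
  expect_equal(lrs[1], 1e-2)
  expect_lte(lrs[200], 1e-7)
  expect_true(all(diff(lrs) <= 0))   # monotone decay without restarts

  tcw <- train_config(epochs = 20, cycles = 2, warm_restarts = TRUE)
  lrw <- vapply(1:20, function(e) lr_at(tcw, e), 0)
  expect_equal(lrw[1], lrw[11])      # restart at each cycle
  expect_error(train_config(epochs = 10, cycles = 3), "divide")
})

test_that("training on a tiny dataset yields finite losses and checkpoints", {
  prs <- tiny_pairs(10, size = 32)
  data <- list(train = prs[1:8], val = prs[9:10])
  net <- dsae_net(2, 2, seed = 1)
  tc <- train_config(epochs = 2, cycles = 1, batch_size = 4,
                     input_size = 32, seed = 1)
  fit <- dsae_fit(data, net = net, loss = loss_config(0.7, "ce"),
                  train = tc, verbose = FALSE)
  expect_true(all(is.finite(fit$history$loss)))
  expect_s3_class(fit, "dsae_fit")
  expect_false(is.null(fit$best$state))

  ck <- tempfile(fileext = ".rds")
  save_checkpoint(fit$net, ck, input_size = c(32, 32))
  expect_true(file.exists(ck))
  side <- jsonlite::read_json(paste0(ck, ".json"))
  expect_equal(side$n_params, count_parameters(fit$net))
  net2 <- load_checkpoint(ck)
  img <- prs[[1]]$image
  expect_equal(tta_predict(net2, img, tta = FALSE),
               tta_predict(fit$net, img, tta = FALSE))
  unlink(c(ck, paste0(ck, ".json")))
})

test_that("loss on a single repeated batch decreases after warm-up", {
  set.seed(1)
  g <- generate_vessel_tree(vessel_tree_params(image_size = c(32, 32),
                                               seed = 60))
  x <- array(g$image, c(32, 32, 3, 1))
  mask <- array(g$mask, c(32, 32, 1))
  oh <- ns$onehot_batch(mask)
  w <- array(suppressWarnings(dsaenet:::sdl_weight_map(g$mask)),
             c(32, 32, 1, 1))
  net <- dsae_net(2, 4, seed = 2)
  params <- ns$collect_params(unclass(net))
  opt <- ns$adam_new(params)
  losses <- numeric(30)
  for (i in 1:30) {
    ns$tape_begin()
    out <- ns$forward_dsae(net, x, training = TRUE)
    lm <- ns$stage_loss_ad(out$logits_mid, out$mid, oh, w, 0.3, "ce")
    le <- ns$stage_loss_ad(out$logits_end, out$end, oh, w, 0.3, "ce")
    L <- ns$s_add(ns$s_mul(lm, 0.5), ns$s_mul(le, 0.5))
    ns$backward(L)
    ns$tape_end()
    ns$adam_step(opt, 3e-3)
    losses[i] <- L$val
  }
  expect_lt(mean(tail(losses, 5)), mean(head(losses, 5)))
  expect_lt(losses[30], 0.8 * losses[1])
})

test_that("reproducibility: identical seeds give identical trajectories", {
  prs <- tiny_pairs(6, size = 32)
  data <- list(train = prs[1:5], val = prs[6])
  tc <- train_config(epochs = 2, cycles = 1, batch_size = 4,
                     input_size = 32, seed = 7)
  f1 <- dsae_fit(data, net = dsae_net(2, 2, seed = 7),
                 loss = loss_config(0.5), train = tc, verbose = FALSE)
  f2 <- dsae_fit(data, net = dsae_net(2, 2, seed = 7),
                 loss = loss_config(0.5), train = tc, verbose = FALSE)
  expect_identical(f1$history$loss, f2$history$loss)
})

test_that("the retained checkpoint maximises cycle-end validation AUC", {
  prs <- tiny_pairs(8, size = 32)
  data <- list(train = prs[1:6], val = prs[7:8])
  tc <- train_config(epochs = 4, cycles = 2, batch_size = 3,
                     input_size = 32, seed = 3)
  fit <- dsae_fit(data, net = dsae_net(2, 2, seed = 3),
                  loss = loss_config(0), train = tc, verbose = FALSE)
  aucs <- fit$history$val_auc[!is.na(fit$history$val_auc)]
  expect_equal(fit$best$auc, max(aucs))
})

test_that("flip TTA averages the four inverse-transformed predictions", {
  net <- dsae_net(2, 2, seed = 5)
  set.seed(10)
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))

  # hand-computed four-term average
  H <- 24; W <- 24
  acc <- matrix(0, H, W)
  for (fh in c(FALSE, TRUE)) for (fv in c(FALSE, TRUE)) {
    im <- img
    if (fh) im <- im[rev(seq_len(H)), , , drop = FALSE]
    if (fv) im <- im[, rev(seq_len(W)), , drop = FALSE]
    p <- dsaenet:::predict_prob(net, im)$end
    if (fh) p <- p[rev(seq_len(H)), ]
    if (fv) p <- p[, rev(seq_len(W))]
    acc <- acc + p
  }
  expect_equal(tta_predict(net, img), acc / 4)

  # a constant-output model is a TTA fixed point
  params <- ns$collect_params(unclass(net))
  for (p in params) p$val[] <- 0
  pt <- tta_predict(net, img)
  expect_equal(pt, matrix(0.5, H, W), tolerance = 1e-12)

  # probabilities stay in [0, 1] and shape is preserved
  expect_equal(dim(pt), c(H, W))
  expect_true(all(pt >= 0 & pt <= 1))
})

test_that("prediction pads non-divisible sizes by reflection", {
  net <- dsae_net(3, 4, seed = 6)
  img <- array(runif(50 * 45 * 3), c(50, 45, 3))   # not divisible by 4
  p <- tta_predict(net, img, tta = FALSE)
  expect_equal(dim(p), c(50, 45))
})

test_that("the loss ablation report carries four labelled curves", {
  prs <- tiny_pairs(7, size = 32, seed0 = 400)
  data <- list(train = prs[1:5], val = prs[6:7])
  tc <- train_config(epochs = 2, cycles = 2, batch_size = 4,
                     input_size = 32, seed = 2)
  rep <- run_sdl_ablation(data, train = tc)
  expect_s3_class(rep, "sdl_ablation")
  expect_setequal(names(rep$runs), c("ce", "ce+sdl", "dice", "dice+sdl"))
  for (r in rep$runs) {
    expect_length(r$miou_curve, 2)
    # the stored variance statistic recomputes from the stored history
    cv <- r$history$val_miou[!is.na(r$history$val_miou)]
    expect_equal(r$curve_var, var(diff(cv)))
    expect_equal(r$final_miou, cv[length(cv)])
  }

  # alpha sweep mode mirrors the sensitivity grid, including alpha = 1
  sweep <- run_sdl_ablation(data, train = tc, alphas = c(0, 0.7, 1.0))
  expect_setequal(names(sweep$runs),
                  paste0("alpha=", format(c(0, 0.7, 1.0))))
})
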