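test_that("soft Dice loss on hand-counted masks", {
  t4 <- array(0, c(4, 4, 4)); t4[1:4, 1, 1] <- 1     # 4 target voxels
  p4 <- array(0, c(4, 4, 4)); p4[3:4, 1, 1] <- 1; p4[3:4, 2, 1] <- 1
  expect_equal(soft_dice_loss(p4, t4, eps = 0), 0.5)  # 1 - 4/8
  expect_lt(soft_dice_loss(t4, t4, eps = 1e-5), 1e-4)
  disj <- array(0, c(4, 4, 4)); disj[1, 4, 4] <- 1
  expect_gt(soft_dice_loss(disj, t4, eps = 1e-5), 1 - 1e-4)
})

test_that("binary cross-entropy closed forms and direction", {
  t <- array(c(1, 0, 1, 0), c(4, 1, 1))
  expect_lt(cross_entropy_loss(t, t), 1e-6)
  half <- array(0.5, c(4, 1, 1))
  expect_equal(cross_entropy_loss(half, t), log(2), tolerance = 1e-12)
  closer <- array(c(0.7, 0.3, 0.7, 0.3), c(4, 1, 1))
  expect_lt(cross_entropy_loss(closer, t), cross_entropy_loss(half, t))
})

test_that("heatmap MSE identities", {
  set.seed(50)
  a <- array(rnorm(3 * 4^3), c(3, 4, 4, 4))
  expect_equal(heatmap_mse(a, a), 0)
  expect_equal(heatmap_mse(a + 0.3, a), 0.09, tolerance = 1e-12)
  b <- array(rnorm(3 * 4^3), c(3, 4, 4, 4))
  expect_equal(heatmap_mse(a + 2 * (b - a), a), 4 * heatmap_mse(b, a),
               tolerance = 1e-9)
  expect_error(heatmap_mse(a, array(0, c(3, 2, 2, 2))), "differ")
})

test_that("all segmentation loss variants vanish at a perfect binary prediction", {
  t <- random_mask(c(5, 5, 5), 0.3) * 1
  for (nm in c("ce_plus_dice", "dice", "squared_dice", "log_cosh_dice", "ce"))
    expect_lt(seg_loss_variant(nm)(t, t), 1e-3)
  expect_error(seg_loss_variant("focal"), "unknown segmentation loss")
})

test_that("log-cosh Dice never exceeds the plain Dice loss", {
  set.seed(51)
  for (i in 1:100) {
    p <- array(runif(64), c(4, 4, 4))
    t <- random_mask(c(4, 4, 4), 0.4) * 1
    expect_lte(seg_loss_variant("log_cosh_dice")(p, t),
               seg_loss_variant("dice")(p, t) + 1e-12)
  }
})

test_that("squared Dice equals plain Dice on hard binary masks", {
  t4 <- array(0, c(4, 4, 4)); t4[1:4, 1, 1] <- 1
  p4 <- array(0, c(4, 4, 4)); p4[3:4, 1, 1] <- 1; p4[3:4, 2, 1] <- 1
  expect_equal(seg_loss_variant("squared_dice")(p4, t4, eps = 0), 0.5)
})

test_that("ce_plus_dice decomposes exactly into its components", {
  set.seed(52)
  p <- array(runif(64, 0.01, 0.99), c(4, 4, 4))
  t <- random_mask(c(4, 4, 4), 0.4) * 1
  expect_equal(seg_loss_variant("ce_plus_dice")(p, t),
               cross_entropy_loss(p, t) + soft_dice_loss(p, t),
               tolerance = 1e-12)
})

test_that("composite loss reduces to the two t0 terms without deep supervision", {
  net <- tiny_net(seed = 6, deep_supervision = FALSE)
  x <- array(rnorm(16^3), c(16, 16, 16))
  lab <- random_mask(c(16, 16, 16), 0.1)
  lm <- new_landmark_set(c(5, 5, 5), c(8, 8, 8), c(11, 11, 11))
  b <- network_forward(net, x)
  targets <- make_targets(lab, lm, 1, 3)
  out <- composite_loss(b, targets, loss_config())
  seg_direct <- seg_loss_variant("ce_plus_dice")(as.numeric(b$seg$value),
                                                 as.numeric(lab))
  hm_direct <- heatmap_mse(b$heatmaps$value, targets$heatmaps)
  expect_equal(out$total$value, seg_direct + hm_direct, tolerance = 1e-9)
  expect_equal(unname(out$components["seg"]), seg_direct, tolerance = 1e-9)
})

test_that("a near-perfect bundle gives a near-zero composite loss on all terminals", {
  lab <- random_mask(c(16, 16, 16), 0.15)
  lm <- new_landmark_set(c(5, 5, 5), c(8, 8, 8), c(11, 11, 11))
  targets <- make_targets(lab, lm, 1, 3, aux_levels = 2L)
  bundle <- list(
    seg = cochleaseg:::ag_leaf(array(pmin(pmax(targets$seg, 1e-6), 1 - 1e-6),
                                     c(1, 16, 16, 16))),
    heatmaps = cochleaseg:::ag_leaf(targets$heatmaps),
    aux = list(list(
      seg = cochleaseg:::ag_leaf(array(pmin(pmax(targets$aux[[1]]$seg, 1e-6),
                                            1 - 1e-6), c(1, 8, 8, 8))),
      heatmaps = cochleaseg:::ag_leaf(targets$aux[[1]]$heatmaps), level = 2L)))
  out <- composite_loss(bundle, targets, loss_config())
  expect_lt(out$total$value, 1e-4)
})

test_that("missing auxiliary targets with deep supervision on is an error", {
  net <- tiny_net(seed = 6, deep_supervision = TRUE)
  x <- array(rnorm(16^3), c(16, 16, 16))
  lab <- random_mask(c(16, 16, 16), 0.1)
  lm <- new_landmark_set(c(5, 5, 5), c(8, 8, 8), c(11, 11, 11))
  b <- network_forward(net, x)
  targets <- make_targets(lab, lm, 1, 3)  # no aux
  expect_error(composite_loss(b, targets, loss_config()), "auxiliary targets")
})

test_that("composite loss is invariant under a joint voxel permutation", {
  set.seed(53)
  p <- array(runif(4^3, 0.05, 0.95), c(1, 4, 4, 4))
  hm <- array(rnorm(3 * 4^3), c(3, 4, 4, 4))
  lab <- random_mask(c(4, 4, 4), 0.4)
  lmh <- array(rnorm(3 * 4^3), c(3, 4, 4, 4))
  bundle <- list(seg = cochleaseg:::ag_leaf(p),
                 heatmaps = cochleaseg:::ag_leaf(hm), aux = list())
  t1 <- list(seg = lab, heatmaps = lmh, aux = list())
  perm <- sample(64)
  p2 <- array(as.numeric(p)[perm], c(1, 4, 4, 4))
  lab2 <- array(as.numeric(lab)[perm], c(4, 4, 4))
  hm2 <- hm; lmh2 <- lmh
  for (ch in 1:3) {
    hm2[ch, , , ] <- array(as.numeric(hm[ch, , , ])[perm], c(4, 4, 4))
    lmh2[ch, , , ] <- array(as.numeric(lmh[ch, , , ])[perm], c(4, 4, 4))
  }
  bundle2 <- list(seg = cochleaseg:::ag_leaf(p2),
                  heatmaps = cochleaseg:::ag_leaf(hm2), aux = list())
  t2 <- list(seg = lab2, heatmaps = lmh2, aux = list())
  cfg <- loss_config()
  expect_equal(composite_loss(bundle, t1, cfg)$total$value,
               composite_loss(bundle2, t2, cfg)$total$value,
               tolerance = 1e-12)
})

test_that("analytic loss gradients match finite differences on 4^3 inputs", {
  set.seed(54)
  t <- random_mask(c(4, 4, 4), 0.4) * 1
  p0 <- array(runif(64, 0.1, 0.9), c(1, 4, 4, 4))
  cases <- list(
    bce = function(n) cochleaseg:::ag_bce(n, t),
    dice = function(n) cochleaseg:::ag_dice(n, t, 1e-5, "dice"),
    squared = function(n) cochleaseg:::ag_dice(n, t, 1e-5, "squared"),
    log_cosh = function(n) cochleaseg:::ag_dice(n, t, 1e-5, "log_cosh"),
    mse = function(n) cochleaseg:::ag_mse(n, array(t, c(1, 4, 4, 4))))
  for (nm in names(cases)) {
    node <- cochleaseg:::ag_leaf(p0)
    root <- cases[[nm]](node)
    cochleaseg:::ag_backward(root)
    fd <- fd_grad(function(v) cases[[nm]](cochleaseg:::ag_leaf(v))$value, p0)
    expect_lt(max_rel_err(node$grad, fd), 1e-4)
  }
})
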