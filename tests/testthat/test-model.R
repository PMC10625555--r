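test_that("the default architecture traces the documented shape cascade", {
  cfg <- network_config()
  sh <- network_shapes(cfg, 128)
  expect_equal(sh$edge, c(64, 32, 16, 8))
  expect_equal(cfg$channels, c(32, 64, 128, 256, 320))
  expect_equal(sh$channels, c(64, 128, 256, 320))
  expect_error(network_shapes(cfg, 100), "divisible")
})

test_that("config invariants are enforced", {
  expect_error(network_config(levels = 3, channels = c(8, 16)), "length")
  expect_error(network_config(seg_channels = 2), "fixed")
  expect_error(network_config(heatmap_channels = 1), "fixed")
})

test_that("forward output shapes honour the contract at several chunk edges", {
  net <- tiny_net(levels = 2, channels = c(4, 8, 12), deep_supervision = TRUE)
  for (edge in c(16, 32)) {
    b <- network_forward(net, array(rnorm(edge^3), rep(edge, 3)))
    expect_identical(dim(b$seg$value), c(1L, rep(as.integer(edge), 3)))
    expect_identical(dim(b$heatmaps$value), c(3L, rep(as.integer(edge), 3)))
    expect_length(b$aux, 1)
    expect_identical(dim(b$aux[[1]]$seg$value),
                     c(1L, rep(as.integer(edge / 2), 3)))
    expect_gte(min(b$seg$value), 0)
    expect_lte(max(b$seg$value), 1)
  }
})

test_that("traced shapes agree with an actual forward pass", {
  cfg <- network_config(levels = 2, channels = c(4, 8, 12),
                        deep_supervision = FALSE)
  sh <- network_shapes(cfg, 32)
  net <- build_network(cfg, seed = 5)
  b <- network_forward(net, array(rnorm(32^3), c(32, 32, 32)))
  # deepest deep-supervision-free observable: aux absent, but the level-2
  # decoder feature is implied by the seg output path; verify via a 3-level
  # trace on a divisible edge instead
  expect_equal(sh$edge[cfg$levels], 32 / 2^cfg$levels)
  expect_identical(dim(b$seg$value)[2], 32L)
})

test_that("forward is deterministic and initialization is a pure function of the seed", {
  net1 <- tiny_net(seed = 7)
  net2 <- tiny_net(seed = 7)
  net3 <- tiny_net(seed = 8)
  expect_identical(net1$params, net2$params)
  expect_false(identical(net1$params, net3$params))
  x <- array(rnorm(16^3), c(16, 16, 16))
  expect_identical(network_forward(net1, x)$seg$value,
                   network_forward(net1, x)$seg$value)
})

test_that("every trainable parameter receives gradient from the composite loss", {
  for (att in c("none", "global")) {
    net <- tiny_net(seed = 3, attention = att, deep_supervision = TRUE)
    x <- array(rnorm(16^3), c(16, 16, 16))
    lab <- array(0L, c(16, 16, 16)); lab[4:9, 5:10, 6:11] <- 1L
    lm <- new_landmark_set(c(5, 6, 7), c(8, 9, 10), c(3, 4, 5))
    b <- network_forward(net, x)
    targets <- make_targets(lab, lm, 1, 3, aux_levels = 2L)
    loss <- composite_loss(b, targets, loss_config())
    cochleaseg:::ag_backward(loss$total)
    g <- cochleaseg:::collect_grads(b)
    nonzero <- vapply(g, function(v) !is.null(v) && any(v != 0), logical(1))
    expect_true(all(nonzero),
                info = paste("no gradient:", paste(names(g)[!nonzero],
                                                   collapse = ", ")))
  }
})

test_that("attention gating adds parameters and global is the largest variant", {
  n_none <- n_parameters(tiny_net(attention = "none"))
  n_seg <- n_parameters(tiny_net(attention = "seg_head"))
  n_hm <- n_parameters(tiny_net(attention = "heatmap_head"))
  n_glob <- n_parameters(tiny_net(attention = "global"))
  expect_gt(n_seg, n_none)
  expect_gt(n_glob, n_seg)
  expect_equal(n_seg, n_hm)
  expect_equal(n_glob - n_none, 2 * (n_seg - n_none))
})

test_that("attention coefficients lie in [0, 1] and identity weights pass skips through", {
  net <- tiny_net(seed = 9, attention = "global")
  # force psi to zero and its bias large -> sigmoid ~ 1 -> gate ~ identity
  for (nm in grep("_att.*_psi_w$", names(net$params), value = TRUE))
    net$params[[nm]][] <- 0
  for (nm in grep("_att.*_psi_b$", names(net$params), value = TRUE))
    net$params[[nm]][] <- 50
  x <- array(rnorm(16^3), c(16, 16, 16))
  b_gated <- network_forward(net, x)
  net_plain <- net
  net_plain$config$attention <- "none"
  b_plain <- network_forward(net_plain, x)
  expect_equal(b_gated$seg$value, b_plain$seg$value, tolerance = 1e-9)
})

test_that("all activation variants run and differ", {
  x <- array(rnorm(16^3), c(16, 16, 16))
  outs <- lapply(c("leaky_relu", "relu", "prelu", "gelu", "silu", "mish"),
                 function(a) {
                   net <- tiny_net(seed = 2, activation = a,
                                   deep_supervision = FALSE)
                   network_forward(net, x)$seg$value
                 })
  for (i in seq_along(outs)) expect_true(all(is.finite(outs[[i]])))
  expect_false(identical(outs[[1]], outs[[2]]))
})

test_that("single-head forwards produce only the requested decoder output", {
  net <- tiny_net(seed = 4)
  x <- array(rnorm(16^3), c(16, 16, 16))
  s <- network_forward(net, x, heads = "seg")
  expect_null(s$heatmaps)
  expect_false(is.null(s$seg))
  h <- network_forward(net, x, heads = "hm")
  expect_null(h$seg)
  expect_identical(dim(h$heatmaps$value)[1], 3L)
})

test_that("a tiny network overfits a single fixed chunk", {
  p <- small_phantom(seed = 40, edge = 32, noise = 10)
  chunk <- preprocess_internal(p$volume)$volume$data[1:16, 9:24, 9:24]
  lab <- p$label$data[1:16, 9:24, 9:24]
  skip_if(sum(lab) < 20)
  lm <- new_landmark_set(p$landmarks$helicotrema - c(0, 8, 8),
                         p$landmarks$oval_window - c(0, 8, 8),
                         p$landmarks$round_window - c(0, 8, 8))
  net <- tiny_net(seed = 41, channels = c(4, 8, 12), deep_supervision = FALSE)
  cfg <- loss_config()
  targets <- make_targets(lab, lm, 1, 3)
  opt <- optimizer("adamw", weight_decay = 0)
  init_loss <- NULL
  for (i in 1:200) {
    b <- network_forward(net, chunk)
    loss <- composite_loss(b, targets, cfg)
    if (i == 1) init_loss <- loss$total$value
    cochleaseg:::ag_backward(loss$total)
    step <- optimizer_step(opt, net$params, cochleaseg:::collect_grads(b), 3e-3)
    net$params <- step$params
    opt <- step$opt
  }
  final <- composite_loss(network_forward(net, chunk), targets, cfg)$total$value
  expect_lt(final, 0.1 * init_loss)
})
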