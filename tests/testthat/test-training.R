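test_that("trapezoidal learning rate: ramp origin, plateau, final step, bounds", {
  sched <- lr_schedule(1000, peak_lr = 1e-3, warmup_frac = 0.1,
                       plateau_frac = 0.6, anneal_frac = 0.3)
  expect_equal(lr_at(sched, 0), 0)
  expect_equal(lr_at(sched, 50), 1e-3 * 50 / 100)
  expect_equal(lr_at(sched, 400), 1e-3)               # mid-plateau
  expect_equal(lr_at(sched, 999), 1e-3 / 300)         # one step above zero
  expect_error(lr_at(sched, 1000), "outside")
  expect_error(lr_at(sched, -1), "outside")
  expect_error(lr_schedule(100, warmup_frac = 0.5, plateau_frac = 0.6,
                           anneal_frac = 0.3), "sum to 1")
})

test_that("summed learning rates integrate to the trapezoid area", {
  sched <- lr_schedule(2000, peak_lr = 2e-3, warmup_frac = 0.2,
                       plateau_frac = 0.5, anneal_frac = 0.3)
  total <- sum(vapply(0:1999, function(i) lr_at(sched, i), numeric(1)))
  area <- 2e-3 * (sched$warmup / 2 + sched$plateau + sched$anneal / 2)
  expect_lt(abs(total - area) / area, 0.001)
})

test_that("fold plans give the documented split sizes and are seeded", {
  ids <- seq_len(43)
  plan <- make_folds(ids, k = 3, n_val = 5, seed = 2)
  expect_length(plan, 3)
  for (fold in plan) {
    expect_length(fold$train, 38)
    expect_length(fold$validation, 5)
    expect_length(intersect(fold$train, fold$validation), 0)
    expect_setequal(c(fold$train, fold$validation), ids)
  }
  expect_identical(make_folds(ids, 3, 5, seed = 2), plan)
  expect_error(make_folds(1:4, 3, 5), "smaller")
})

test_that("accumulated-mean gradients equal the large-batch gradient step", {
  net <- tiny_net(seed = 10, channels = c(4, 8, 12), deep_supervision = FALSE)
  set.seed(11)
  n_acc <- 4L
  samples <- lapply(seq_len(n_acc), function(i) {
    lab <- random_mask(c(16, 16, 16), 0.1)
    list(x = array(rnorm(16^3), c(16, 16, 16)), lab = lab,
         lm = new_landmark_set(sample(0:15, 3, TRUE), sample(0:15, 3, TRUE),
                               sample(0:15, 3, TRUE)))
  })
  cfg <- loss_config()
  grad_of <- function(s, weight = 1) {
    b <- network_forward(net, s$x)
    targets <- make_targets(s$lab, s$lm, 1, 3)
    loss <- composite_loss(b, targets, cfg)
    root <- cochleaseg:::ag_wsum(list(loss$total), weight)
    cochleaseg:::ag_backward(root)
    cochleaseg:::collect_grads(b)
  }
  # route 1: accumulate per-sample gradients, average
  acc <- NULL
  for (s in samples) acc <- cochleaseg:::add_grads(acc, grad_of(s))
  acc <- cochleaseg:::scale_grads(acc, 1 / n_acc)
  # route 2: single pass with the mean loss over the batch
  batch <- NULL
  for (s in samples) batch <- cochleaseg:::add_grads(batch, grad_of(s, 1 / n_acc))
  for (nm in names(acc)) {
    if (is.null(acc[[nm]])) next
    expect_lt(max_rel_err(acc[[nm]], batch[[nm]]), 1e-5)
  }
  # identical AdamW steps from identical gradients
  s1 <- optimizer_step(optimizer("adamw"), net$params, acc, 1e-3)
  s2 <- optimizer_step(optimizer("adamw"), net$params, batch, 1e-3)
  for (nm in names(net$params))
    expect_lt(max(abs(s1$params[[nm]] - s2$params[[nm]])), 1e-9)
})

test_that("AdamW weight decay is decoupled from the gradient moments", {
  params <- list(w = matrix(2, 2, 2))
  grads <- list(w = matrix(0, 2, 2))
  out <- optimizer_step(optimizer("adamw", weight_decay = 0.1), params, grads,
                        lr = 0.5)
  # zero gradient: the only movement is -lr * lambda * w
  expect_equal(out$params$w, matrix(2 - 0.5 * 0.1 * 2, 2, 2))
  out2 <- optimizer_step(optimizer("sgd", momentum = 0), params,
                         list(w = matrix(1, 2, 2)), lr = 0.1)
  expect_equal(out2$params$w, matrix(2 - 0.1, 2, 2))
})

micro_setup <- function(n_train = 3, n_val = 2, edge = 16L, seed = 60) {
  cohort <- generate_cohort(n_train + n_val, shape = c(32, 32, 32), seed = seed)
  insts <- lapply(cohort, function(p) {
    v <- preprocess_internal(p$volume)$volume
    # crop the central 16^3 window so micro-runs stay fast
    sl <- 9:24
    lmo <- lapply(unclass(p$landmarks), function(q) q - 8)
    cochleaseg:::prepare_instance(v$data[sl, sl, sl], p$label$data[sl, sl, sl],
                     new_landmark_set(lmo$helicotrema, lmo$oval_window,
                                      lmo$round_window),
                     chunk = 16L, stride = 16L)
  })
  list(train = insts[seq_len(n_train)], val = insts[n_train + seq_len(n_val)])
}

test_that("validation runs on the configured cadence and loss descends", {
  d <- micro_setup()
  net <- tiny_net(seed = 61, channels = c(4, 8, 12))
  cfg <- train_config(iterations = 60L, accumulation = 2L, peak_lr = 3e-3,
                      validation_every = 30L, seed = 62L)
  res <- train_one_fold(net, d$train, d$val, cfg,
                        schedule = heatmap_schedule(c(0, 30), c(1, 2), c(4, 3)))
  expect_identical(nrow(res$log), 2L)                 # exactly 2 validations
  expect_identical(res$log$iteration, c(30L, 60L))
  expect_lt(res$log$train_loss[2], res$log$train_loss[1] * 1.5)
  expect_gte(res$best$dsc, res$log$dsc[nrow(res$log)] - 1e-12)
  expect_identical(res$last$iteration, 60L)
})

test_that("training runs are bitwise reproducible from the seeds", {
  d <- micro_setup(seed = 63)
  cfg <- train_config(iterations = 20L, accumulation = 2L, peak_lr = 3e-3,
                      validation_every = 10L, seed = 64L)
  run <- function() {
    net <- tiny_net(seed = 65, channels = c(4, 8, 12))
    train_one_fold(net, d$train, d$val, cfg,
                   schedule = heatmap_schedule(c(0, 10), c(1, 2), c(4, 3)),
                   protocol = augmentation_protocol("alpha"))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$log, r2$log)
  expect_identical(r1$net$params, r2$net$params)
})

test_that("a short descent run reduces the training loss", {
  d <- micro_setup(seed = 66)
  net <- tiny_net(seed = 67, channels = c(4, 8, 12))
  cfg <- train_config(iterations = 80L, accumulation = 1L, peak_lr = 3e-3,
                      validation_every = 20L, seed = 68L)
  res <- train_one_fold(net, d$train, d$val, cfg,
                        schedule = heatmap_schedule(c(0, 40), c(1, 2), c(4, 3)))
  expect_lt(res$log$loss[nrow(res$log)], res$log$loss[1])
  expect_gt(res$log$dsc[nrow(res$log)], res$log$dsc[1] - 0.05)
})

test_that("the chunk sampler crops consistently and visits every grid origin", {
  p <- small_phantom(seed = 70, edge = 32, noise = 0)
  inst <- cochleaseg:::prepare_instance(p$volume$data, p$label$data,
                                        p$landmarks, chunk = 16L, stride = 8L)
  n_origins <- nrow(inst$grid$origins)
  seen <- character(0)
  with_seed(71, {
    for (i in 1:400) {
      s <- sample_chunk(list(inst), augmentation_protocol("none"))
      expect_identical(dim(s$intensity), c(16L, 16L, 16L))
      # recover the origin from the landmark shift; the crop must agree
      o <- p$landmarks$helicotrema - s$landmarks$helicotrema
      expect_true(all(o == floor(o)))
      expect_identical(s$intensity,
                       p$volume$data[o[1] + 1:16, o[2] + 1:16, o[3] + 1:16])
      seen <- c(seen, paste(o, collapse = ","))
    }
  })
  expect_identical(length(unique(seen)), n_origins)
})

test_that("checkpoints round-trip through disk with config and seed", {
  net <- tiny_net(seed = 72)
  f <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(net, f, extra = list(iteration = 5L))
  back <- read_checkpoint(f)
  expect_identical(back$params, net$params)
  expect_identical(back$config, net$config)
  expect_identical(back$seed, net$seed)
  x <- array(rnorm(16^3), c(16, 16, 16))
  expect_identical(network_forward(back, x)$seg$value,
                   network_forward(net, x)$seg$value)
})
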