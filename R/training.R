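# The optimization loop: chunk sampling with augmentation and scheduled
# heatmap targets, gradient accumulation (averaged), trapezoidal learning
# rate, periodic validation (IoU/DSC for the segmentation head, MSE/MAE for
# the heatmap head, and the validation loss), best + last checkpointing,
# and k-fold cross-validation planning.

#' Training configuration
#'
#' @param iterations total iterations (one iteration = one forward/backward
#'   pass of a chunk batch).
#' @param accumulation update parameters every `accumulation` iterations
#'   with the mean of the accumulated gradients.
#' @param optimizer_kind `"adamw"` or `"sgd"`.
#' @param weight_decay AdamW lambda.
#' @param peak_lr,warmup_frac,plateau_frac,anneal_frac see [lr_schedule()].
#' @param validation_every validation cadence in iterations.
#' @param seed seed for sampling, augmentation and initialisation.
#' @return A `train_config` object.
#' @export
train_config <- function(iterations = 75000L, accumulation = 10L,
                         optimizer_kind = "adamw", weight_decay = 0.025,
                         peak_lr = 1e-3, warmup_frac = 0.1,
                         plateau_frac = 0.6, anneal_frac = 0.3,
                         validation_every = 750L, seed = 1L) {
  stopifnot(iterations >= 1, accumulation >= 1, validation_every >= 1)
  structure(list(iterations = as.integer(iterations),
                 accumulation = as.integer(accumulation),
                 optimizer_kind = optimizer_kind, weight_decay = weight_decay,
                 peak_lr = peak_lr, warmup_frac = warmup_frac,
                 plateau_frac = plateau_frac, anneal_frac = anneal_frac,
                 validation_every = as.integer(validation_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Plan k-fold cross-validation splits
#'
#' Each fold draws its validation instances by independent random sampling
#' (random resampling per fold rather than a strict partition), so
#' validation sets of different folds may overlap.
#'
#' @param instance_ids vector of instance identifiers.
#' @param k fold count.
#' @param n_val validation instances per fold.
#' @param seed seed for the draws.
#' @return A `fold_plan`: list of `k` lists with `train` and `validation`
#'   id vectors (disjoint, jointly covering all ids).
#' @export
make_folds <- function(instance_ids, k = 3L, n_val = 5L, seed = 1L) {
  n <- length(instance_ids)
  if (n_val >= n) stop("n_val must be smaller than the number of instances")
  folds <- with_seed(seed, {
    lapply(seq_len(k), function(i) {
      val <- sample(instance_ids, n_val)
      list(train = setdiff(instance_ids, val), validation = val)
    })
  })
  structure(folds, class = "fold_plan", k = k)
}

#' Sample one training chunk
#'
#' Draws an instance and a chunk origin uniformly from the precomputed
#' grids, crops intensity and label, shifts landmarks into chunk
#' coordinates, and applies the augmentation protocol. Uses R's RNG (seed
#' the stream for reproducibility).
#'
#' @param dataset list of instances, each with `intensity` (3D array),
#'   `label` (3D array), `landmarks` ([new_landmark_set()]) and `grid`
#'   (a [plan_chunks()] grid).
#' @param protocol an [augmentation_protocol()].
#' @return A [train_sample()].
#' @export
sample_chunk <- function(dataset, protocol) {
  inst <- dataset[[sample.int(length(dataset), 1L)]]
  grid <- inst$grid
  o <- grid$origins[sample.int(nrow(grid$origins), 1L), ]
  k <- grid$chunk
  intensity <- pad_volume_data(inst$intensity, grid)
  label <- pad_volume_data(inst$label, grid)
  cs <- lapply(1:3, function(a) o[a] + seq_len(k))
  lm_shift <- o - grid$pad[1, ]
  lm <- new_landmark_set(inst$landmarks$helicotrema - lm_shift,
                         inst$landmarks$oval_window - lm_shift,
                         inst$landmarks$round_window - lm_shift)
  s <- train_sample(intensity[cs[[1]], cs[[2]], cs[[3]], drop = FALSE],
                    label[cs[[1]], cs[[2]], cs[[3]], drop = FALSE], lm)
  apply_protocol(s, protocol)
}

prepare_instance <- function(intensity, label, landmarks, chunk, stride) {
  list(intensity = intensity, label = label, landmarks = landmarks,
       grid = plan_chunks(dim(intensity), chunk, stride))
}

validate_network <- function(net, val_set, schedule, iteration, loss_cfg,
                             heads = "both") {
  ab <- schedule_at(schedule, iteration)
  aux_levels <- if (net$config$deep_supervision && net$config$levels >= 2L)
    2:min(net$config$levels, 4L) else integer(0)
  rows <- lapply(val_set, function(inst) {
    # deterministic centre chunk per validation instance
    grid <- inst$grid
    mid <- grid$origins[ceiling(nrow(grid$origins) / 2), ]
    k <- grid$chunk
    intensity <- pad_volume_data(inst$intensity, grid)
    label <- pad_volume_data(inst$label, grid)
    cs <- lapply(1:3, function(a) mid[a] + seq_len(k))
    lm_shift <- mid - grid$pad[1, ]
    lm <- new_landmark_set(inst$landmarks$helicotrema - lm_shift,
                           inst$landmarks$oval_window - lm_shift,
                           inst$landmarks$round_window - lm_shift)
    chunk <- intensity[cs[[1]], cs[[2]], cs[[3]], drop = FALSE]
    lab <- label[cs[[1]], cs[[2]], cs[[3]], drop = FALSE]
    bundle <- network_forward(net, chunk, heads = heads)
    targets <- make_targets(lab, lm, ab["alpha"], ab["beta"], aux_levels)
    loss <- composite_loss(bundle, targets, loss_cfg)
    seg_bin <- array(as.integer(bundle$seg$value >= 0.5), dim(lab))
    if (!is.null(bundle$heatmaps)) {
      hm_err <- bundle$heatmaps$value - targets$heatmaps
      mse <- mean(hm_err^2); mae <- mean(abs(hm_err))
    } else {
      mse <- NA_real_; mae <- NA_real_
    }
    c(dsc = dsc(seg_bin, lab), iou = iou(seg_bin, lab),
      mse = mse, mae = mae, loss = loss$total$value)
  })
  colMeans(do.call(rbind, rows))
}

#' Train a network on one fold
#'
#' Runs the full optimization loop: per iteration one chunk is sampled,
#' augmented, forwarded, and the composite loss backpropagated; parameters
#' update every `accumulation` iterations with the mean of the accumulated
#' gradients; validation metrics are recorded every `validation_every`
#' iterations and the best-by-validation-DSC and last parameter sets are
#' kept (ties resolve toward the higher iteration).
#'
#' @param net a [build_network()] network (its parameters are the starting
#'   point).
#' @param train_set,val_set lists of instances from [prepare_instance()].
#' @param cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param schedule a [heatmap_schedule()].
#' @param protocol an [augmentation_protocol()].
#' @param heads `"both"` for the joint dual-head objective, `"seg"` for the
#'   single-task segmentation-only variant (heatmap decoder untouched).
#' @param verbose print validation lines?
#' @return List with `best` and `last` checkpoints (params + iteration +
#'   metrics), the validation `log` (data.frame) and the final `net`.
#' @export
train_one_fold <- function(net, train_set, val_set, cfg,
                           loss_cfg = loss_config(),
                           schedule = heatmap_schedule(),
                           protocol = augmentation_protocol("none"),
                           heads = "both", verbose = FALSE) {
  sched <- lr_schedule(cfg$iterations, cfg$peak_lr, cfg$warmup_frac,
                       cfg$plateau_frac, cfg$anneal_frac)
  opt <- optimizer(cfg$optimizer_kind, weight_decay = cfg$weight_decay)
  aux_levels <- if (net$config$deep_supervision && net$config$levels >= 2L)
    2:min(net$config$levels, 4L) else integer(0)
  acc <- NULL; n_acc <- 0L
  log_rows <- list()
  best <- list(dsc = -Inf, params = NULL, iteration = NA_integer_)
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations) - 1L) {
      ab <- schedule_at(schedule, it)
      s <- sample_chunk(train_set, protocol)
      bundle <- network_forward(net, s$intensity, heads = heads)
      targets <- make_targets(s$label, s$landmarks, ab["alpha"], ab["beta"],
                              aux_levels)
      loss <- composite_loss(bundle, targets, loss_cfg)
      if (!is.finite(loss$total$value))
        stop("non-finite training loss at iteration ", it,
             " (seg = ", loss$components["seg"],
             ", heatmap = ", loss$components["heatmap"], ")")
      ag_backward(loss$total)
      acc <- add_grads(acc, collect_grads(bundle))
      n_acc <- n_acc + 1L
      if (n_acc == cfg$accumulation) {
        step <- optimizer_step(opt, net$params, scale_grads(acc, 1 / n_acc),
                               lr_at(sched, it))
        net$params <- step$params
        opt <- step$opt
        acc <- NULL; n_acc <- 0L
      }
      if ((it + 1L) %% cfg$validation_every == 0L && length(val_set) > 0) {
        vm <- validate_network(net, val_set, schedule, it, loss_cfg, heads)
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(iteration = it + 1L, lr = lr_at(sched, it),
                     train_loss = loss$total$value, t(vm))
        if (verbose)
          message(sprintf("it %d  val DSC %.4f  IoU %.4f  MSE %.5f  loss %.4f",
                          it + 1L, vm["dsc"], vm["iou"], vm["mse"], vm["loss"]))
        if (vm["dsc"] >= best$dsc) {
          best <- list(dsc = vm["dsc"], params = net$params,
                       iteration = it + 1L, metrics = vm)
        }
      }
    }
  })
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(iteration = integer(0))
  last <- list(params = net$params, iteration = cfg$iterations,
               metrics = if (length(log_rows)) log_rows[[length(log_rows)]] else NULL)
  if (is.null(best$params)) best <- c(last, dsc = NA_real_)
  list(best = best, last = last, log = log, net = net)
}

#' Save / load a checkpoint
#'
#' A checkpoint carries the parameters, the full network configuration and
#' the seeds, sufficient to rebuild and rerun deterministically on CPU.
#'
#' @param net a [build_network()] network.
#' @param path file path (RDS).
#' @param extra optional named list stored alongside.
#' @return `path` (write) or the network (read).
#' @export
write_checkpoint <- function(net, path, extra = list()) {
  saveRDS(c(list(config = net$config, params = net$params, seed = net$seed,
                 in_channels = net$in_channels), extra), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  structure(list(config = ck$config, params = ck$params, seed = ck$seed,
                 in_channels = ck$in_channels %||% 1L),
            class = "network")
}
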