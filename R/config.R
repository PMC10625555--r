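# YAML experiment configuration: one file with model / loss / train /
# heatmap_schedule / augmentation / chunking sections, cross-validated at
# load (channel-cascade length, chunk-edge divisibility, schedule
# monotonicity), plus the experiment manifest that makes a run replayable.

default_config <- function() {
  list(
    model = list(levels = 4L, channels = c(32, 64, 128, 256, 320),
                 norm = "instance", activation = "mish", act_slope = 0.025,
                 attention = "global", deep_supervision = TRUE),
    loss = list(seg_loss = "ce_plus_dice", dice_eps = 1e-5,
                deep_supervision_weights = c(1, 0.5, 0.25, 0.125),
                weight_decay = 0.025),
    train = list(iterations = 75000L, accumulation = 15L,
                 optimizer_kind = "adamw", peak_lr = 1e-3,
                 warmup_frac = 0.1, plateau_frac = 0.6, anneal_frac = 0.3,
                 validation_every = 750L, seed = 1L),
    heatmap_schedule = list(milestones = c(0, 15000, 37500),
                            alpha = c(1, 5, 10), beta = c(6, 4, 2)),
    augmentation = list(name = "beta", p = 0.5,
                        intensity_scale_range = c(0.8, 1.2),
                        gaussian_noise_sigma = 0.1),
    chunking = list(chunk = 128L, stride = 25L)
  )
}

KNOWN_SECTIONS <- c("model", "loss", "train", "heatmap_schedule",
                    "augmentation", "chunking")

#' Load and validate an experiment configuration
#'
#' Reads a YAML file (or takes a list), merges it over the package
#' defaults, constructs every module's config object and cross-validates
#' them: unknown sections/keys are rejected, the channel cascade must match
#' the level count, the chunk edge must be divisible by `2^levels`, and the
#' heatmap schedule must be monotone.
#'
#' @param path YAML file path, or `NULL` to use `overrides` only.
#' @param overrides named list merged over the file content.
#' @return List of validated config objects: `model` ([network_config()]),
#'   `loss` ([loss_config()]), `train` ([train_config()]), `schedule`
#'   ([heatmap_schedule()]), `augmentation` ([augmentation_protocol()]),
#'   `chunking` (list `chunk`, `stride`), `raw` (the merged list).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- modifyList(user, overrides)
  bad <- setdiff(names(user), KNOWN_SECTIONS)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  raw <- default_config()
  for (sec in names(user)) {
    bad_keys <- setdiff(names(user[[sec]]), names(raw[[sec]]))
    if (length(bad_keys))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad_keys, collapse = ", "))
    raw[[sec]] <- modifyList(raw[[sec]], user[[sec]])
  }
  model <- do.call(network_config, raw$model)
  loss <- do.call(loss_config, c(raw$loss, list(heatmap_loss = "mse")))
  train <- do.call(train_config, raw$train)
  schedule <- do.call(heatmap_schedule, raw$heatmap_schedule)
  protocol <- do.call(augmentation_protocol, raw$augmentation)
  if (raw$chunking$chunk %% 2^model$levels != 0)
    stop("chunk edge ", raw$chunking$chunk,
         " is not divisible by 2^levels = ", 2^model$levels)
  lr_schedule(train$iterations, train$peak_lr, train$warmup_frac,
              train$plateau_frac, train$anneal_frac)  # validates fractions
  list(model = model, loss = loss, train = train, schedule = schedule,
       augmentation = protocol, chunking = raw$chunking, raw = raw)
}

#' Write an experiment manifest
#'
#' Records the full config snapshot, seeds, package version, artifact
#' paths and a timestamp: enough to replay the run deterministically on
#' CPU.
#'
#' @param path output JSON path.
#' @param config a [load_config()] result.
#' @param paths named list of artifact paths (must exist).
#' @param extra named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, paths = list(), extra = list()) {
  for (p in unlist(paths))
    if (!file.exists(p)) stop("manifest references missing path '", p, "'")
  manifest <- c(list(package_version = as.character(utils::packageVersion("cochleaseg")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                     config = config$raw, paths = paths), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
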