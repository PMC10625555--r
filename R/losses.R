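# Component and composite losses. The training objective is the unweighted
# sum of a segmentation term (binary cross-entropy plus soft Dice by
# default), the heatmap mean-squared-error term and weight decay; weight
# decay is decoupled and lives in the optimizer, not here. With deep
# supervision each term is a weighted sum over the output terminals.

SEG_LOSS_NAMES <- c("ce_plus_dice", "dice", "squared_dice", "log_cosh_dice", "ce")

#' Loss configuration
#'
#' @param seg_loss segmentation loss variant, one of `"ce_plus_dice"`
#'   (default), `"dice"`, `"squared_dice"`, `"log_cosh_dice"`, `"ce"`.
#' @param dice_eps Dice smoothing constant.
#' @param deep_supervision_weights per-terminal coefficients for terminals
#'   t0, t1, t2, t3 (full to 1/8 resolution); normalised to sum 1 over the
#'   terminals actually present.
#' @param heatmap_loss only `"mse"` is defined.
#' @param weight_decay decoupled weight-decay strength lambda, applied by
#'   the AdamW optimizer (recorded here so a config snapshot is complete).
#' @return A `loss_config` object.
#' @export
loss_config <- function(seg_loss = SEG_LOSS_NAMES, dice_eps = 1e-5,
                        deep_supervision_weights = c(1, 0.5, 0.25, 0.125),
                        heatmap_loss = "mse", weight_decay = 0.025) {
  seg_loss <- match.arg(seg_loss)
  if (heatmap_loss != "mse") stop("unknown heatmap loss '", heatmap_loss, "'")
  stopifnot(dice_eps > 0, all(deep_supervision_weights >= 0),
            deep_supervision_weights[1] > 0, weight_decay >= 0)
  structure(list(seg_loss = seg_loss, dice_eps = dice_eps,
                 deep_supervision_weights = deep_supervision_weights,
                 heatmap_loss = heatmap_loss, weight_decay = weight_decay),
            class = "loss_config")
}

#' Soft Dice loss (plain numeric version)
#'
#' `1 - (2 sum(p t) + eps) / (sum(p) + sum(t) + eps)`. The autograd path
#' uses the same formula; this numeric version backs tests and validation
#' metrics.
#'
#' @param pred array of probabilities in `[0, 1]`.
#' @param target congruent binary array.
#' @param eps smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(pred, target, eps = 1e-5) {
  if (!identical(dim(pred), dim(target)) && length(pred) != length(target))
    stop("prediction and target shapes differ")
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

#' Binary cross-entropy loss (plain numeric version)
#'
#' Voxel-mean binary cross-entropy with predictions clamped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @inheritParams soft_dice_loss
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(pred, target) {
  if (length(pred) != length(target))
    stop("prediction and target shapes differ")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Heatmap mean squared error (plain numeric version)
#'
#' @param pred,target congruent heatmap stacks.
#' @return Mean over all channels and voxels of the squared difference.
#' @export
heatmap_mse <- function(pred, target) {
  if (!identical(dim(pred), dim(target)))
    stop("heatmap shapes differ")
  mean((pred - target)^2)
}

#' Segmentation loss variant (numeric)
#'
#' Dispatcher over the ablation variants; all are `>= 0` and vanish (up to
#' the eps residual) at a perfect prediction.
#'
#' @param name variant name (see [loss_config()]).
#' @return A function `(pred, target, eps) -> scalar`.
#' @export
seg_loss_variant <- function(name) {
  if (!name %in% SEG_LOSS_NAMES)
    stop("unknown segmentation loss '", name, "'")
  switch(name,
    ce = function(pred, target, eps = 1e-5) cross_entropy_loss(pred, target),
    dice = function(pred, target, eps = 1e-5) soft_dice_loss(pred, target, eps),
    squared_dice = function(pred, target, eps = 1e-5) {
      1 - (2 * sum(pred * target) + eps) / (sum(pred^2) + sum(target^2) + eps)
    },
    log_cosh_dice = function(pred, target, eps = 1e-5)
      log(cosh(soft_dice_loss(pred, target, eps))),
    ce_plus_dice = function(pred, target, eps = 1e-5)
      cross_entropy_loss(pred, target) + soft_dice_loss(pred, target, eps)
  )
}

# tape version of the configured segmentation loss
ag_seg_loss <- function(pred, target, cfg) {
  switch(cfg$seg_loss,
    ce = ag_bce(pred, target),
    dice = ag_dice(pred, target, cfg$dice_eps, "dice"),
    squared_dice = ag_dice(pred, target, cfg$dice_eps, "squared"),
    log_cosh_dice = ag_dice(pred, target, cfg$dice_eps, "log_cosh"),
    ce_plus_dice = ag_wsum(list(ag_bce(pred, target),
                                ag_dice(pred, target, cfg$dice_eps, "dice")))
  )
}

# nearest-neighbour downsampling of a chunk-shaped array by factor f
downsample_nearest <- function(x, f) {
  d <- dim(x)
  x[seq(1, d[1], by = f), seq(1, d[2], by = f), seq(1, d[3], by = f),
    drop = FALSE]
}

#' Build training targets for all supervision terminals
#'
#' t0 targets are the label chunk and the Gaussian heatmaps rendered at the
#' scheduled `(alpha, beta)`. Auxiliary targets at 1/2^k resolution use
#' nearest-neighbour downsampled labels and Gaussians re-rendered on the
#' coarse grid (landmark coordinates and spread divided by the factor).
#'
#' @param label binary 3D label chunk.
#' @param landmarks [new_landmark_set()] in chunk voxel units.
#' @param alpha,beta heatmap amplitude and spread (see [render_heatmaps()]).
#' @param aux_levels integer vector of decoder levels (2 = 1/2 resolution
#'   and so on) needing auxiliary targets; `integer(0)` for none.
#' @return List with `seg`, `heatmaps` and `aux` (list of
#'   `(seg, heatmaps, level)`).
#' @export
make_targets <- function(label, landmarks, alpha, beta,
                         aux_levels = integer(0)) {
  shape <- dim(label)
  out <- list(seg = label,
              heatmaps = render_heatmaps(landmarks, shape, alpha, beta),
              aux = list())
  for (lv in aux_levels) {
    f <- 2^(lv - 1L)
    lm <- new_landmark_set(landmarks$helicotrema / f, landmarks$oval_window / f,
                           landmarks$round_window / f)
    out$aux[[length(out$aux) + 1L]] <-
      list(seg = downsample_nearest(label, f),
           heatmaps = render_heatmaps(lm, shape %/% f, alpha, max(beta / f, 0.5)),
           level = lv)
  }
  out
}

#' Composite loss on the autograd tape
#'
#' Total = segmentation term + heatmap MSE term, each summed over the
#' supervision terminals with the configured weights (normalised to sum 1
#' over the terminals present). Weight decay is not added here; it is
#' decoupled into the optimizer step.
#'
#' @param bundle a [network_forward()] prediction bundle.
#' @param targets a [make_targets()] list matching the bundle's terminals.
#' @param cfg a [loss_config()].
#' @return List with `total` (scalar node) and numeric `components`
#'   (seg/heatmap per terminal) for logging.
#' @export
composite_loss <- function(bundle, targets, cfg) {
  n_term <- 1L + length(bundle$aux)
  if (length(bundle$aux) > 0 && length(targets$aux) < length(bundle$aux))
    stop("deep supervision is on but auxiliary targets are missing")
  w <- cfg$deep_supervision_weights[seq_len(n_term)]
  w <- w / sum(w)
  totals <- list()
  components <- c(seg = 0, heatmap = 0)
  if (!is.null(bundle$seg)) {
    seg_terms <- list(ag_seg_loss(bundle$seg, targets$seg, cfg))
    for (i in seq_along(bundle$aux))
      seg_terms[[i + 1L]] <- ag_seg_loss(bundle$aux[[i]]$seg,
                                         targets$aux[[i]]$seg, cfg)
    totals$seg <- ag_wsum(seg_terms, w)
    components["seg"] <- totals$seg$value
  }
  if (!is.null(bundle$heatmaps)) {
    hm_terms <- list(ag_mse(bundle$heatmaps, targets$heatmaps))
    for (i in seq_along(bundle$aux))
      hm_terms[[i + 1L]] <- ag_mse(bundle$aux[[i]]$heatmaps,
                                   targets$aux[[i]]$heatmaps)
    totals$hm <- ag_wsum(hm_terms, w)
    components["heatmap"] <- totals$hm$value
  }
  if (length(totals) == 0) stop("bundle has no head outputs")
  list(total = ag_wsum(unname(totals)), components = components)
}
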