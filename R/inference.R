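# Full-volume prediction: chunking, per-chunk rotation-based test-time
# augmentation (identity plus quarter-turn rotations about all three axes,
# 10 supersamples), voxel-wise averaging into the final prediction and a
# per-voxel standard-deviation map that doubles as an out-of-distribution
# signal, followed by binarisation and global landmark decoding.

#' Build the rotation TTA plan
#'
#' Identity plus 90/180/270-degree quarter-turn rotations about each of the
#' three spatial axes: 10 exactly invertible voxel permutations.
#'
#' @return A `tta_plan`: list with `transforms` (list of `(axis, k)` pairs,
#'   axis 0 = identity) and `count`.
#' @export
tta_plan <- function() {
  tr <- list(list(axis = 0L, k = 0L))
  for (axis in 1:3) for (k in 1:3)
    tr[[length(tr) + 1L]] <- list(axis = axis, k = k)
  structure(list(transforms = tr, count = length(tr)), class = "tta_plan")
}

apply_tta_transform <- function(arr, tf) {
  if (tf$axis == 0L) arr else rot90_3d(arr, tf$axis, tf$k)
}

invert_tta_transform <- function(arr, tf) {
  if (tf$axis == 0L) arr else rot90_3d(arr, tf$axis, 4L - tf$k)
}

# normalise a network or a plain closure into chunk -> list(seg, heatmaps)
as_forward_fn <- function(model) {
  if (inherits(model, "network")) {
    function(chunk) {
      b <- network_forward(model, chunk)
      list(seg = array(b$seg$value, dim(chunk)),
           heatmaps = b$heatmaps$value)
    }
  } else if (is.function(model)) {
    model
  } else stop("model must be a network or a forward function")
}

#' Predict one chunk with test-time augmentation
#'
#' For every transform in the plan the chunk is rotated, forwarded, and
#' both head outputs are rotated back; the supersamples are averaged on the
#' voxel level. The segmentation supersample stack is returned for
#' uncertainty estimation.
#'
#' @param model a trained [build_network()] network or a forward closure
#'   `chunk -> list(seg = 3D array, heatmaps = (3, ...) array)`.
#' @param chunk cubic 3D array.
#' @param plan a [tta_plan()]; `NULL` disables TTA (single forward pass).
#' @return List with `seg` (mean probability map), `heatmaps` (mean
#'   3-channel stack), `seg_stack` (supersamples x voxels array) and
#'   `seg_sd` (per-voxel population SD over supersamples; zeros without
#'   TTA).
#' @export
predict_chunk_tta <- function(model, chunk, plan = tta_plan()) {
  fwd <- as_forward_fn(model)
  if (is.null(plan)) plan <- structure(list(transforms = list(list(axis = 0L, k = 0L)),
                                            count = 1L), class = "tta_plan")
  d <- dim(chunk)
  n <- plan$count
  seg_stack <- array(0, c(n, d))
  hm_acc <- NULL
  for (i in seq_len(n)) {
    tf <- plan$transforms[[i]]
    out <- fwd(apply_tta_transform(chunk, tf))
    seg <- invert_tta_transform(array(out$seg, d), tf)
    hm <- out$heatmaps
    hm_inv <- array(0, dim(hm))
    for (ch in seq_len(dim(hm)[1]))
      hm_inv[ch, , , ] <- invert_tta_transform(array(hm[ch, , , ], d), tf)
    seg_stack[i, , , ] <- seg
    hm_acc <- if (is.null(hm_acc)) hm_inv else hm_acc + hm_inv
  }
  seg_mean <- colMeans(seg_stack)           # over the supersample axis
  seg_sd <- if (n > 1) {
    sqrt(pmax(colMeans(seg_stack^2) - seg_mean^2, 0))
  } else array(0, d)
  list(seg = seg_mean, heatmaps = hm_acc / n,
       seg_stack = seg_stack, seg_sd = seg_sd)
}

#' Predict a full volume
#'
#' The automated end of the pipeline: the (preprocessed) volume is chunked
#' with the sliding-window grid, each chunk is predicted (optionally with
#' TTA), per-chunk outputs are fused by voxel mean, the fused probability
#' map is binarised at `threshold`, and the landmarks are decoded from the
#' fused full-volume heatmaps by global argmax.
#'
#' @param model a trained network or forward closure (see
#'   [predict_chunk_tta()]).
#' @param v a [new_volume()], already preprocessed (or `preprocess = TRUE`
#'   to apply the in-domain clip + z-normalization first).
#' @param chunk,stride sliding-window geometry (defaults 128 / 25).
#' @param tta use rotation TTA?
#' @param threshold binarisation threshold on the fused probability map.
#' @param preprocess apply [preprocess_internal()] to `v` first?
#' @return List with `label` ([new_label_volume()]), `prob` (3D array),
#'   `landmarks` ([new_landmark_set()]), `heatmaps` ((3, ...) array),
#'   `uncertainty` (list `data` = per-voxel SD map, `summary` = volume
#'   mean, `n_tta`).
#' @export
predict_volume <- function(model, v, chunk = 128L, stride = 25L,
                           tta = TRUE, threshold = 0.5, preprocess = FALSE) {
  if (preprocess) v <- preprocess_internal(v)$volume
  plan <- if (tta) tta_plan() else NULL
  grid <- plan_chunks(dim(v$data), chunk, stride)
  chunks <- extract_chunks(v$data, grid)
  seg_pred <- vector("list", length(chunks))
  sd_pred <- vector("list", length(chunks))
  hm_pred <- lapply(1:3, function(i) vector("list", length(chunks)))
  for (i in seq_along(chunks)) {
    out <- predict_chunk_tta(model, chunks[[i]], plan)
    if (!all(is.finite(out$seg)) || !all(is.finite(out$heatmaps)))
      stop("non-finite prediction in chunk ", i)
    seg_pred[[i]] <- out$seg
    sd_pred[[i]] <- out$seg_sd
    for (ch in 1:3) hm_pred[[ch]][[i]] <- array(out$heatmaps[ch, , , ],
                                                dim(chunks[[i]]))
  }
  prob <- aggregate_chunks(seg_pred, grid)
  sd_map <- aggregate_chunks(sd_pred, grid)
  hm_full <- array(0, c(3L, dim(v$data)))
  for (ch in 1:3) hm_full[ch, , , ] <- aggregate_chunks(hm_pred[[ch]], grid)
  label <- new_label_volume(array(as.integer(prob >= threshold), dim(prob)),
                            spacing = v$spacing, origin = v$origin)
  list(label = label, prob = prob,
       landmarks = decode_heatmaps(hm_full), heatmaps = hm_full,
       uncertainty = structure(list(data = sd_map, summary = mean(sd_map),
                                    n_tta = if (tta) tta_plan()$count else 1L),
                               class = "uncertainty_map"))
}

#' Volume-mean TTA standard deviation
#'
#' The scalar out-of-distribution signal: the mean over all voxels of the
#' per-voxel standard deviation of the TTA supersamples. Domain-shifted or
#' pathological inputs show a strongly elevated value compared to
#' in-distribution scans.
#'
#' @param u the `uncertainty` element of a [predict_volume()] result.
#' @return Scalar mean SD.
#' @export
uncertainty_summary <- function(u) {
  if (!inherits(u, "uncertainty_map")) stop("not an uncertainty map")
  if (u$n_tta < 2)
    stop("uncertainty summary is undefined without TTA (need >= 2 supersamples)")
  mean(u$data)
}
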