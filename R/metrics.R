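# Segmentation and localization evaluation criteria: overlap scores (DSC as
# the primary metric, IoU, volumetric similarity), Hausdorff distances over
# full foreground voxel sets, per-landmark Euclidean deviations, and the
# mean/SD/median table aggregation used for cohort reports.

as_binary_mask <- function(x) {
  d <- if (inherits(x, "volume")) x$data else x
  if (!all(d %in% c(0, 1))) stop("mask must be binary (values 0/1)")
  d
}

check_congruent_masks <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks are on incongruent grids: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

#' Dice-Sorensen similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b binary masks (3D arrays or [new_label_volume()] objects) on
#'   congruent grids.
#' @return A scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  check_congruent_masks(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Intersection-over-union (Jaccard index)
#'
#' `|A n B| / |A u B|`; 1 when both masks are empty.
#' @inheritParams dsc
#' @return A scalar in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  check_congruent_masks(a, b)
  inter <- sum(a * b)
  uni <- sum(a) + sum(b) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Volumetric similarity
#'
#' `1 - ||A| - |B|| / (|A| + |B|)`: agreement of foreground volumes
#' irrespective of overlap; 1 when both masks are empty.
#' @inheritParams dsc
#' @return A scalar in `[0, 1]`.
#' @export
vs <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  check_congruent_masks(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  1 - abs(sa - sb) / (sa + sb)
}

mask_coords <- function(m) {
  idx <- which(m == 1)
  if (length(idx) == 0) return(NULL)
  arrayInd(idx, dim(m)) - 1
}

#' Hausdorff distance and its voxel-averaged variant
#'
#' Distances are computed between the full foreground voxel sets (not
#' extracted surfaces) in voxel units. The directed distance of voxel `x`
#' to set `S` is the minimum Euclidean distance over the voxels of `S`;
#' `HD` is the maximum of the two directed maxima, `avgHD` the mean of the
#' two directed averages.
#'
#' @inheritParams dsc
#' @return Named numeric vector `c(hd = , avg_hd = )`.
#' @export
hausdorff <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  check_congruent_masks(a, b)
  ca <- mask_coords(a); cb <- mask_coords(b)
  if (is.null(ca) || is.null(cb))
    stop("Hausdorff distance is undefined for an empty mask")
  dab <- cpp_directed_min_dist(ca, cb)
  dba <- cpp_directed_min_dist(cb, ca)
  c(hd = max(max(dab), max(dba)),
    avg_hd = mean(c(mean(dab), mean(dba))))
}

#' Per-landmark Euclidean deviation
#'
#' Euclidean distance between predicted and ground-truth coordinates per
#' landmark, in voxel units, plus their mean.
#'
#' @param pred,truth [new_landmark_set()] objects.
#' @return Named vector with the three per-landmark deviations and `average`.
#' @export
landmark_deviation <- function(pred, truth) {
  devs <- vapply(LANDMARK_NAMES, function(nm) {
    p <- pred[[nm]]; t <- truth[[nm]]
    if (is.null(p) || anyNA(p)) stop("prediction is missing landmark '", nm, "'")
    if (is.null(t) || anyNA(t)) stop("ground truth is missing landmark '", nm, "'")
    sqrt(sum((p - t)^2))
  }, numeric(1))
  c(devs, average = mean(devs))
}

#' Evaluate one predicted instance against its ground truth
#'
#' @param pred_label,true_label binary masks on congruent grids.
#' @param pred_landmarks,true_landmarks [new_landmark_set()] objects
#'   (optional; `NULL` skips localization metrics).
#' @return A one-row data.frame of all per-instance criteria.
#' @export
evaluate_instance <- function(pred_label, true_label,
                              pred_landmarks = NULL, true_landmarks = NULL) {
  hd <- hausdorff(pred_label, true_label)
  row <- data.frame(dsc = dsc(pred_label, true_label),
                    iou = iou(pred_label, true_label),
                    vs = vs(pred_label, true_label),
                    hd = unname(hd["hd"]), avg_hd = unname(hd["avg_hd"]))
  if (!is.null(pred_landmarks) && !is.null(true_landmarks)) {
    dev <- landmark_deviation(pred_landmarks, true_landmarks)
    row$dev_helicotrema <- dev[["helicotrema"]]
    row$dev_oval_window <- dev[["oval_window"]]
    row$dev_round_window <- dev[["round_window"]]
    row$dev_average <- dev[["average"]]
  }
  row
}

#' Aggregate per-instance metric rows into a cohort report
#'
#' Mean, standard deviation (sample convention, divisor `n - 1`; 0 for a
#' single row) and median per column, in the layout of a results table.
#'
#' @param rows data.frame of per-instance rows ([evaluate_instance()]).
#' @return A `metrics_report`: list with `per_instance` and `aggregate`
#'   (rows mean/sd/median).
#' @export
aggregate_metrics <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("need at least one per-instance metric row")
  agg <- as.data.frame(lapply(rows, function(col) {
    c(mean = mean(col),
      sd = if (length(col) > 1) sd(col) else 0,
      median = median(col))
  }))
  rownames(agg) <- c("mean", "sd", "median")
  structure(list(per_instance = rows, aggregate = agg),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>", nrow(x$per_instance), "instance(s)\n")
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Worst-case cochlear-duct-length error from landmark deviations
#'
#' A cochlear duct length measurement is initialized from the helicotrema
#' and round-window positions, so in the worst case both localization errors
#' add. Converts the summed deviation from voxel units to millimetres via
#' the voxel edge length.
#'
#' @param dev_helicotrema,dev_round_window mean deviations in voxel units.
#' @param voxel_um voxel edge length in micrometres.
#' @return Worst-case error in millimetres.
#' @export
cdl_worst_case <- function(dev_helicotrema, dev_round_window, voxel_um = 99) {
  (dev_helicotrema + dev_round_window) * voxel_um / 1000
}
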