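# Intensity normalization: quantile clipping, z-normalization and quantile
# (histogram) matching. The in-domain pipeline is clip(0.01, 0.99) followed
# by z-normalization computed on the whole volume; domain-shifted external
# scans are additionally remapped onto a stored training-domain reference
# distribution, cluster by cluster.

#' Clip a volume at empirical quantiles
#'
#' Intensities below the `q_low` quantile or above the `q_high` quantile of
#' the whole volume are clamped to those quantile values; everything in
#' between is unchanged. Quantiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param v a [new_volume()].
#' @param q_low,q_high quantile levels in `[0, 1]`, `q_low < q_high`.
#' @return The clipped volume.
#' @export
clip_quantiles <- function(v, q_low = 0.01, q_high = 0.99) {
  stopifnot(q_low >= 0, q_high <= 1, q_low < q_high)
  q <- quantile(v$data, c(q_low, q_high), names = FALSE)
  new_volume(array(pmin(pmax(v$data, q[1]), q[2]), dim(v$data)),
             spacing = v$spacing, origin = v$origin)
}

#' Z-normalize a volume
#'
#' Rescales intensities to zero mean and unit standard deviation (population
#' convention, i.e. divisor `n`), returning the statistics used so they can
#' be reapplied to further volumes of the same domain.
#'
#' @param v a [new_volume()].
#' @return A list `(volume, mean, sd)`.
#' @export
znormalize <- function(v) {
  mu <- mean(v$data)
  sigma <- sqrt(mean((v$data - mu)^2))
  if (sigma == 0) stop("cannot z-normalize a constant volume (sd = 0)")
  list(volume = new_volume((v$data - mu) / sigma, spacing = v$spacing,
                           origin = v$origin),
       mean = mu, sd = sigma)
}

#' Compute a reference quantile table
#'
#' Summarises the intensity distribution of a (preprocessed) reference
#' cohort as a monotone table of `(level, intensity)` pairs, the sidecar
#' against which external domain-shifted volumes are histogram-matched.
#'
#' @param volumes a list of [new_volume()] objects (or a single volume).
#' @param n_levels number of quantile levels (default 256).
#' @return A data.frame with columns `level`, `intensity`.
#' @export
reference_quantiles <- function(volumes, n_levels = 256L) {
  if (inherits(volumes, "volume")) volumes <- list(volumes)
  x <- unlist(lapply(volumes, function(v) as.numeric(v$data)))
  lv <- seq(0, 1, length.out = n_levels)
  data.frame(level = lv, intensity = quantile(x, lv, names = FALSE))
}

validate_reference <- function(ref) {
  if (!is.data.frame(ref) || !all(c("level", "intensity") %in% names(ref)))
    stop("reference must be a data.frame with columns 'level' and 'intensity'")
  if (nrow(ref) < 2) stop("reference table needs at least 2 rows")
  if (is.unsorted(ref$level) || is.unsorted(ref$intensity))
    stop("reference quantile table must be non-decreasing in both columns")
  invisible(TRUE)
}

#' Histogram-match a volume onto a reference distribution
#'
#' Applies the monotone quantile mapping from the input's empirical
#' distribution onto the reference table: each voxel is assigned the
#' reference intensity at its own quantile level. Voxel ranking is preserved
#' (ties allowed), and the output quantiles agree with the reference at the
#' table's levels up to one intensity bin.
#'
#' @param v a [new_volume()].
#' @param ref a reference table from [reference_quantiles()].
#' @return The matched volume.
#' @export
histogram_match <- function(v, ref) {
  validate_reference(ref)
  src <- quantile(v$data, ref$level, names = FALSE)
  # collapse duplicated source quantiles so approx() sees a function
  keep <- !duplicated(src)
  src_u <- src[keep]
  dst_u <- ref$intensity[keep]
  out <- if (length(src_u) == 1L) {
    array(dst_u, dim(v$data))  # constant input maps to reference location
  } else {
    array(approx(src_u, dst_u, xout = as.numeric(v$data), rule = 2)$y,
          dim(v$data))
  }
  new_volume(out, spacing = v$spacing, origin = v$origin)
}

#' Save / load a reference distribution sidecar
#'
#' @param ref a reference table from [reference_quantiles()].
#' @param path JSON path.
#' @return `path` (write) or the table (read).
#' @export
write_reference <- function(ref, path) {
  validate_reference(ref)
  jsonlite::write_json(ref, path, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- as.data.frame(ref)
  validate_reference(ref)
  ref
}

#' Preprocess an in-domain volume
#'
#' The standard pipeline for scans from the training domain: quantile
#' clipping at (0.01, 0.99) followed by z-normalization on the whole volume.
#'
#' @param v a [new_volume()].
#' @param q_low,q_high clipping quantile levels.
#' @return A list `(volume, mean, sd)` as from [znormalize()].
#' @export
preprocess_internal <- function(v, q_low = 0.01, q_high = 0.99) {
  znormalize(clip_quantiles(v, q_low, q_high))
}

#' Preprocess an external, domain-shifted volume
#'
#' Voxels are partitioned into clusters by user-supplied intensity
#' thresholds (domain-shifted cohorts show distinct contrast clusters that
#' are delineated by inspection, not by an automatic algorithm). Each
#' cluster is quantile-clipped and histogram-matched onto the
#' training-domain reference independently; a final global z-normalization
#' brings the composite volume to zero mean / unit sd.
#'
#' @param v a [new_volume()].
#' @param ref training-domain reference table ([reference_quantiles()]).
#' @param cluster_bounds numeric vector of interior thresholds partitioning
#'   the observed intensity range (empty = single cluster).
#' @param q_low,q_high per-cluster clipping levels.
#' @return A list `(volume, mean, sd)`.
#' @export
preprocess_external <- function(v, ref, cluster_bounds = numeric(0),
                                q_low = 0.01, q_high = 0.99) {
  validate_reference(ref)
  breaks <- c(-Inf, sort(cluster_bounds), Inf)
  idx <- findInterval(as.numeric(v$data), breaks, left.open = FALSE)
  out <- array(NA_real_, dim(v$data))
  for (cl in sort(unique(idx))) {
    sel <- idx == cl
    if (!any(sel)) {
      warning("empty intensity cluster ", cl, " skipped")
      next
    }
    sub <- new_volume(array(v$data[sel], c(sum(sel), 1, 1)))
    sub <- clip_quantiles(sub, q_low, q_high)
    sub <- histogram_match(sub, ref)
    out[sel] <- sub$data
  }
  znormalize(new_volume(out, spacing = v$spacing, origin = v$origin))
}
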