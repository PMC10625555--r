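# Gaussian heatmap targets for landmark regression. Channel k of a heatmap
# stack carries alpha * exp(-||x - c_k||^2 / (2 beta^2)) on the voxel grid,
# where c_k is the (possibly fractional) landmark coordinate; beta acts as
# the Gaussian sd ("spread") and alpha as the amplitude. During training the
# targets are sharpened according to a preset schedule: alpha increases and
# beta decreases at fixed iteration milestones, smoothly guiding the network
# from diffuse to peaked heatmaps.

#' Render Gaussian heatmap targets
#'
#' @param landmarks a [new_landmark_set()] in 0-based voxel units of the
#'   chunk (landmarks outside the chunk simply yield a near-zero tail).
#' @param shape integer 3-vector, the chunk shape.
#' @param alpha amplitude (> 0).
#' @param beta spread (Gaussian sd) in voxels (> 0).
#' @return A 4D array of dim `c(3, shape)`, channels ordered
#'   helicotrema, oval_window, round_window.
#' @export
render_heatmaps <- function(landmarks, shape, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  shape <- rep_len(as.integer(shape), 3L)
  ax <- lapply(shape, function(n) seq_len(n) - 1)
  out <- array(0, c(3L, shape))
  for (k in seq_along(LANDMARK_NAMES)) {
    c_k <- landmarks[[LANDMARK_NAMES[k]]]
    dx2 <- (ax[[1]] - c_k[1])^2
    dy2 <- (ax[[2]] - c_k[2])^2
    dz2 <- (ax[[3]] - c_k[3])^2
    r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    out[k, , , ] <- alpha * exp(-r2 / (2 * beta^2))
  }
  out
}

#' Heatmap parameter schedule
#'
#' A piecewise-constant, right-continuous map from training iteration to
#' `(alpha, beta)`. A milestone at iteration 0 is mandatory; alpha must be
#' non-decreasing and beta non-increasing across milestones (targets only
#' ever sharpen).
#'
#' @param milestones strictly increasing iteration numbers, first = 0.
#' @param alpha,beta per-milestone amplitudes and spreads.
#' @param name schedule label.
#' @return A `heatmap_schedule` object.
#' @export
heatmap_schedule <- function(milestones = c(0, 15000, 37500),
                             alpha = c(1, 5, 10), beta = c(6, 4, 2),
                             name = "gamma") {
  if (length(milestones) != length(alpha) || length(alpha) != length(beta))
    stop("milestones, alpha and beta must have equal length")
  if (milestones[1] != 0) stop("a milestone at iteration 0 is mandatory")
  if (is.unsorted(milestones, strictly = TRUE))
    stop("milestones must be strictly increasing")
  if (is.unsorted(alpha)) stop("alpha must be non-decreasing across milestones")
  if (is.unsorted(rev(beta))) stop("beta must be non-increasing across milestones")
  if (any(beta <= 0)) stop("beta must be positive everywhere")
  structure(list(milestones = milestones, alpha = alpha, beta = beta,
                 name = name), class = "heatmap_schedule")
}

#' Look up schedule parameters at a training iteration
#'
#' @param schedule a [heatmap_schedule()].
#' @param iteration training iteration (>= 0).
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @export
schedule_at <- function(schedule, iteration) {
  stopifnot(inherits(schedule, "heatmap_schedule"), iteration >= 0)
  i <- findInterval(iteration, schedule$milestones)
  c(alpha = schedule$alpha[i], beta = schedule$beta[i])
}

#' Decode heatmaps to landmark coordinates
#'
#' Per channel, the landmark estimate is the 0-based index of the maximum
#' heatmap value (mode localization by argmax); ties break to the
#' lexicographically smallest `(i, j, k)` index.
#'
#' @param h a 4D heatmap stack of dim `c(3, shape)`.
#' @return A [new_landmark_set()] with integer coordinates.
#' @export
decode_heatmaps <- function(h) {
  stopifnot(length(dim(h)) == 4L, dim(h)[1] == 3L)
  if (!all(is.finite(h))) stop("heatmaps must be finite")
  shape <- dim(h)[2:4]
  coords <- lapply(1:3, function(k) {
    ch <- h[k, , , ]
    if (max(ch) == min(ch)) {
      warning("constant heatmap channel ", k, "; decoding to (0,0,0)")
      return(c(0, 0, 0))
    }
    pos <- arrayInd(which(ch == max(ch)), shape)
    pos[order(pos[, 1], pos[, 2], pos[, 3])[1], ] - 1
  })
  new_landmark_set(coords[[1]], coords[[2]], coords[[3]])
}
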