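# Stochastic training-time augmentation applied consistently to a sample's
# intensities, labels and landmark coordinates. Two named protocols are
# provided: alpha (fixed quarter-turn rotations about the first axis only,
# free rotations up to 30 degrees) and beta (quarter-turns about all three
# axes, free rotations up to 45 degrees). Intensity transforms are a
# multiplicative contrast scale and additive Gaussian or Poisson noise.

#' Augmentation protocol definition
#'
#' @param name `"alpha"`, `"beta"` or `"none"`.
#' @param p probability of applying each transform family (fixed rotation,
#'   free rotation, intensity scale, noise), each drawn independently.
#' @param intensity_scale_range multiplicative contrast range `(lo, hi)`.
#' @param gaussian_noise_sigma sd of additive Gaussian noise (on the
#'   z-normalized intensity scale).
#' @param poisson_noise if `TRUE`, noise draws choose Gaussian or Poisson
#'   with equal probability; Poisson noise shifts intensities to a positive
#'   range, samples, and shifts back (z-normalized inputs can be negative).
#' @param poisson_scale event-count scale for Poisson noise (larger =
#'   weaker noise).
#' @return An `augmentation_protocol` object. For `"none"` every
#'   probability is zero and [apply_protocol()] is the identity.
#' @export
augmentation_protocol <- function(name = c("alpha", "beta", "none"),
                                  p = 0.5,
                                  intensity_scale_range = c(0.8, 1.2),
                                  gaussian_noise_sigma = 0.1,
                                  poisson_noise = TRUE,
                                  poisson_scale = 100) {
  name <- match.arg(name)
  stopifnot(p >= 0, p <= 1, all(intensity_scale_range > 0),
            gaussian_noise_sigma >= 0)
  structure(list(
    name = name,
    fixed_rotation_axes = switch(name, alpha = 1L, beta = 1:3, none = integer(0)),
    free_rotation_amplitude = switch(name, alpha = 30, beta = 45, none = 0),
    intensity_scale_range = intensity_scale_range,
    gaussian_noise_sigma = gaussian_noise_sigma,
    poisson_noise = poisson_noise,
    poisson_scale = poisson_scale,
    p = if (name == "none") 0 else p
  ), class = "augmentation_protocol")
}

#' A training sample: chunk intensities + label chunk + landmarks
#'
#' Landmarks are in 0-based voxel units of the chunk and may lie outside it
#' (the heatmap target then has only a tail inside).
#'
#' @param intensity 3D array.
#' @param label 3D binary array, congruent with `intensity`.
#' @param landmarks a [new_landmark_set()] in chunk coordinates.
#' @return A `train_sample` list.
#' @export
train_sample <- function(intensity, label, landmarks) {
  stopifnot(identical(dim(intensity), dim(label)))
  structure(list(intensity = intensity, label = label, landmarks = landmarks),
            class = "train_sample")
}

# Quarter-turn rotation of a 3D array about `axis` by k*90 degrees as a pure
# voxel permutation. Convention: rotating about axis a maps the remaining
# ordered axis pair (b, c) by (b, c) -> (n_c - 1 - c, b) per quarter turn.
rot90_3d <- function(arr, axis, k) {
  k <- k %% 4L
  if (k == 0L) return(arr)
  perm_once <- function(a) {
    if (axis == 1L) {
      a <- aperm(a, c(1, 3, 2))[, dim(a)[3]:1, , drop = FALSE]
    } else if (axis == 2L) {
      a <- aperm(a, c(3, 2, 1))[dim(a)[3]:1, , , drop = FALSE]
    } else {
      a <- aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
    }
    a
  }
  for (i in seq_len(k)) arr <- perm_once(arr)
  arr
}

rot90_coord <- function(p, shape, axis, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    q <- p
    if (axis == 1L) {
      q[2] <- shape[3] - 1 - p[3]; q[3] <- p[2]
      shape <- shape[c(1, 3, 2)]
    } else if (axis == 2L) {
      q[1] <- shape[3] - 1 - p[3]; q[3] <- p[1]
      shape <- shape[c(3, 2, 1)]
    } else {
      q[1] <- p[2]; q[2] <- shape[1] - 1 - p[1]
      shape <- shape[c(2, 1, 3)]
    }
    p <- q
  }
  p
}

#' Fixed quarter-turn rotation of a sample
#'
#' A pure voxel permutation (no interpolation, exactly invertible) of
#' intensities and labels about one coordinate axis, with landmark
#' coordinates mapped by the same permutation.
#'
#' @param sample a [train_sample()] with a cubic chunk.
#' @param axis rotation axis (1, 2 or 3).
#' @param k number of quarter turns (1, 2 or 3).
#' @return The rotated sample.
#' @export
fixed_rotation <- function(sample, axis, k) {
  stopifnot(k %in% 1:3, axis %in% 1:3)
  shp <- dim(sample$intensity)
  inplane <- shp[-axis]
  if (inplane[1] != inplane[2])
    stop("fixed rotation requires equal in-plane axes (got ",
         paste(shp, collapse = "x"), ")")
  lm <- lapply(unclass(sample$landmarks), rot90_coord, shape = shp,
               axis = axis, k = k)
  train_sample(rot90_3d(sample$intensity, axis, k),
               rot90_3d(sample$label, axis, k),
               new_landmark_set(lm$helicotrema, lm$oval_window, lm$round_window))
}

#' Free-angle rotation of a sample about a coordinate axis
#'
#' Intensities are resampled with trilinear interpolation, labels with
#' nearest neighbour (staying integral), and landmarks are mapped by the
#' exact rotation matrix about the chunk centre. Voxels rotated in from
#' outside the chunk take `fill`.
#'
#' @param sample a [train_sample()].
#' @param axis rotation axis (1, 2 or 3).
#' @param angle rotation angle in degrees.
#' @param fill background fill value for intensities.
#' @return The rotated sample.
#' @export
free_rotation <- function(sample, axis, angle, fill = 0) {
  shp <- dim(sample$intensity)
  ctr <- (shp - 1) / 2
  deg <- c(0, 0, 0); deg[axis] <- angle
  rot <- euler_matrix(deg)
  # output voxel o samples input at R^-1 (o - c) + c
  A <- t(rot)  # inverse of a rotation
  t_off <- ctr - A %*% ctr
  intensity <- array(cpp_affine_resample(as.numeric(sample$intensity), shp,
                                         shp, A, as.numeric(t_off), 0L, fill), shp)
  label <- array(as.integer(cpp_affine_resample(as.numeric(sample$label), shp,
                                                shp, A, as.numeric(t_off), 1L, 0)), shp)
  lm <- lapply(unclass(sample$landmarks), function(p) {
    as.numeric(rot %*% (p - ctr) + ctr)
  })
  train_sample(intensity, label,
               new_landmark_set(lm$helicotrema, lm$oval_window, lm$round_window))
}

#' Intensity augmentation
#'
#' Multiplies intensities by a contrast scale and/or adds noise; labels and
#' landmarks are untouched.
#'
#' @param sample a [train_sample()].
#' @param scale multiplicative factor (1 = identity).
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param sigma Gaussian noise sd.
#' @param poisson_scale event-count scale for Poisson noise.
#' @return The transformed sample.
#' @export
intensity_augment <- function(sample, scale = 1, noise = "none",
                              sigma = 0.1, poisson_scale = 100) {
  x <- sample$intensity * scale
  if (noise == "gaussian" && sigma > 0) {
    x <- x + array(rnorm(length(x), 0, sigma), dim(x))
  } else if (noise == "poisson") {
    # shift to a positive range, sample counts, shift back
    lo <- min(x)
    shifted <- (x - lo) + 1
    x <- rpois(length(x), shifted * poisson_scale) / poisson_scale - 1 + lo
    x <- array(x, dim(sample$intensity))
  } else if (noise != "none") {
    stop("unknown noise kind '", noise, "'")
  }
  train_sample(x, sample$label, sample$landmarks)
}

#' Apply a full augmentation protocol to a sample
#'
#' Draws independent coin flips and transform parameters from R's RNG (seed
#' it for reproducibility): optionally a fixed quarter-turn rotation about a
#' protocol axis, a free rotation up to the protocol amplitude about a
#' random coordinate axis, a contrast scale, and Gaussian-or-Poisson noise.
#'
#' @param sample a [train_sample()].
#' @param protocol an [augmentation_protocol()].
#' @return The augmented sample.
#' @export
apply_protocol <- function(sample, protocol) {
  if (!inherits(protocol, "augmentation_protocol"))
    stop("unknown augmentation protocol")
  if (protocol$name == "none" || protocol$p == 0) return(sample)
  if (runif(1) < protocol$p) {
    axis <- if (length(protocol$fixed_rotation_axes) == 1L)
      protocol$fixed_rotation_axes else sample(protocol$fixed_rotation_axes, 1)
    sample <- fixed_rotation(sample, axis, sample.int(3L, 1))
  }
  if (runif(1) < protocol$p && protocol$free_rotation_amplitude > 0) {
    sample <- free_rotation(sample, sample.int(3L, 1),
                            runif(1, -protocol$free_rotation_amplitude,
                                  protocol$free_rotation_amplitude))
  }
  if (runif(1) < protocol$p) {
    sample <- intensity_augment(sample,
                                scale = runif(1, protocol$intensity_scale_range[1],
                                              protocol$intensity_scale_range[2]))
  }
  if (runif(1) < protocol$p) {
    kind <- if (protocol$poisson_noise && runif(1) < 0.5) "poisson" else "gaussian"
    sample <- intensity_augment(sample, scale = 1, noise = kind,
                                sigma = protocol$gaussian_noise_sigma,
                                poisson_scale = protocol$poisson_scale)
  }
  sample
}
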