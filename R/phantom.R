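# Synthetic cochlea-like phantoms: a conical-spiral tube (cochlear turns),
# three tori (semicircular canals) and an ellipsoid (vestibule) embedded in a
# bright bone-like background, with the three landmarks placed at the spiral
# apex (helicotrema analog) and on two membrane patches of the vestibule
# boundary (oval/round window analogs). Geometry is rasterised by stamping
# balls along parametric curves, so rigid rotations apply exactly to the
# geometry and the landmarks jointly, with no image interpolation.

#' Run code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators do not perturb the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic inner-ear phantom
#'
#' Default geometric parameters scale with the smallest volume edge `m` so
#' the same spec family works at 32^3 (test scale) and 128^3 (demo scale).
#' Intensities emulate temporal-bone CT: a high-radiodensity bone background
#' (`intensity_bg`) surrounding the darker fluid-filled labyrinth
#' (`intensity_fg`).
#'
#' @param shape integer 3-vector of voxel counts.
#' @param spacing isotropic voxel spacing in um.
#' @param turns number of spiral turns of the cochlea analog.
#' @param spiral_radius_start,spiral_radius_end spiral radius (voxels) at the
#'   base and apex; decreasing, as in the cochlear cone.
#' @param tube_radius radius of the spiral tube in voxels.
#' @param canal_radii ring radii of the three semicircular-canal tori.
#' @param canal_tube_radius tube radius of the canal tori.
#' @param vestibule_radii semi-axes of the vestibule ellipsoid.
#' @param intensity_bg,intensity_fg background (bone) and foreground (fluid)
#'   intensities in arbitrary CT units.
#' @param noise_sigma sd of additive Gaussian noise.
#' @param rotation Euler angles (degrees) about the three axes, applied to
#'   geometry and landmarks jointly about the volume centre.
#' @param domain_shift one of `"none"`, `"invert_fluid"`, `"offset_cluster"`.
#' @param seed integer seed; the phantom is fully determined by the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = 99, turns = 2.5,
                         spiral_radius_start = NULL, spiral_radius_end = NULL,
                         tube_radius = NULL, canal_radii = NULL,
                         canal_tube_radius = NULL, vestibule_radii = NULL,
                         intensity_bg = 1800, intensity_fg = 400,
                         noise_sigma = 30, rotation = c(0, 0, 0),
                         domain_shift = "none", seed = 1L) {
  shape <- rep_len(as.integer(shape), 3L)
  m <- min(shape)
  spec <- list(
    shape = shape, spacing = spacing, turns = turns,
    spiral_radius_start = spiral_radius_start %||% (0.18 * m),
    spiral_radius_end = spiral_radius_end %||% (0.055 * m),
    tube_radius = tube_radius %||% max(1.5, 0.042 * m),
    canal_radii = canal_radii %||% (c(0.115, 0.100, 0.085) * m),
    canal_tube_radius = canal_tube_radius %||% max(1.1, 0.022 * m),
    vestibule_radii = vestibule_radii %||% (c(0.085, 0.070, 0.070) * m),
    intensity_bg = intensity_bg, intensity_fg = intensity_fg,
    noise_sigma = noise_sigma, rotation = rep_len(rotation, 3L),
    domain_shift = match.arg(domain_shift,
                             c("none", "invert_fluid", "offset_cluster")),
    seed = as.integer(seed))
  if (spec$turns <= 0) stop("turns must be positive")
  if (spec$noise_sigma < 0) stop("noise_sigma must be non-negative")
  radii <- c(spec$spiral_radius_start, spec$spiral_radius_end,
             spec$tube_radius, spec$canal_radii, spec$canal_tube_radius,
             spec$vestibule_radii)
  if (any(radii <= 0)) stop("all phantom radii must be positive")
  structure(spec, class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

euler_matrix <- function(deg) {
  a <- deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Parametric geometry in unrotated frame; returns list of (points, radius)
# stamping groups plus fractional landmark positions.
phantom_geometry <- function(spec) {
  m <- min(spec$shape)
  ctr <- (spec$shape - 1) / 2
  s0 <- ctr + c(-0.10, -0.04, -0.10) * m      # spiral axis base
  hz <- 0.17 * m                              # conical rise of the spiral
  # arc length ~ 2*pi*turns*mean_radius; sample at ~0.4 voxel steps
  n_s <- max(200L, ceiling(2 * pi * spec$turns *
                             mean(c(spec$spiral_radius_start,
                                    spec$spiral_radius_end)) / 0.4))
  t <- seq(0, 1, length.out = n_s)
  r <- spec$spiral_radius_start + t * (spec$spiral_radius_end - spec$spiral_radius_start)
  th <- 2 * pi * spec$turns * t
  spiral <- cbind(s0[1] + r * cos(th), s0[2] + r * sin(th), s0[3] + t * hz)
  helicotrema <- spiral[n_s, ]

  vr <- spec$vestibule_radii
  v0 <- s0 + c(spec$spiral_radius_start + 0.6 * vr[1], 0, 0.03 * m)
  # ellipsoid surface sampled on a lat/long grid for stamping
  ph <- seq(0, pi, length.out = 24L)
  la <- seq(0, 2 * pi, length.out = 48L)
  g <- expand.grid(ph = ph, la = la)
  shell <- cbind(v0[1] + vr[1] * sin(g$ph) * cos(g$la),
                 v0[2] + vr[2] * sin(g$ph) * sin(g$la),
                 v0[3] + vr[3] * cos(g$ph))
  surface_point <- function(u) {
    u <- u / sqrt(sum(u^2))
    s <- 1 / sqrt(sum((u / vr)^2))
    v0 + u * s
  }
  oval <- surface_point(c(0.25, 0.85, 0.45))
  round_ <- surface_point(c(0.25, 0.85, -0.45))

  k0 <- v0 + c(0.85 * vr[1] + 0.01 * m, 0, 0.04 * m)
  normals <- list(c(1, 0, 0), c(0, 1, 0.2), c(0.2, 0, 1))
  canals <- lapply(seq_len(3L), function(i) {
    nrm <- normals[[i]] / sqrt(sum(normals[[i]]^2))
    u <- c(nrm[2], -nrm[1], 0); if (sum(abs(u)) < 1e-8) u <- c(1, 0, 0)
    u <- u / sqrt(sum(u^2)); w <- pracma_cross(nrm, u)
    rr <- spec$canal_radii[i]
    ang <- seq(0, 2 * pi, length.out = max(60L, ceiling(2 * pi * rr / 0.4)))
    t(sapply(ang, function(a) k0 + rr * (cos(a) * u + sin(a) * w)))
  })

  list(groups = c(list(list(pts = spiral, r = spec$tube_radius),
                       list(pts = shell, r = min(vr) * 0.55)),
                  lapply(canals, function(p) list(pts = p, r = spec$canal_tube_radius)),
                  list(list(pts = rbind(oval, round_), r = 1.5))),
       landmarks = rbind(helicotrema = helicotrema, oval_window = oval,
                         round_window = round_),
       centre = ctr)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Generate a synthetic inner-ear phantom
#'
#' Produces a two-phase intensity volume (plus Gaussian noise), its binary
#' foreground label and the three ground-truth landmarks. The rigid rotation
#' of the spec is applied to the parametric geometry before rasterisation, so
#' labels and landmarks transform exactly together.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume`, `label`, `landmarks`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  rot <- euler_matrix(spec$rotation)
  rot_pts <- function(p) sweep(sweep(p, 2, geo$centre) %*% t(rot), 2, geo$centre, "+")
  mask <- array(0L, spec$shape)
  max_r <- 0
  for (g in geo$groups) {
    pts <- rot_pts(g$pts)
    mask <- cpp_stamp_balls(mask, spec$shape, pts, g$r)
    max_r <- max(max_r, g$r)
    lo <- apply(pts, 2, min) - g$r; hi <- apply(pts, 2, max) + g$r
    if (any(lo < 2) || any(hi > spec$shape - 3))
      stop("phantom foreground violates the 2-voxel margin after rotation ",
           "(axis extent ", paste(sprintf("%.1f..%.1f", lo, hi), collapse = ", "), ")")
  }
  dim(mask) <- spec$shape
  lms <- rot_pts(geo$landmarks)
  lm <- new_landmark_set(round(lms["helicotrema", ]),
                         round(lms["oval_window", ]),
                         round(lms["round_window", ]))
  validate_landmarks(lm, spec$shape)
  vol <- with_seed(spec$seed, {
    x <- array(spec$intensity_bg, spec$shape)
    x[mask == 1L] <- spec$intensity_fg
    if (spec$noise_sigma > 0)
      x <- x + array(rnorm(length(x), 0, spec$noise_sigma), spec$shape)
    x
  })
  v <- new_volume(vol, spacing = rep(spec$spacing, 3L))
  if (spec$domain_shift != "none") v <- apply_domain_shift(v, spec$domain_shift)
  list(volume = v,
       label = new_label_volume(mask, spacing = rep(spec$spacing, 3L)),
       landmarks = lm, spec = spec)
}

#' Generate a reproducible cohort of jittered phantoms
#'
#' Each instance draws its geometric parameters from the sampler ranges and
#' gets a per-instance seed derived deterministically from the master seed.
#'
#' @param n number of phantoms.
#' @param shape voxel counts per instance.
#' @param sampler named list of `c(lo, hi)` ranges overriding the defaults
#'   for `turns`, `radius_scale` (global multiplier on all radii),
#'   `rotation` (amplitude in degrees, per axis) and `noise_sigma`.
#' @param seed master seed.
#' @param domain_shift passed through to every instance.
#' @return A list of `n` phantom instances (as from [generate_phantom()]).
#' @export
generate_cohort <- function(n, shape = c(64, 64, 64),
                            sampler = list(), seed = 1L,
                            domain_shift = "none") {
  stopifnot(n >= 1)
  rng <- modifyList(list(turns = c(2.2, 2.7), radius_scale = c(0.9, 1.1),
                         rotation = c(-15, 15), noise_sigma = c(25, 35)),
                    sampler)
  with_seed(seed, {
    draws <- lapply(seq_len(n), function(i) {
      list(turns = runif(1, rng$turns[1], rng$turns[2]),
           rs = runif(1, rng$radius_scale[1], rng$radius_scale[2]),
           rotation = runif(3, rng$rotation[1], rng$rotation[2]),
           noise = runif(1, rng$noise_sigma[1], rng$noise_sigma[2]),
           seed = sample.int(.Machine$integer.max - 1L, 1))
    })
    lapply(draws, function(d) {
      base <- phantom_spec(shape = shape)
      spec <- phantom_spec(shape = shape, turns = d$turns,
                           spiral_radius_start = base$spiral_radius_start * d$rs,
                           spiral_radius_end = base$spiral_radius_end * d$rs,
                           tube_radius = base$tube_radius * d$rs,
                           noise_sigma = d$noise, rotation = d$rotation,
                           domain_shift = domain_shift, seed = d$seed)
      generate_phantom(spec)
    })
  })
}

#' Apply a dataset-style domain shift to a volume
#'
#' Emulates the systematic contrast differences between preservation schemes
#' of ex-vivo specimens: `invert_fluid` reverses the foreground/background
#' intensity ordering (dry/embalmed specimens where the fluid space images
#' bright), `offset_cluster` adds a constant scanner-offset to all voxels.
#' Labels and landmarks are untouched by construction.
#'
#' @param v a [new_volume()].
#' @param mode `"invert_fluid"` or `"offset_cluster"`.
#' @param offset additive constant for `offset_cluster`.
#' @return The shifted volume.
#' @export
apply_domain_shift <- function(v, mode, offset = 500) {
  if (!mode %in% c("invert_fluid", "offset_cluster"))
    stop("unknown domain shift mode '", mode, "'")
  d <- v$data
  d <- switch(mode,
              invert_fluid = (max(d) + min(d)) - d,
              offset_cluster = d + offset)
  new_volume(d, spacing = v$spacing, origin = v$origin)
}
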