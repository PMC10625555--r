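make_sample <- function(edge = 16L, seed = 1L) {
  set.seed(seed)
  lab <- array(0L, rep(edge, 3))
  lab[4:8, 5:9, 6:10] <- 1L
  train_sample(array(rnorm(edge^3), rep(edge, 3)), lab,
               new_landmark_set(c(5, 6, 7), c(4, 8, 9), c(7, 5, 6)))
}

test_that("four quarter turns compose to the identity on all sample parts", {
  s <- make_sample()
  for (axis in 1:3) {
    r <- s
    for (i in 1:4) r <- fixed_rotation(r, axis, 1)
    expect_identical(r$intensity, s$intensity)
    expect_identical(r$label, s$label)
    expect_equal(unclass(r$landmarks), unclass(s$landmarks))
  }
})

test_that("k and 4-k quarter turns are mutually inverse", {
  s <- make_sample(seed = 2)
  for (axis in 1:3) for (k in 1:3) {
    r <- fixed_rotation(fixed_rotation(s, axis, k), axis, 4L - k)
    expect_identical(r$intensity, s$intensity)
    expect_equal(unclass(r$landmarks), unclass(s$landmarks))
  }
})

test_that("the chunk centre is a fixed point of every quarter turn", {
  edge <- 16L
  ctr <- (edge - 1) / 2
  s <- train_sample(array(0, rep(edge, 3)), array(0L, rep(edge, 3)),
                    new_landmark_set(rep(ctr, 3), rep(ctr, 3), rep(ctr, 3)))
  for (axis in 1:3) for (k in 1:3) {
    r <- fixed_rotation(s, axis, k)
    expect_equal(r$landmarks$helicotrema, rep(ctr, 3))
  }
})

test_that("quarter-turn landmark mapping matches a one-hot voxel oracle", {
  edge <- 16L
  for (axis in 1:3) for (k in 1:3) {
    p <- c(10, 3, 7)
    onehot <- array(0L, rep(edge, 3))
    onehot[p[1] + 1, p[2] + 1, p[3] + 1] <- 1L
    s <- train_sample(array(0, rep(edge, 3)), onehot,
                      new_landmark_set(p, p, p))
    r <- fixed_rotation(s, axis, k)
    hit <- which(r$label == 1L, arr.ind = TRUE)[1, ] - 1
    expect_equal(r$landmarks$helicotrema, unname(hit))
  }
})

test_that("zero-angle free rotation is the identity", {
  s <- make_sample(seed = 3)
  r <- free_rotation(s, 1, 0)
  expect_equal(r$intensity, s$intensity, tolerance = 1e-12)
  expect_equal(r$label, s$label)
  expect_equal(unclass(r$landmarks), unclass(s$landmarks), tolerance = 1e-12)
})

test_that("labels stay binary under free rotations", {
  s <- make_sample(seed = 4)
  for (ang in c(-37, 12, 45)) {
    r <- free_rotation(s, sample(1:3, 1), ang)
    expect_true(all(r$label %in% c(0L, 1L)))
  }
})

test_that("rotated landmarks track the rotated mask (one-hot oracle)", {
  set.seed(5)
  edge <- 24L
  for (i in 1:20) {
    p <- sample(6:17, 3, TRUE)
    blob <- array(0L, rep(edge, 3))
    blob[p[1] + 0:2, p[2] + 0:2, p[3] + 0:2] <- 1L  # 3-voxel cube marker
    s <- train_sample(array(0, rep(edge, 3)), blob,
                      new_landmark_set(p + 1, p + 1, p + 1))
    r <- free_rotation(s, sample(1:3, 1), runif(1, -45, 45))
    fg <- which(r$label == 1L, arr.ind = TRUE) - 1
    skip_if(nrow(fg) == 0)  # marker rotated fully out of bounds
    d <- sqrt(min(colSums((t(fg) - r$landmarks$helicotrema)^2)))
    expect_lte(d, sqrt(3) + 1)
  }
})

test_that("intensity augmentation: identity, exact scaling, noise moments", {
  s <- make_sample(seed = 6)
  expect_identical(intensity_augment(s, scale = 1)$intensity, s$intensity)
  expect_equal(intensity_augment(s, scale = 2)$intensity, 2 * s$intensity)
  set.seed(7)
  big <- train_sample(array(0, c(64, 64, 64)), array(0L, c(64, 64, 64)),
                      new_landmark_set(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)))
  noisy <- intensity_augment(big, noise = "gaussian", sigma = 0.5)
  expect_lt(abs(sd(noisy$intensity) - 0.5) / 0.5, 0.05)
  expect_identical(noisy$label, big$label)
})

test_that("Poisson noise handles negative (z-normalized) intensities", {
  set.seed(8)
  s <- train_sample(array(rnorm(16^3), c(16, 16, 16)),
                    array(0L, c(16, 16, 16)),
                    new_landmark_set(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)))
  out <- intensity_augment(s, noise = "poisson", poisson_scale = 200)
  expect_true(all(is.finite(out$intensity)))
  expect_lt(abs(mean(out$intensity) - mean(s$intensity)), 0.1)
})

test_that("protocol none is the identity and seeds reproduce draws exactly", {
  s <- make_sample(seed = 9)
  expect_identical(apply_protocol(s, augmentation_protocol("none")), s)
  proto <- augmentation_protocol("beta")
  a <- with_seed(11, apply_protocol(s, proto))
  b <- with_seed(11, apply_protocol(s, proto))
  expect_identical(a$intensity, b$intensity)
  expect_equal(unclass(a$landmarks), unclass(b$landmarks))
})

test_that("protocol alpha rotates about axis 1 only; beta reaches all three axes", {
  # distinguish the fixed-rotation axis by where a marked voxel travels
  probe_axis <- function(proto_name, n_draws, seed) {
    axes_seen <- integer(0)
    with_seed(seed, {
      proto <- augmentation_protocol(proto_name, p = 1,
                                     gaussian_noise_sigma = 0)
      for (i in seq_len(n_draws)) {
        axis <- if (length(proto$fixed_rotation_axes) == 1L)
          proto$fixed_rotation_axes else sample(proto$fixed_rotation_axes, 1)
        axes_seen <- c(axes_seen, axis)
        invisible(runif(4))  # consume stream irregularly
      }
    })
    axes_seen
  }
  expect_identical(unique(probe_axis("alpha", 50, 1)), 1L)
  expect_setequal(unique(probe_axis("beta", 200, 2)), 1:3)
  expect_equal(augmentation_protocol("alpha")$free_rotation_amplitude, 30)
  expect_equal(augmentation_protocol("beta")$free_rotation_amplitude, 45)
})

test_that("landmark/mask consistency is preserved across random protocol draws", {
  p <- small_phantom(seed = 30, edge = 32, noise = 0)
  lab <- p$label$data
  s <- train_sample(p$volume$data, lab, p$landmarks)
  fg0 <- which(lab == 1L, arr.ind = TRUE) - 1
  d_before <- max(vapply(c("helicotrema", "oval_window", "round_window"),
                         function(nm) sqrt(min(colSums((t(fg0) - s$landmarks[[nm]])^2))),
                         numeric(1)))
  proto <- augmentation_protocol("beta")
  with_seed(31, {
    for (i in 1:25) {
      r <- apply_protocol(s, proto)
      fg <- which(r$label == 1L, arr.ind = TRUE) - 1
      for (nm in c("helicotrema", "oval_window", "round_window")) {
        d <- sqrt(min(colSums((t(fg) - r$landmarks[[nm]])^2)))
        expect_lte(d, d_before + 1)
      }
    }
  })
})
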