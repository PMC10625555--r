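# Shared fixtures, built in code at test time. Phantoms are cached per
# session so multiple test files can reuse the same instances.

fixture_env <- new.env()

small_phantom <- function(seed = 1L, edge = 32L, noise = 30, rotation = c(0, 0, 0)) {
  key <- paste("ph", seed, edge, noise, paste(rotation, collapse = "_"), sep = "_")
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_phantom(
      phantom_spec(shape = rep(edge, 3L), seed = seed, noise_sigma = noise,
                   rotation = rotation))
  }
  fixture_env[[key]]
}

tiny_net <- function(seed = 1L, levels = 2L, channels = c(4, 8, 12), ...) {
  build_network(network_config(levels = levels, channels = channels, ...),
                seed = seed)
}

random_mask <- function(shape, p = 0.2) {
  array(as.integer(stats::runif(prod(shape)) < p), shape)
}

# independent sort-free brute-force directed distances for Hausdorff oracle
oracle_hausdorff <- function(a, b) {
  ca <- which(a == 1, arr.ind = TRUE) - 1
  cb <- which(b == 1, arr.ind = TRUE) - 1
  cross <- function(p, q) {
    # full pairwise distance matrix, no shortcuts
    dm <- outer(seq_len(nrow(p)), seq_len(nrow(q)), function(i, j) {
      sqrt((p[i, 1] - q[j, 1])^2 + (p[i, 2] - q[j, 2])^2 + (p[i, 3] - q[j, 3])^2)
    })
    apply(dm, 1, min)
  }
  dab <- cross(ca, cb)
  dba <- cross(cb, ca)
  c(hd = max(c(dab, dba)), avg_hd = mean(c(mean(dab), mean(dba))))
}

# central finite differences of a scalar function of an array
fd_grad <- function(fn, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}
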