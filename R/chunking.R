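# Sliding-window decomposition of volumes into overlapping cubic chunks and
# re-assembly of per-chunk predictions by unweighted voxel-mean fusion.
# Chunks of edge 128 with stride 25 are the working configuration for
# full-size scans; all functions are parameterised so desk-scale tests can
# use smaller grids.

#' Plan a sliding-window chunk grid
#'
#' Per axis the chunk origins are the arithmetic progression
#' `0, stride, 2*stride, ...`, with a final origin snapped to `dim - chunk`
#' so the last chunk abuts the boundary (duplicates removed). Volumes
#' smaller than the chunk edge are handled by symmetric zero-padding at
#' extraction time; the plan records the padding.
#'
#' @param volume_shape integer 3-vector.
#' @param chunk cubic chunk edge length in voxels (default 128).
#' @param stride isotropic stride in voxels (default 25).
#' @return A `chunk_grid`: list with `origins` (matrix, one 0-based corner
#'   per row), `chunk`, `stride`, `volume_shape`, `pad` (per-axis low/high
#'   zero padding).
#' @export
plan_chunks <- function(volume_shape, chunk = 128L, stride = 25L) {
  if (stride <= 0) stop("stride must be positive")
  volume_shape <- rep_len(as.integer(volume_shape), 3L)
  chunk <- as.integer(chunk)
  pad <- matrix(0L, 2, 3)
  padded <- volume_shape
  for (a in 1:3) {
    if (volume_shape[a] < chunk) {
      deficit <- chunk - volume_shape[a]
      pad[1, a] <- deficit %/% 2L
      pad[2, a] <- deficit - pad[1, a]
      padded[a] <- chunk
    }
  }
  axes <- lapply(1:3, function(a) {
    o <- seq.int(0L, max(0L, padded[a] - chunk), by = stride)
    unique(c(o, padded[a] - chunk))
  })
  origins <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
  dimnames(origins) <- NULL
  storage.mode(origins) <- "integer"
  # lexicographic order with axis 1 fastest (column-major convention)
  structure(list(origins = origins, chunk = chunk, stride = as.integer(stride),
                 volume_shape = volume_shape, padded_shape = padded, pad = pad),
            class = "chunk_grid")
}

pad_volume_data <- function(data, grid, fill = 0) {
  if (all(grid$pad == 0L)) return(data)
  out <- array(fill, grid$padded_shape)
  p <- grid$pad
  out[p[1, 1] + seq_len(dim(data)[1]),
      p[1, 2] + seq_len(dim(data)[2]),
      p[1, 3] + seq_len(dim(data)[3])] <- data
  out
}

crop_volume_data <- function(data, grid) {
  if (all(grid$pad == 0L)) return(data)
  p <- grid$pad
  data[p[1, 1] + seq_len(grid$volume_shape[1]),
       p[1, 2] + seq_len(grid$volume_shape[2]),
       p[1, 3] + seq_len(grid$volume_shape[3]), drop = FALSE]
}

#' Extract the chunks of a volume
#'
#' @param v a [new_volume()] or bare 3D array.
#' @param grid a [plan_chunks()] grid planned for `v`'s shape.
#' @param fill padding value for volumes smaller than the chunk edge.
#' @return A list of 3D arrays, one per grid origin, in grid order.
#' @export
extract_chunks <- function(v, grid, fill = 0) {
  data <- if (inherits(v, "volume")) v$data else v
  if (!identical(dim(data), grid$volume_shape) &&
      !identical(as.integer(dim(data)), grid$volume_shape))
    stop("volume shape does not match the chunk grid")
  data <- pad_volume_data(data, grid)
  k <- grid$chunk
  lapply(seq_len(nrow(grid$origins)), function(i) {
    o <- grid$origins[i, ]
    data[o[1] + seq_len(k), o[2] + seq_len(k), o[3] + seq_len(k), drop = FALSE]
  })
}

#' Fuse per-chunk maps back into a full-volume map
#'
#' Each output voxel is the unweighted arithmetic mean of all chunk
#' predictions covering it (every voxel is covered at least once by
#' construction of the grid). Means of probabilities stay in `[0, 1]`.
#'
#' @param predictions list of per-chunk 3D arrays, one per grid origin.
#' @param grid the [plan_chunks()] grid.
#' @return A 3D array of the original volume shape.
#' @export
aggregate_chunks <- function(predictions, grid) {
  n <- nrow(grid$origins)
  if (length(predictions) != n)
    stop("aggregation needs one prediction per chunk origin (",
         length(predictions), " given, ", n, " required)")
  k <- grid$chunk
  acc <- array(0, grid$padded_shape)
  cov <- array(0, grid$padded_shape)
  for (i in seq_len(n)) {
    p <- predictions[[i]]
    if (is.null(p)) stop("missing chunk prediction at origin (",
                         paste(grid$origins[i, ], collapse = ","), ")")
    if (!all(dim(p) == k)) stop("chunk prediction ", i, " has wrong shape")
    o <- grid$origins[i, ]
    ix <- o[1] + seq_len(k); iy <- o[2] + seq_len(k); iz <- o[3] + seq_len(k)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + p
    cov[ix, iy, iz] <- cov[ix, iy, iz] + 1
  }
  if (any(cov == 0)) stop("chunk grid does not cover every voxel")
  crop_volume_data(acc / cov, grid)
}

#' Per-voxel chunk coverage counts
#'
#' @param grid a [plan_chunks()] grid.
#' @return An integer 3D array (original volume shape) of coverage counts.
#' @export
chunk_coverage <- function(grid) {
  k <- grid$chunk
  cov <- array(0L, grid$padded_shape)
  for (i in seq_len(nrow(grid$origins))) {
    o <- grid$origins[i, ]
    ix <- o[1] + seq_len(k); iy <- o[2] + seq_len(k); iz <- o[3] + seq_len(k)
    cov[ix, iy, iz] <- cov[ix, iy, iz] + 1L
  }
  crop_volume_data(cov, grid)
}
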