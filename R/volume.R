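#' @useDynLib cochleaseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx median quantile rnorm rpois runif sd setNames
#' @importFrom utils read.csv write.csv head modifyList
NULL

LANDMARK_NAMES <- c("helicotrema", "oval_window", "round_window")

#' Volumetric scalar image
#'
#' A `volume` is a 3D scalar grid together with its physical voxel spacing
#' and origin. Spacing and origin are stored in micrometres (the native scale
#' of flat-panel CT temporal-bone imaging, where voxels are ~99 um across).
#' Coordinates throughout the package are 0-based voxel indices in array
#' order (axis 1, axis 2, axis 3); conversion to physical units happens only
#' at I/O boundaries.
#'
#' @param data numeric 3D array of intensities (arbitrary CT units).
#' @param spacing numeric vector of 3 positive voxel edge lengths in um.
#' @param origin numeric vector of 3 physical offsets in um.
#' @return An object of class `volume`.
#' @export
new_volume <- function(data, spacing = c(99, 99, 99), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (!all(is.finite(data)))
    stop("volume data must contain only finite values")
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(spacing <= 0)) stop("voxel spacing components must be strictly positive")
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume")
}

#' Binary label volume
#'
#' Integer per-voxel labels (0 = background, 1 = inner-ear foreground) on a
#' grid congruent with the paired intensity volume.
#'
#' @param data integer-valued 3D array with values in \{0, 1\}.
#' @inheritParams new_volume
#' @return An object of class `label_volume` (also inherits `volume`).
#' @export
new_label_volume <- function(data, spacing = c(99, 99, 99), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("label data must be a 3D array")
  if (!all(data %in% c(0, 1)))
    stop("label values must be 0 or 1")
  v <- new_volume(array(as.integer(data), dim(data)), spacing, origin)
  class(v) <- c("label_volume", "volume")
  v
}

#' Named anatomical landmark set
#'
#' Three landmarks of the inner ear: the helicotrema (apex of the cochlear
#' spiral), the oval window and the round window, each a 0-based voxel
#' coordinate vector in array axis order. Coordinates may be fractional
#' (sub-voxel positions are meaningful for Gaussian heatmap targets).
#'
#' @param helicotrema,oval_window,round_window numeric 3-vectors, 0-based
#'   voxel coordinates.
#' @return An object of class `landmark_set`: a named list of 3-vectors.
#' @export
new_landmark_set <- function(helicotrema, oval_window, round_window) {
  lm <- list(helicotrema = as.numeric(helicotrema),
             oval_window = as.numeric(oval_window),
             round_window = as.numeric(round_window))
  for (nm in LANDMARK_NAMES) {
    if (length(lm[[nm]]) != 3L || anyNA(lm[[nm]]))
      stop("landmark '", nm, "' must be a numeric 3-vector")
  }
  structure(lm, class = "landmark_set")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing (%s) um, origin (%s) um\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> (0-based voxel coordinates)\n")
  for (nm in LANDMARK_NAMES)
    cat(sprintf("  %-13s (%s)\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

#' Check that landmarks lie inside a volume's bounds
#'
#' @param lm a [new_landmark_set()] object.
#' @param shape integer 3-vector of voxel counts.
#' @return `TRUE` invisibly; errors naming the offending landmark otherwise.
#' @export
validate_landmarks <- function(lm, shape) {
  for (nm in LANDMARK_NAMES) {
    p <- lm[[nm]]
    if (any(p < 0) || any(p > shape - 1))
      stop("landmark '", nm, "' lies outside the volume bounds")
  }
  invisible(TRUE)
}

stopifnot_congruent <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grids are not congruent: shapes ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (!isTRUE(all.equal(a$spacing, b$spacing)))
    stop("grids are not congruent: spacings differ")
  invisible(TRUE)
}
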