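#' Read a volumetric image from disk
#'
#' Reads a NIfTI file (`.nii` / `.nii.gz`) into a [new_volume()]. Voxel
#' spacing is taken from the file's `pixdim` header (converted to um from the
#' declared spatial units) and the origin from the qform/sform translation.
#'
#' DICOM series directories are a common clinical interchange format for
#' flat-panel CT, but no DICOM codec is available to this package; pointing
#' `read_volume` at a directory raises an informative error. Convert DICOM
#' series to NIfTI upstream (e.g. with dcm2niix).
#'
#' @param path path to a NIfTI file.
#' @return A [new_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path))
    stop("'", path, "' is a directory; DICOM series input is not supported, ",
         "convert the series to NIfTI first")
  if (!file.exists(path)) stop("cannot read volume: no such file '", path, "'")
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("unsupported volume format for '", path, "' (expected .nii or .nii.gz)")
  img <- RNifti::readNifti(path)
  sp <- utils::head(RNifti::pixdim(img), 3L)
  un <- RNifti::pixunits(img)[1]
  mult <- switch(un, um = 1, mm = 1000, m = 1e6, Unknown = NA_real_, NA_real_)
  if (is.na(mult) || any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel-spacing metadata in '", path, "'")
  x <- RNifti::xform(img)
  origin <- as.numeric(x[1:3, 4]) * mult
  data <- as.array(img)
  attributes(data) <- list(dim = dim(data))
  new_volume(data, spacing = sp * mult, origin = origin)
}

#' Write a volume (or label volume) to NIfTI
#'
#' Spacing is written in micron units so that sub-millimetre voxel sizes
#' survive the float32 `pixdim` header exactly; intensities are stored as
#' float64 (labels as int16) so the round-trip is bit-for-bit.
#'
#' @param v a [new_volume()] or [new_label_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("unsupported volume format for '", path, "' (expected .nii or .nii.gz)")
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::pixunits(img) <- c("um", "s")
  cur <- RNifti::xform(img)
  cur[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(cur, code = 2L)
  dtype <- if (inherits(v, "label_volume")) "int16" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read landmark coordinates
#'
#' Supports three interchange formats for the helicotrema / oval-window /
#' round-window triple:
#' \describe{
#'   \item{JSON}{named arrays of 0-based voxel coordinates.}
#'   \item{CSV}{columns `name, i, j, k` with 0-based voxel coordinates.}
#'   \item{FCSV}{3DSlicer markups fiducials, physical millimetre coordinates;
#'     converted to voxel units via `(mm * 1000 - origin) / spacing`, which
#'     requires `spacing` (and optionally `origin`) of the associated grid.}
#' }
#' Landmark names are matched case-insensitively; `oval`/`round` prefixes
#' are accepted for the window landmarks.
#'
#' @param path path to a `.json`, `.csv` or `.fcsv` file.
#' @param spacing voxel spacing in um (required for FCSV).
#' @param origin physical origin in um (FCSV only; default 0).
#' @return A [new_landmark_set()] in 0-based voxel units.
#' @export
read_landmarks <- function(path, spacing = NULL, origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("cannot read landmarks: no such file '", path, "'")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = {
      lst <- jsonlite::read_json(path, simplifyVector = TRUE)
      lst[intersect(names(lst), c(LANDMARK_NAMES, "oval", "round"))]
    },
    csv = {
      df <- read.csv(path, stringsAsFactors = FALSE)
      setNames(lapply(seq_len(nrow(df)), function(i) as.numeric(df[i, 2:4])),
               df[[1]])
    },
    fcsv = {
      if (is.null(spacing))
        stop("FCSV stores physical coordinates; 'spacing' (um) is required")
      lines <- readLines(path)
      body <- lines[!startsWith(lines, "#")]
      df <- read.csv(text = body, header = FALSE, stringsAsFactors = FALSE)
      # Slicer markups columns: id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,...
      pts <- lapply(seq_len(nrow(df)), function(i) {
        mm <- as.numeric(df[i, 2:4])
        (mm * 1000 - rep_len(origin, 3L)) / rep_len(spacing, 3L)
      })
      setNames(pts, df[[12]])
    },
    stop("unsupported landmark format '.", ext, "' for '", path, "'")
  )
  canon <- function(key, alt) {
    hit <- which(tolower(names(raw)) == key | startsWith(tolower(names(raw)), alt))
    if (length(hit) == 0)
      stop("landmark file '", path, "' is missing the '", key, "' landmark")
    as.numeric(raw[[hit[1]]])
  }
  new_landmark_set(helicotrema = canon("helicotrema", "helico"),
                   oval_window = canon("oval_window", "oval"),
                   round_window = canon("round_window", "round"))
}

#' Write landmark coordinates
#'
#' @param lm a [new_landmark_set()] (0-based voxel units).
#' @param path output path; format chosen by extension (`.json`, `.csv`,
#'   `.fcsv`).
#' @param spacing,origin grid geometry in um, required for FCSV (voxel ->
#'   physical mm conversion).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path, spacing = NULL, origin = c(0, 0, 0)) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(lapply(unclass(lm), as.numeric), path, digits = NA)
  } else if (ext == "csv") {
    df <- data.frame(name = LANDMARK_NAMES,
                     t(vapply(LANDMARK_NAMES, function(n) lm[[n]], numeric(3))))
    names(df)[2:4] <- c("i", "j", "k")
    write.csv(df, path, row.names = FALSE)
  } else if (ext == "fcsv") {
    if (is.null(spacing))
      stop("FCSV stores physical coordinates; 'spacing' (um) is required")
    rows <- vapply(seq_along(LANDMARK_NAMES), function(i) {
      nm <- LANDMARK_NAMES[i]
      mm <- (lm[[nm]] * rep_len(spacing, 3L) + rep_len(origin, 3L)) / 1000
      sprintf("%d,%.6f,%.6f,%.6f,0,0,0,1,1,1,0,%s,,", i, mm[1], mm[2], mm[3], nm)
    }, character(1))
    writeLines(c("# Markups fiducial file version = 4.11",
                 "# CoordinateSystem = 0",
                 "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
                 rows), path)
  } else {
    stop("unsupported landmark format '.", ext, "'")
  }
  invisible(path)
}

#' Resample a volume to an isotropic grid
#'
#' The convolutional architecture is unaware of anisotropic pattern scale, so
#' every input is brought to a common isotropic working spacing (99 um by
#' default elsewhere in the pipeline) before any processing. Output shape is
#' `round(shape * spacing / target)` per axis; intensities are interpolated
#' trilinearly, label volumes with nearest neighbour (dispatch on class), so
#' labels stay integral.
#'
#' @param v a [new_volume()] or [new_label_volume()].
#' @param target isotropic target spacing in um.
#' @return A resampled object of the same class as `v`.
#' @export
resample_isotropic <- function(v, target) {
  stopifnot(target > 0)
  shp <- dim(v$data)
  out_shape <- as.integer(round(shp * v$spacing / target))
  if (any(out_shape < 1))
    stop("degenerate grid: target spacing ", target,
         " um collapses an axis to zero voxels")
  nearest <- inherits(v, "label_volume")
  A <- diag(target / v$spacing)
  out <- cpp_affine_resample(as.numeric(v$data), dim(v$data), out_shape,
                             A, c(0, 0, 0), as.integer(nearest), 0, clamp = 1L)
  if (nearest) {
    new_label_volume(array(as.integer(out), out_shape),
                     spacing = rep(target, 3L), origin = v$origin)
  } else {
    new_volume(array(out, out_shape), spacing = rep(target, 3L),
               origin = v$origin)
  }
}

#' Rescale landmark coordinates to a new isotropic spacing
#'
#' Companion to [resample_isotropic()]: voxel coordinates scale by
#' `spacing / target` per axis.
#'
#' @param lm a [new_landmark_set()].
#' @param spacing current per-axis spacing in um.
#' @param target isotropic target spacing in um.
#' @return A rescaled [new_landmark_set()].
#' @export
resample_landmarks <- function(lm, spacing, target) {
  f <- rep_len(spacing, 3L) / target
  new_landmark_set(lm$helicotrema * f, lm$oval_window * f, lm$round_window * f)
}
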