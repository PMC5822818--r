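#' 3D image volume with voxel geometry
#'
#' The unit container for all maps and masks: a 3D numeric array plus voxel
#' spacing (mm) and origin (mm, physical position of the centre of voxel
#' \code{[1,1,1]}). Orientation is restricted to axis-aligned grids.
#'
#' @param data 3D numeric array.
#' @param spacing numeric(3), voxel size in mm per axis.
#' @param origin numeric(3), physical coordinate (mm) of the first voxel
#'   centre. Default \code{c(0, 0, 0)}.
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("image_volume: `data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: `spacing` must be 3 positive numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: `origin` must be 3 finite numbers", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' 4D dynamic contrast-enhanced series
#'
#' A stack of 3D volumes acquired at known times, sharing one geometry.
#'
#' @param data 4D numeric array, dimensions \code{[x, y, z, phase]}.
#' @param times numeric vector of acquisition times (s), one per phase,
#'   all distinct. Phases may be stored in any order; consumers index by
#'   time.
#' @param spacing,origin voxel geometry, as in [image_volume()].
#' @return An object of class \code{dynamic_series}.
#' @export
dynamic_series <- function(data, times, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop("dynamic_series: `data` must be a 4D array", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) != dim(data)[4L])
    stop("dynamic_series: length(times) must equal the number of phases",
         call. = FALSE)
  if (anyDuplicated(times))
    stop("dynamic_series: `times` must be distinct", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("dynamic_series: invalid spacing", call. = FALSE)
  structure(list(data = data, times = times, spacing = spacing,
                 origin = origin),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat("<dynamic_series> ", paste(dim(x$data)[1:3], collapse = " x "),
      " voxels x ", dim(x$data)[4L], " phases (",
      signif(x$times[1L], 4), "..", signif(x$times[length(x$times)], 4),
      " s)\n", sep = "")
  invisible(x)
}

geometry_of <- function(x) {
  list(shape = if (inherits(x, "dynamic_series")) dim(x$data)[1:3] else dim(x$data),
       spacing = x$spacing, origin = x$origin)
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- geometry_of(a); gb <- geometry_of(b)
  identical(as.integer(ga$shape), as.integer(gb$shape)) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

stopifnot_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b))
    stop("geometry mismatch between ", what, call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI-1 volume as an image_volume
#'
#' Accepts only axis-aligned orientations; oblique acquisition matrices are
#' rejected because all geometry handling in this package assumes grid axes
#' parallel to physical axes.
#'
#' @param path path to a \code{.nii} or \code{.nii.gz} file.
#' @return An [image_volume()] (3D file) or a 3D+t array wrapped as
#'   [dynamic_series()] cannot be built without times; for 4D files use
#'   [read_dynamic()].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("read_volume: expected a 3D file; use read_dynamic() for 4D",
         call. = FALSE)
  geo <- .nifti_geometry(img)
  image_volume(arr, spacing = geo$spacing, origin = geo$origin)
}

#' Write an image_volume as NIfTI-1
#'
#' @param volume an [image_volume()].
#' @param path output path (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::qform(img) <- structure(.affine_from(volume$spacing, volume$origin),
                                  code = 2L)
  RNifti::sform(img) <- structure(.affine_from(volume$spacing, volume$origin),
                                  code = 2L)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI-1 dynamic series
#'
#' NIfTI stores no per-phase timestamps, so acquisition times are supplied by
#' the caller (from the run configuration). A sidecar JSON written by
#' [write_dynamic()] is used when present and `times` is missing.
#'
#' @param path path to a 4D NIfTI file.
#' @param times acquisition times (s); optional if a `.json` sidecar exists.
#' @return A [dynamic_series()].
#' @export
read_dynamic <- function(path, times = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("read_dynamic: expected a 4D file", call. = FALSE)
  if (is.null(times)) {
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (!file.exists(sidecar))
      stop("read_dynamic: no `times` given and no sidecar ", sidecar,
           call. = FALSE)
    times <- as.numeric(jsonlite::fromJSON(sidecar)$times)
  }
  geo <- .nifti_geometry(img)
  dynamic_series(arr, times = times, spacing = geo$spacing, origin = geo$origin)
}

#' Write a dynamic series as 4D NIfTI-1 plus a times sidecar
#'
#' @param series a [dynamic_series()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_dynamic <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  img <- RNifti::asNifti(series$data)
  RNifti::qform(img) <- structure(.affine_from(series$spacing, series$origin),
                                  code = 2L)
  RNifti::sform(img) <- structure(.affine_from(series$spacing, series$origin),
                                  code = 2L)
  RNifti::pixdim(img) <- c(series$spacing, 1)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(times = series$times), sidecar,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

.affine_from <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  m
}

.nifti_geometry <- function(img) {
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)), 1)))
    stop("oblique orientation not supported: grid axes must be ",
         "parallel to physical axes", call. = FALSE)
  # RNifti's canonical xform may flip to RAS; take magnitudes for spacing and
  # the translation column as origin of voxel [1,1,1] (0-indexed voxel 0).
  list(spacing = abs(diag(rot)), origin = as.numeric(xf[1:3, 4]))
}

# physical coordinates (mm) of voxel centres along one axis
.axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing
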