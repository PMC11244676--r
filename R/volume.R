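#' CT volume container
#'
#' A `ct_volume` holds a 3-D grid of attenuation values in Hounsfield units
#' together with its voxel spacing and physical origin. The axis order is
#' fixed as (slice, row, column) and all voxel coordinates used by this
#' package are 0-based in that order.
#'
#' @param data 3-D numeric array of HU values, axis order (slice, row,
#'   column). All values must be finite.
#' @param spacing numeric length-3, voxel edge length in mm per axis
#'   (slice, row, column); all components must be > 0.
#' @param origin numeric length-3, physical position (mm) of voxel
#'   (0, 0, 0).
#'
#' @return An object of class `ct_volume`: a list with elements `data`,
#'   `spacing`, `origin` and `calibrated` (logical; `TRUE` once values are on
#'   the HU scale, so a rescale can never be applied twice).
#' @seealso [read_volume()], [write_volume()]
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (slice, row, column)")
  if (any(dim(data) < 1L))
    stop("each axis of `data` must have length >= 1")
  data <- array(as.double(data), dim(data))
  if (!all(is.finite(data)))
    stop("HU values must all be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)")
  structure(
    list(data = data, spacing = spacing, origin = origin, calibrated = TRUE),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels (slice x row x col), spacing %s mm\n",
    d[1], d[2], d[3], paste(format(x$spacing, digits = 4), collapse = " x ")
  ))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%s) mm\n",
              min(x$data), max(x$data),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Read a CT volume from disk
#'
#' Reads a NIfTI-1 file or a DICOM series directory into a [ct_volume()].
#' DICOM pixel data are mapped through the stored rescale slope/intercept so
#' the returned volume is HU-calibrated; NIfTI data are assumed to already be
#' in HU.
#'
#' @param path file path (NIfTI) or directory containing one DICOM series.
#' @param format `"auto"` (default; directories are treated as DICOM series,
#'   files as NIfTI), `"nifti"`, or `"dicom"`.
#'
#' @return A [ct_volume()]. For DICOM series the slice spacing is derived
#'   from the slice positions; a missing pixel spacing, mixed orientations
#'   within the series, or a missing rescale slope/intercept are hard errors.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("path does not exist: ", path)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom" else "nifti"
  if (format == "dicom")
    return(read_dicom_series(path))

  img <- RNifti::readNifti(path)
  data <- as.array(img)
  if (length(dim(data)) != 3L)
    stop("expected a 3-D NIfTI volume, got ", length(dim(data)), " dimensions")
  spacing <- RNifti::pixdim(img)
  if (length(spacing) < 3L || any(spacing[1:3] <= 0))
    stop("NIfTI header carries no positive voxel spacing")
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else xf[1:3, 4]
  ct_volume(data, spacing = spacing[1:3], origin = origin)
}

#' Write a CT volume to a NIfTI-1 file
#'
#' The array is stored with NIfTI dimensions 1..3 equal to the package's
#' (slice, row, column) axes and the voxel spacing/origin in the header, so
#' [read_volume()] inverts [write_volume()] exactly.
#'
#' @param volume a [ct_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  m <- diag(4)
  diag(m)[1:3] <- volume$spacing
  m[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
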