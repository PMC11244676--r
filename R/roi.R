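#' Region-of-interest specification
#'
#' Describes a circular or rectangular ROI on one slice of a [ct_volume()].
#' Coordinates are 0-based voxel units in (row, column) order; the ROI must
#' lie fully inside the slice and contain at least two voxels so that a
#' standard deviation is defined.
#'
#' @param slice_index 0-based slice coordinate.
#' @param shape `"circle"` or `"rectangle"`.
#' @param center numeric length-2, (row, col) center in voxel units.
#' @param size for a circle, the radius (voxels); for a rectangle, length-2
#'   half-extents (row, col) in voxels.
#' @param label free-text label.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(slice_index, shape = c("circle", "rectangle"),
                     center, size, label = "") {
  shape <- match.arg(shape)
  slice_index <- as.integer(slice_index)
  if (length(slice_index) != 1L || is.na(slice_index) || slice_index < 0L)
    stop("`slice_index` must be a single non-negative integer (0-based)")
  center <- as.numeric(center)
  if (length(center) != 2L || any(!is.finite(center)))
    stop("`center` must be (row, col) in voxel units")
  size <- as.numeric(size)
  if (shape == "circle") {
    if (length(size) != 1L || !is.finite(size) || size <= 0)
      stop("circle `size` must be a single positive radius")
  } else {
    if (length(size) == 1L) size <- c(size, size)
    if (length(size) != 2L || any(!is.finite(size)) || any(size < 0))
      stop("rectangle `size` must be non-negative half-extents (row, col)")
  }
  structure(
    list(slice_index = slice_index, shape = shape, center = center,
         size = size, label = as.character(label)[1]),
    class = "roi_spec"
  )
}

# Logical in-slice mask for an roi_spec; errors if the ROI leaves the slice
# or selects fewer than 2 voxels.
roi_mask <- function(roi, slice_dim) {
  nr <- slice_dim[1]; nc <- slice_dim[2]
  r <- matrix(seq_len(nr) - 1, nr, nc)
  c_ <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  if (roi$shape == "circle") {
    mask <- (r - roi$center[1])^2 + (c_ - roi$center[2])^2 <= roi$size^2
    lo <- roi$center - roi$size
    hi <- roi$center + roi$size
  } else {
    mask <- abs(r - roi$center[1]) <= roi$size[1] &
      abs(c_ - roi$center[2]) <= roi$size[2]
    lo <- roi$center - roi$size
    hi <- roi$center + roi$size
  }
  if (any(lo < 0) || hi[1] > nr - 1 || hi[2] > nc - 1)
    stop("ROI extends outside the slice",
         if (nzchar(roi$label)) paste0(" (", roi$label, ")") else "")
  if (sum(mask) < 2L)
    stop("ROI contains fewer than 2 voxels",
         if (nzchar(roi$label)) paste0(" (", roi$label, ")") else "")
  mask
}

#' ROI attenuation metrics: Diff_HU and SD_ARTIFACT
#'
#' Computes the signed mean-attenuation difference between an artifact ROI
#' (placed where the metal artifact is most pronounced) and a reference ROI
#' over a comparable artifact-free structure, plus the sample standard
#' deviation inside the artifact ROI. The sign convention is artifact minus
#' reference ("metal minus normal"), so dark streaks in lung yield negative
#' `diff_hu`.
#'
#' @param volume a [ct_volume()].
#' @param artifact_roi,reference_roi [roi_spec()] objects; both must lie on
#'   in-range slices and fully inside their slice.
#' @return An object of class `roi_metrics`: list with `diff_hu` (HU,
#'   signed), `sd_artifact` (HU, sample SD, always >= 0), and the per-ROI
#'   means and voxel counts.
#' @export
compute_roi_metrics <- function(volume, artifact_roi, reference_roi) {
  stopifnot(inherits(volume, "ct_volume"),
            inherits(artifact_roi, "roi_spec"),
            inherits(reference_roi, "roi_spec"))
  d <- dim(volume$data)
  for (roi in list(artifact_roi, reference_roi))
    if (roi$slice_index > d[1] - 1L)
      stop("ROI slice_index ", roi$slice_index, " outside volume (",
           d[1], " slices)")
  sl_a <- volume$data[artifact_roi$slice_index + 1L, , ]
  sl_r <- volume$data[reference_roi$slice_index + 1L, , ]
  m_a <- roi_mask(artifact_roi, d[2:3])
  m_r <- roi_mask(reference_roi, d[2:3])
  vals_a <- sl_a[m_a]
  vals_r <- sl_r[m_r]
  structure(
    list(
      diff_hu = mean(vals_a) - mean(vals_r),
      sd_artifact = stats::sd(vals_a),
      artifact_mean = mean(vals_a), reference_mean = mean(vals_r),
      artifact_n = length(vals_a), reference_n = length(vals_r)
    ),
    class = "roi_metrics"
  )
}

#' @export
print.roi_metrics <- function(x, ...) {
  cat(sprintf("<roi_metrics> diff_hu = %.1f HU, sd_artifact = %.1f HU (n = %d / %d voxels)\n",
              x$diff_hu, x$sd_artifact, x$artifact_n, x$reference_n))
  invisible(x)
}
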