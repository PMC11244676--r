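# Bilinear interpolation of a slice at fractional (row, col) 0-based
# coordinates.
bilinear_sample <- function(slice, rows, cols) {
  nr <- nrow(slice); nc <- ncol(slice)
  r0 <- pmin(pmax(floor(rows), 0), nr - 2)
  c0 <- pmin(pmax(floor(cols), 0), nc - 2)
  fr <- rows - r0
  fc <- cols - c0
  i00 <- cbind(r0 + 1, c0 + 1)
  i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2)
  i11 <- cbind(r0 + 2, c0 + 2)
  slice[i00] * (1 - fr) * (1 - fc) + slice[i10] * fr * (1 - fc) +
    slice[i01] * (1 - fr) * fc + slice[i11] * fr * fc
}

# Shoelace signed area of a closed polygon given as (row, col) columns.
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Arc-length resampling of a closed polygon to exactly n points, starting at
# the current first vertex.
resample_closed <- function(pts, n) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(closed)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  t_out <- (seq_len(n) - 1) * total / n
  idx <- findInterval(t_out, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(closed) - 1L)
  frac <- (t_out - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  closed[idx, , drop = FALSE] +
    (closed[idx + 1L, , drop = FALSE] - closed[idx, , drop = FALSE]) * frac
}

#' Extract a closed contour surrounding the metal in one slice
#'
#' Thresholds the slice at `metal_threshold`, keeps the largest in-slice
#' region, dilates it by `offset_voxels` (disc structuring element) so the
#' trace runs outside partial-volume metal voxels but inside the streak
#' field, and extracts the sub-voxel iso-level-0.5 boundary of that mask by
#' marching squares. The boundary is oriented counter-clockwise, rotated to
#' start at its vertex of minimal row (then minimal column), and resampled by
#' arc length to exactly `n_points` positions, where HU values are read by
#' bilinear interpolation.
#'
#' @param volume a [ct_volume()].
#' @param slice_index 0-based slice coordinate.
#' @param metal_threshold HU threshold defining metal (by default the same
#'   800 HU lower band bound used by [compute_bloom_vol()], so one metal
#'   definition serves both metrics).
#' @param offset_voxels non-negative integer dilation radius between the
#'   metal boundary and the trace.
#' @param n_points number of arc-length-equidistant samples. The default 141
#'   puts the second Fourier bin at frequency 2/141 ~ 0.0142 cycles/sample.
#' @return An object of class `contour_trace`: `points` (n x 2 matrix of
#'   0-based (row, col) positions, first point not repeated), `hu_samples`,
#'   and `slice_index`.
#' @export
extract_metal_contour <- function(volume, slice_index, metal_threshold = 800,
                                  offset_voxels = 3, n_points = 141) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$data)
  if (slice_index < 0 || slice_index > d[1] - 1L)
    stop("slice_index ", slice_index, " outside volume")
  if (n_points < 8L) stop("`n_points` must be at least 8")
  slice <- volume$data[slice_index + 1L, , ]

  metal <- slice >= metal_threshold
  if (!any(metal))
    stop("no metal in slice ", slice_index,
         " (no voxel >= ", metal_threshold, " HU)")

  # Largest in-slice region: reuse the 3-D labeller on a single-slice array,
  # which restricted to one slice is 8-connected labelling.
  lab <- label_components(array(metal, c(1L, d[2], d[3])))
  mask <- largest_component(lab)[1, , ]

  offset_voxels <- as.integer(offset_voxels)
  if (offset_voxels < 0L) stop("`offset_voxels` must be non-negative")
  if (offset_voxels > 0L) {
    brush <- EBImage::makeBrush(2L * offset_voxels + 1L, shape = "disc")
    mask <- EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
    mask <- matrix(as.logical(mask), d[2], d[3])
  }
  if (any(mask[1, ]) || any(mask[d[2], ]) || any(mask[, 1]) || any(mask[, d[3]]))
    stop("contour touches the image border in slice ", slice_index)

  rings <- grDevices::contourLines(
    x = seq_len(d[2]) - 1, y = seq_len(d[3]) - 1,
    z = mask + 0, levels = 0.5
  )
  if (length(rings) == 0L)
    stop("contour extraction failed in slice ", slice_index)
  pts_list <- lapply(rings, function(r) cbind(r$x, r$y))
  areas <- vapply(pts_list, function(p) abs(polygon_area(p)), numeric(1))
  pts <- pts_list[[which.max(areas)]]
  # contourLines closes loops by repeating the first point; drop it.
  if (isTRUE(all.equal(pts[1, ], pts[nrow(pts), ]))) pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 4L)
    stop("degenerate contour in slice ", slice_index)

  if (polygon_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  start <- order(pts[, 1], pts[, 2])[1]
  if (start > 1L) pts <- pts[c(start:nrow(pts), 1:(start - 1L)), , drop = FALSE]

  pts <- resample_closed(pts, n_points)
  hu <- bilinear_sample(slice, pts[, 1], pts[, 2])
  structure(
    list(points = pts, hu_samples = hu, slice_index = as.integer(slice_index)),
    class = "contour_trace"
  )
}

#' @export
print.contour_trace <- function(x, ...) {
  cat(sprintf("<contour_trace> %d points on slice %d, HU range [%.1f, %.1f]\n",
              nrow(x$points), x$slice_index,
              min(x$hu_samples), max(x$hu_samples)))
  invisible(x)
}
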