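# Minimal DICOM series reader: uncompressed explicit-VR little-endian only,
# which is what CT scanners export for axial reconstructions. Sequences,
# compressed transfer syntaxes and multi-frame objects are rejected.

DICOM_TAGS <- c(
  rows              = "0028,0010",
  cols              = "0028,0011",
  bits_allocated    = "0028,0100",
  pixel_rep         = "0028,0103",
  pixel_spacing     = "0028,0030",
  slice_thickness   = "0018,0050",
  image_position    = "0020,0032",
  image_orientation = "0020,0037",
  frame_of_ref      = "0020,0052",
  rescale_intercept = "0028,1052",
  rescale_slope     = "0028,1053",
  transfer_syntax   = "0002,0010",
  pixel_data        = "7fe0,0010"
)

uint16_le <- function(raw2) as.integer(raw2[1]) + 256L * as.integer(raw2[2])
uint32_le <- function(raw4) sum(as.numeric(raw4) * 256^(0:3))

# Walk top-level data elements of one file; returns named list of raw values
# (by "gggg,eeee" key) for the tags of interest.
parse_dicom_elements <- function(raw, file) {
  n <- length(raw)
  if (n < 132L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", file)
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "OD", "SQ", "UT", "UN")
  out <- list()
  wanted <- unname(DICOM_TAGS)
  while (pos + 7L <= n) {
    group <- uint16_le(raw[pos:(pos + 1L)])
    elem <- uint16_le(raw[(pos + 2L):(pos + 3L)])
    tag <- sprintf("%04x,%04x", group, elem)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- uint32_le(raw[(pos + 8L):(pos + 11L)])
      hdr <- 12L
    } else {
      len <- uint16_le(raw[(pos + 6L):(pos + 7L)])
      hdr <- 8L
    }
    if (vr == "SQ" || len == 4294967295)
      stop("DICOM sequences / undefined lengths are unsupported: ", file)
    val_start <- pos + hdr
    if (val_start + len - 1L > n)
      stop("truncated DICOM element ", tag, " in ", file)
    if (tag %in% wanted)
      out[[tag]] <- list(vr = vr, bytes = raw[seq.int(val_start, length.out = len)])
    pos <- val_start + len
    if (tag == "7fe0,0010") break
  }
  out
}

dicom_value <- function(elements, key, numeric = TRUE) {
  el <- elements[[DICOM_TAGS[[key]]]]
  if (is.null(el)) return(NULL)
  if (el$vr == "US") return(uint16_le(el$bytes))
  txt <- trimws(rawToChar(el$bytes))
  if (!numeric) return(txt)
  as.numeric(strsplit(txt, "\\\\")[[1]])
}

read_dicom_slice <- function(file) {
  raw <- readBin(file, "raw", n = file.size(file))
  el <- parse_dicom_elements(raw, file)
  ts <- dicom_value(el, "transfer_syntax", numeric = FALSE)
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2.1"))
    stop("unsupported DICOM transfer syntax ", ts, " in ", file)
  nr <- dicom_value(el, "rows")
  nc <- dicom_value(el, "cols")
  if (is.null(nr) || is.null(nc))
    stop("DICOM file without Rows/Columns: ", file)
  spacing <- dicom_value(el, "pixel_spacing")
  if (is.null(spacing) || length(spacing) != 2L || any(spacing <= 0))
    stop("DICOM file without a valid PixelSpacing: ", file)
  slope <- dicom_value(el, "rescale_slope")
  intercept <- dicom_value(el, "rescale_intercept")
  if (is.null(slope) || is.null(intercept))
    stop("DICOM file without RescaleSlope/RescaleIntercept: ", file)
  bits <- dicom_value(el, "bits_allocated")
  if (is.null(bits)) bits <- 16L
  if (bits != 16L)
    stop("only 16-bit DICOM pixel data are supported: ", file)
  signed <- isTRUE(dicom_value(el, "pixel_rep") == 1L)
  px <- el[[DICOM_TAGS[["pixel_data"]]]]
  if (is.null(px))
    stop("DICOM file without PixelData: ", file)
  stored <- readBin(px$bytes, "integer", n = nr * nc, size = 2L,
                    signed = signed, endian = "little")
  # Pixel data are row-major (row by row); our in-slice layout is [row, col].
  mat <- matrix(stored, nrow = nr, ncol = nc, byrow = TRUE)
  list(
    hu = slope * mat + intercept,
    pixel_spacing = spacing,                       # (row, col) mm
    position = dicom_value(el, "image_position"),  # may be NULL
    orientation = dicom_value(el, "image_orientation"),
    slice_thickness = dicom_value(el, "slice_thickness"),
    frame_of_ref = dicom_value(el, "frame_of_ref", numeric = FALSE),
    file = file
  )
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("no files in DICOM directory: ", dir)
  slices <- lapply(sort(files), read_dicom_slice)

  ref <- slices[[1]]
  for (s in slices[-1]) {
    if (!isTRUE(all.equal(s$pixel_spacing, ref$pixel_spacing)))
      stop("mixed pixel spacing within series at ", s$file)
    if (!is.null(ref$orientation) &&
        !isTRUE(all.equal(s$orientation, ref$orientation)))
      stop("mixed image orientation within series at ", s$file)
    if (!is.null(ref$frame_of_ref) && !identical(s$frame_of_ref, ref$frame_of_ref))
      stop("mixed frame of reference within series at ", s$file)
  }

  # Order slices along the slice normal and derive the slice spacing.
  if (!is.null(ref$position) && length(slices) > 1L) {
    ori <- ref$orientation
    normal <- if (is.null(ori)) c(0, 0, 1) else
      c(ori[2] * ori[6] - ori[3] * ori[5],
        ori[3] * ori[4] - ori[1] * ori[6],
        ori[1] * ori[5] - ori[2] * ori[4])
    proj <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
    slices <- slices[order(proj)]
    gaps <- diff(sort(proj))
    if (any(gaps <= 0) || max(gaps) - min(gaps) > 0.01 * mean(gaps))
      stop("DICOM series has duplicate or unevenly spaced slice positions")
    slice_mm <- mean(gaps)
  } else {
    slice_mm <- ref$slice_thickness
    if (is.null(slice_mm) || !is.finite(slice_mm) || slice_mm <= 0)
      stop("cannot determine slice spacing: no positions or SliceThickness")
  }

  d1 <- length(slices)
  nr <- nrow(slices[[1]]$hu)
  nc <- ncol(slices[[1]]$hu)
  data <- array(0, c(d1, nr, nc))
  for (i in seq_len(d1)) data[i, , ] <- slices[[i]]$hu
  origin <- if (!is.null(slices[[1]]$position)) {
    c(slices[[1]]$position[3], slices[[1]]$position[2], slices[[1]]$position[1])
  } else c(0, 0, 0)
  ct_volume(data,
            spacing = c(slice_mm, ref$pixel_spacing[1], ref$pixel_spacing[2]),
            origin = origin)
}
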