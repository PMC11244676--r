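# Composes minimal explicit-VR little-endian DICOM files byte by byte,
# independently of the package's DICOM parser, so round-trip tests check
# the reader against the header values actually encoded.

le16 <- function(x) as.raw(c(x %% 256, x %/% 256))
le32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                             (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dicom_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1) value <- c(value, charToRaw(" "))
  }
  header <- c(le16(group), le16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(header, as.raw(c(0, 0)), le32(length(value)), value)
  } else {
    c(header, le16(length(value)), value)
  }
}

us_value <- function(x) le16(x)

# pixels: integer matrix (rows x cols) of stored values, written row-major
# as signed 16-bit little endian.
write_test_dicom <- function(file, pixels, pixel_spacing = c(0.5, 0.5),
                             position = c(0, 0, 0), slope = 1,
                             intercept = -1024,
                             orientation = c(1, 0, 0, 0, 1, 0),
                             thickness = 1,
                             frame_of_ref = "1.2.3.4.5") {
  stored <- as.integer(t(pixels))  # row-major
  px <- writeBin(stored, raw(), size = 2L, endian = "little")
  ds <- function(x) paste(format(x, trim = TRUE, scientific = FALSE),
                          collapse = "\\")
  body <- c(
    dicom_element(0x0018, 0x0050, "DS", ds(thickness)),
    dicom_element(0x0020, 0x0032, "DS", ds(position)),
    dicom_element(0x0020, 0x0037, "DS", ds(orientation)),
    dicom_element(0x0020, 0x0052, "UI", frame_of_ref),
    dicom_element(0x0028, 0x0010, "US", us_value(nrow(pixels))),
    dicom_element(0x0028, 0x0011, "US", us_value(ncol(pixels))),
    dicom_element(0x0028, 0x0030, "DS", ds(pixel_spacing)),
    dicom_element(0x0028, 0x0100, "US", us_value(16)),
    dicom_element(0x0028, 0x0103, "US", us_value(1)),
    dicom_element(0x0028, 0x1052, "DS", ds(intercept)),
    dicom_element(0x0028, 0x1053, "DS", ds(slope)),
    dicom_element(0x7fe0, 0x0010, "OW", px)
  )
  meta <- dicom_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(file)
}

# A 2-slice series of 8x8 images with known spacing and rescale.
write_test_dicom_series <- function(dir, slice_gap = 0.4,
                                    pixel_spacing = c(0.3, 0.3),
                                    slope = 1, intercept = -1024) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(99)
  for (i in 1:2) {
    px <- matrix(sample(0:2000, 64, replace = TRUE), 8, 8)
    write_test_dicom(
      file.path(dir, sprintf("slice%02d.dcm", i)), px,
      pixel_spacing = pixel_spacing,
      position = c(0, 0, (i - 1) * slice_gap),
      slope = slope, intercept = intercept
    )
  }
  dir
}
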