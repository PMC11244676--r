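test_that("NIfTI write/read round-trips data, spacing and origin exactly", {
  set.seed(11)
  vol <- ct_volume(array(rnorm(16^3, 0, 200), c(16, 16, 16)),
                   spacing = c(0.4, 0.3, 0.3), origin = c(-12.5, 3, 7.25))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  expect_gt(file.size(path), 0)
  back <- read_volume(path)
  expect_identical(back$data, vol$data)
  # header fields are float32 in NIfTI-1, hence the 1e-6 tolerance
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)

  # anisotropic spacing preserved through a second round trip
  vol2 <- ct_volume(array(0, c(3, 4, 5)), spacing = c(3, 0.25, 0.75))
  path2 <- withr::local_tempfile(fileext = ".nii")
  write_volume(vol2, path2)
  expect_equal(read_volume(path2)$spacing, c(3, 0.25, 0.75))
})

test_that("ct_volume enforces its invariants", {
  expect_error(ct_volume(matrix(0, 2, 2)), "3-D")
  expect_error(ct_volume(array(c(0, NA), c(2, 1, 1))), "finite")
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("DICOM slices are rescaled to HU via slope/intercept", {
  px <- matrix(1024L, 8, 8)
  px[3, 5] <- 2024L
  f <- withr::local_tempfile(fileext = ".dcm")
  dir <- withr::local_tempdir()
  write_test_dicom(file.path(dir, "a.dcm"), px, slope = 1,
                   intercept = -1024, position = c(0, 0, 0))
  vol <- read_volume(dir, format = "dicom")
  # stored 1024 with slope 1, intercept -1024 -> 0 HU
  expect_equal(vol$data[1, 1, 1], 0)
  expect_equal(vol$data[1, 3, 5], 1000)
})

test_that("DICOM series carries spacing from header and slice positions", {
  dir <- withr::local_tempdir()
  write_test_dicom_series(dir, slice_gap = 0.4, pixel_spacing = c(0.3, 0.3))
  vol <- read_volume(dir)
  # independent oracle: the values encoded by the byte-level writer
  expect_equal(vol$spacing, c(0.4, 0.3, 0.3))
  expect_equal(dim(vol$data), c(2L, 8L, 8L))
})

test_that("mixed-orientation DICOM series is rejected naming the file", {
  dir <- withr::local_tempdir()
  write_test_dicom(file.path(dir, "s1.dcm"), matrix(0L, 4, 4),
                   position = c(0, 0, 0))
  write_test_dicom(file.path(dir, "s2.dcm"), matrix(0L, 4, 4),
                   position = c(0, 0, 1),
                   orientation = c(0, 1, 0, 1, 0, 0))
  expect_error(read_volume(dir), "orientation.*s2\\.dcm")
})

test_that("DICOM without rescale or spacing is a hard error", {
  # write a file, then strip elements by rebuilding without them
  dir <- withr::local_tempdir()
  px <- matrix(0L, 4, 4)
  stored <- as.integer(t(px))
  pxraw <- writeBin(stored, raw(), size = 2L, endian = "little")
  meta <- dicom_element(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  no_rescale <- c(
    dicom_element(0x0028, 0x0010, "US", us_value(4)),
    dicom_element(0x0028, 0x0011, "US", us_value(4)),
    dicom_element(0x0028, 0x0030, "DS", "0.5\\0.5"),
    dicom_element(0x0028, 0x0100, "US", us_value(16)),
    dicom_element(0x7fe0, 0x0010, "OW", pxraw)
  )
  f <- file.path(dir, "norescale.dcm")
  con <- file(f, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), meta, no_rescale), con)
  close(con)
  expect_error(read_volume(dir), "Rescale")

  no_spacing <- c(
    dicom_element(0x0028, 0x0010, "US", us_value(4)),
    dicom_element(0x0028, 0x0011, "US", us_value(4)),
    dicom_element(0x0028, 0x1052, "DS", "0"),
    dicom_element(0x0028, 0x1053, "DS", "1"),
    dicom_element(0x7fe0, 0x0010, "OW", pxraw)
  )
  dir2 <- withr::local_tempdir()
  f2 <- file.path(dir2, "nospacing.dcm")
  con <- file(f2, "wb")
  writeBin(c(raw(128), charToRaw("DICM"), meta, no_spacing), con)
  close(con)
  expect_error(read_volume(dir2), "PixelSpacing")
})
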