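test_that("DICOM write/read round-trips the HU lattice, spacing and thickness", {
  set.seed(41)
  vox <- array(sample(-1024:3071, 6 * 5 * 4, replace = TRUE), c(6, 5, 4))
  vol <- ct_volume(vox, spacing = c(0.7, 0.8, 1.0), slice_thickness = 1.0,
                   metadata = list(kvp = 120, ma = 150, kernel = "STANDARD"))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- read_dicom_series(dir)
  expect_identical(back$voxels, array(as.integer(vox), dim(vox)))
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$slice_thickness, 1.0)
  expect_equal(back$metadata$kvp, 120)
  expect_equal(back$metadata$kernel, "STANDARD")

  # 2x2x2 with distinct HU per voxel: bit-exact round trip
  vol2 <- ct_volume(array(as.integer(1:8 * 11 - 500), c(2, 2, 2)), c(1, 1, 1))
  dir2 <- withr::local_tempdir()
  write_dicom_series(vol2, dir2)
  expect_identical(read_dicom_series(dir2)$voxels, vol2$voxels)

  # constant -800 volume decodes to -800 everywhere
  vol3 <- ct_volume(array(-800L, c(3, 3, 3)), c(1, 1, 1))
  dir3 <- withr::local_tempdir()
  write_dicom_series(vol3, dir3)
  expect_true(all(read_dicom_series(dir3)$voxels == -800L))
})

test_that("slice order is recovered from image position, not file names", {
  vox <- array(0L, c(4, 4, 3))
  vox[1, 1, ] <- c(10L, 20L, 30L)  # slice-identifying values
  vol <- ct_volume(vox, c(1, 1, 2.0), slice_thickness = 1.0)
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  # scramble file names so lexicographic order disagrees with position
  f <- file.path(dir, sprintf("slice_%04d.dcm", 1:3))
  tmp <- file.path(dir, "zzz.dcm")
  file.rename(f[1], tmp); file.rename(f[3], f[1]); file.rename(tmp, f[3])
  back <- read_dicom_series(dir)
  expect_identical(back$voxels[1, 1, ], c(10L, 20L, 30L))
  expect_equal(back$spacing[3], 2.0)
})

test_that("stored values map to HU through the rescale tags", {
  # stored 100 with slope 1, intercept -1024 must decode to HU -924
  path <- withr::local_tempfile(fileext = ".dcm")
  noduletex:::dcm_write_slice(path, pixels_i16 = rep(-924L, 4),
                              rows = 2L, cols = 2L, spacing_xy = c(1, 1),
                              slice_thickness = 1, position = c(0, 0, 0),
                              series_uid = "1.2.3", sop_uid = "1.2.3.1",
                              instance_number = 1)
  el <- noduletex:::dcm_read_file(path)
  stored <- readBin(el[["(7fe0,0010)"]]$value, "integer", 4, size = 2L,
                    endian = "little")
  expect_identical(stored, rep(100L, 4))
  dir <- dirname(path)
  vol <- read_dicom_series(dir)
  expect_true(all(vol$voxels == -924L))
})

test_that("reader rejects mixed series, missing rescale and uneven spacing", {
  vol <- ct_volume(array(0L, c(2, 2, 2)), c(1, 1, 1))
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir, series_uid = "1.2.3.100")
  # second series in the same directory
  file.copy(file.path(dir, "slice_0001.dcm"), file.path(dir, "x.dcm"))
  d2 <- withr::local_tempdir()
  write_dicom_series(vol, d2, series_uid = "1.2.3.200")
  file.copy(file.path(d2, "slice_0001.dcm"), file.path(dir, "other.dcm"))
  expect_error(read_dicom_series(dir), "mixed series")

  # missing rescale intercept is reported by name
  d3 <- withr::local_tempdir()
  noduletex:::dcm_write_slice(file.path(d3, "s1.dcm"), pixels_i16 = 0L,
                              rows = 1L, cols = 1L, spacing_xy = c(1, 1),
                              slice_thickness = 1, position = c(0, 0, 0),
                              series_uid = "1.2.3", sop_uid = "1.2.3.1",
                              instance_number = 1,
                              omit_tags = "(0028,1052)")
  expect_error(read_dicom_series(d3), "RescaleIntercept")

  # non-uniform inter-slice spacing beyond 0.01 mm
  d4 <- withr::local_tempdir()
  for (i in 1:3)
    noduletex:::dcm_write_slice(file.path(d4, sprintf("s%d.dcm", i)),
                                pixels_i16 = 0L, rows = 1L, cols = 1L,
                                spacing_xy = c(1, 1), slice_thickness = 1,
                                position = c(0, 0, c(0, 1, 2.5)[i]),
                                series_uid = "1.2.3",
                                sop_uid = sprintf("1.2.3.%d", i),
                                instance_number = i)
  expect_error(read_dicom_series(d4), "non-uniform")
})

test_that("writer enforces the 12-bit HU invariants", {
  bad <- ct_volume(array(4000L, c(2, 2, 2)), c(1, 1, 1))
  expect_error(write_dicom_series(bad, withr::local_tempdir()),
               "12-bit")
  frac <- ct_volume(array(0.5, c(2, 2, 2)), c(1, 1, 1))
  expect_error(write_dicom_series(frac, withr::local_tempdir()),
               "integer")
})

test_that("quantize_12bit clamps, rounds half away from zero, and is idempotent", {
  v <- ct_volume(array(c(5000, -2000, 0.5, -0.5, 1.4, 100), c(6, 1, 1)),
                 c(1, 1, 1))
  q <- quantize_12bit(v)
  expect_identical(as.vector(q$voxels), c(3071L, -1024L, 1L, -1L, 1L, 100L))
  set.seed(7)
  r <- ct_volume(array(runif(125, -3000, 6000), c(5, 5, 5)), c(1, 1, 1))
  q1 <- quantize_12bit(r); q2 <- quantize_12bit(q1)
  expect_identical(q1$voxels, q2$voxels)
  # order preserving
  o <- order(as.vector(r$voxels))
  expect_false(is.unsorted(as.vector(q1$voxels)[o]))
})

test_that("validate_protocol reports every violation of the inclusion rules", {
  ok <- ct_volume(array(0L, c(512, 512, 2)), c(0.7, 0.7, 1.0),
                  slice_thickness = 1.0)
  expect_true(validate_protocol(ok)$conformant)
  thick <- ct_volume(array(0L, c(512, 512, 2)), c(0.7, 0.7, 2.5),
                     slice_thickness = 2.5)
  rep1 <- validate_protocol(thick)
  expect_false(rep1$conformant)
  expect_identical(rep1$violations$field, "slice_thickness")
  both <- ct_volume(array(0L, c(256, 256, 2)), c(0.7, 0.7, 0.89),
                    slice_thickness = 0.89)
  rep2 <- validate_protocol(both)
  expect_equal(nrow(rep2$violations), 2L)
  expect_setequal(rep2$violations$field, c("slice_thickness", "matrix_size"))
  # boundary values are conformant
  edge <- ct_volume(array(0L, c(512, 512, 2)), c(0.7, 0.7, 0.90),
                    slice_thickness = 0.90)
  expect_true(validate_protocol(edge)$conformant)
})

test_that("the archive container round-trips volumes losslessly", {
  set.seed(5)
  vol <- ct_volume(array(sample(-1024:3071, 60), c(5, 4, 3)),
                   c(0.75, 0.75, 1.0), metadata = list(kvp = 120))
  p <- file.path(withr::local_tempdir(), "vol")
  write_volume_archive(vol, p)
  back <- read_volume_archive(p)
  expect_identical(back$voxels, array(as.integer(vol$voxels), dim(vol$voxels)))
  expect_equal(back$spacing, vol$spacing)
  expect_equal(back$metadata$kvp, 120)
})

test_that("written DICOM is readable by an independent implementation", {
  # pydicom as external conformance oracle on a tiny fixture
  vol <- ct_volume(array(as.integer(seq(-100, 99)), c(10, 10, 2)),
                   c(0.6, 0.8, 1.0), slice_thickness = 1.0)
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  script <- paste(
    "import pydicom, sys",
    sprintf("d = pydicom.dcmread(r'%s')", file.path(dir, "slice_0001.dcm")),
    "hu = d.pixel_array * float(d.RescaleSlope) + float(d.RescaleIntercept)",
    "print(int(hu[0, 0]), int(hu[9, 9]), d.Rows, d.Columns,",
    "      float(d.PixelSpacing[0]), float(d.PixelSpacing[1]),",
    "      float(d.SliceThickness))", sep = "\n")
  out <- suppressWarnings(system2("python", "-", input = script,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    fail(paste("pydicom oracle failed:", paste(out, collapse = " ")))
  got <- strsplit(tail(out, 1), " +")[[1]]
  # pixel_array[row, col]; voxels[x = col, y = row]
  expect_equal(as.numeric(got[1]), vol$voxels[1, 1, 1])
  expect_equal(as.numeric(got[2]), vol$voxels[10, 10, 1])
  expect_equal(as.numeric(got[3:4]), c(10, 10))
  expect_equal(as.numeric(got[5:6]), c(0.8, 0.6))  # row spacing = dy first
  expect_equal(as.numeric(got[7]), 1.0)
})
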