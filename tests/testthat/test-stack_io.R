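# Slice/mask stack reading, writing, normalization and geometry contracts.

write_test_png <- function(m, file) png::writePNG(m, file)

test_that("slice stacks read back in numeric filename order with normalized intensities", {
  dir <- withr::local_tempdir()
  # deliberately awkward names: numeric order differs from lexicographic
  vals <- c(s1 = 0.1, s2 = 0.5, s10 = 0.9)
  for (nm in names(vals)) {
    write_test_png(matrix(vals[[nm]], 16, 16), file.path(dir, paste0(nm, ".png")))
  }
  st <- read_slice_stack(dir)
  expect_s3_class(st, "slice_stack")
  expect_equal(n_slices(st), 3L)
  expect_equal(st$height, 16L)
  got <- vapply(0:2, function(i) get_slice(st, i)[1, 1], numeric(1))
  expect_equal(round(got, 1), c(0.1, 0.5, 0.9)) # s1, s2, s10 - numeric order
})

test_that("16-bit TIFF slices are normalized by the dtype maximum", {
  dir <- withr::local_tempdir()
  raw <- matrix(c(0, 65535, 32768, 1000), 2, 2) / 65535
  tiff::writeTIFF(raw, file.path(dir, "slice_0000.tif"), bits.per.sample = 16L)
  st <- read_slice_stack(dir)
  s <- get_slice(st, 0)
  expect_equal(min(s), 0)
  expect_equal(max(s), 1)
  expect_equal(s[1, 2], 32768 / 65535, tolerance = 1e-9)
})

test_that("geometry and format violations are rejected", {
  dir <- withr::local_tempdir()
  write_test_png(matrix(0.2, 8, 8), file.path(dir, "a_1.png"))
  write_test_png(matrix(0.2, 9, 8), file.path(dir, "a_2.png"))
  expect_error_class(read_slice_stack(dir), "paleoseg_geometry_error")

  dir2 <- withr::local_tempdir()
  png::writePNG(array(0.3, c(8, 8, 3)), file.path(dir2, "rgb_1.png"))
  expect_error_class(read_slice_stack(dir2), "paleoseg_format_error")

  expect_error_class(read_slice_stack(withr::local_tempdir()),
                     "paleoseg_missing_input_error")
})

test_that("normalize_intensities is monotone and hits the dtype extremes exactly", {
  expect_equal(normalize_intensities(matrix(c(0, 255), 1, 2), 8),
               matrix(c(0, 1), 1, 2))
  expect_equal(normalize_intensities(matrix(c(0, 65535), 1, 2), 16),
               matrix(c(0, 1), 1, 2))
  expect_equal(normalize_intensities(matrix(128, 2, 2), 8)[1, 1], 128 / 255)
  v <- sort(sample(0:255, 20))
  nv <- normalize_intensities(matrix(v, 1), 8)
  expect_true(all(diff(as.vector(nv)) >= 0))
  expect_error_class(normalize_intensities(matrix(1, 1, 1), 12),
                     "paleoseg_format_error")
  expect_error_class(normalize_intensities(matrix(300, 1, 1), 8),
                     "paleoseg_format_error")
})

test_that("mask stacks binarize, validate, and round-trip bit-exactly in both formats", {
  set.seed(31)
  masks <- list("0" = random_sparse_mask(16, 16, 0.2),
                "200" = matrix(1L, 16, 16),
                "400" = matrix(0L, 16, 16))
  ms <- mask_stack(masks)
  for (fmt in c("png", "tiff")) {
    dir <- withr::local_tempdir()
    manifest <- write_mask_stack(ms, dir, format = fmt)
    expect_equal(manifest$index, c(0L, 200L, 400L))
    # filenames encode the slice indices
    expect_true(all(grepl("00200", basename(manifest$file[2]))))
    back <- read_mask_stack(dir, expected_geometry = c(16, 16))
    expect_identical(mask_indices(back), c(0L, 200L, 400L))
    for (i in mask_indices(ms)) {
      expect_identical(get_mask(back, i), get_mask(ms, i))
    }
  }
  # all-ones mask writes as white (255 in 8-bit -> 1.0 after scaling)
  dir <- withr::local_tempdir()
  write_mask_stack(mask_stack(list("3" = matrix(1L, 4, 4))), dir, format = "png")
  raw <- png::readPNG(list.files(dir, full.names = TRUE)[1])
  expect_true(all(raw == 1))
})

test_that("non-binary masks and geometry mismatches are rejected; empty dirs are valid", {
  dir <- withr::local_tempdir()
  write_test_png(matrix(c(0, 100, 255) / 255, 3, 3), file.path(dir, "m_0.png"))
  expect_error_class(read_mask_stack(dir), "paleoseg_not_binary_error")

  dir2 <- withr::local_tempdir()
  write_test_png(matrix(1, 4, 4), file.path(dir2, "m_0.png"))
  expect_error_class(read_mask_stack(dir2, expected_geometry = c(8, 8)),
                     "paleoseg_geometry_error")

  empty <- read_mask_stack(withr::local_tempdir())
  expect_equal(n_slices(empty), 0L)
})

test_that("slice stacks round-trip through 16-bit TIFF with their sidecar metadata", {
  dir <- withr::local_tempdir()
  st <- slice_stack(lapply(1:3, function(i) matrix(i / 4, 8, 8)),
                    voxel_size_um = 10)
  write_slice_stack(st, dir)
  expect_true(file.exists(file.path(dir, "stack_meta.yaml")))
  back <- read_slice_stack(dir)
  expect_equal(back$voxel_size_um, 10)
  for (i in 0:2) {
    expect_lt(max(abs(get_slice(back, i) - get_slice(st, i))), 1.01 / 65535)
  }
})

test_that("read_slice_stack is deterministic regardless of listing order", {
  dir <- withr::local_tempdir()
  for (i in c(3, 1, 2)) {
    write_test_png(matrix(i / 10, 8, 8), file.path(dir, sprintf("z_%d.png", i)))
  }
  a <- read_slice_stack(dir)
  b <- read_slice_stack(file.path(dir, "*.png"))
  expect_identical(a$slices, b$slices)
})
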