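test_that("TIFF load is an identity on files we write, calibration argument wins", {
  td <- withr::local_tempdir()
  px <- array(sample.int(1000, 2 * 20 * 24, replace = TRUE) - 1L, c(1, 2, 20, 24))
  img <- calibrated_image(px, pixel_size_um = 0.25)
  path <- file.path(td, "two_channel.tif")
  write_image(img, path)

  back <- load_image(path)
  expect_identical(dim(back$pixels), c(1L, 2L, 20L, 24L))
  expect_equal(back$pixel_size_um, 0.25, tolerance = 1e-6)
  expect_equal(back$pixels, img$pixels)           # bit-exact for integer data

  # explicit argument overrides the file metadata
  over <- load_image(path, pixel_size_um = 0.5)
  expect_equal(over$pixel_size_um, 0.5)
})

test_that("channel limit and calibration errors are structured", {
  td <- withr::local_tempdir()
  pages <- lapply(1:6, function(i) matrix(i, 4, 4))
  path <- file.path(td, "six.tif")
  cytoring:::write_tiff(pages, path, bits = 8)
  err <- expect_error(load_image(path, pixel_size_um = 0.5),
                      class = "cytoring_channel_limit_error")
  expect_match(conditionMessage(err), "6")

  # no resolution tags, no argument -> calibration-missing
  path2 <- file.path(td, "nocal.tif")
  cytoring:::write_tiff(list(matrix(0, 4, 4)), path2, bits = 8)
  expect_error(load_image(path2), class = "cytoring_calibration_missing_error")
  expect_s3_class(load_image(path2, pixel_size_um = 1), "CalibratedImage")

  # non-TIFF input
  junk <- file.path(td, "junk.tif")
  writeLines("definitely not a TIFF", junk)
  expect_error(load_image(junk, pixel_size_um = 1),
               class = "cytoring_input_format_error")
  expect_error(load_image(file.path(td, "missing.tif"), pixel_size_um = 1),
               class = "cytoring_input_format_error")
})

test_that("z-stacks load with z preserved and project by max or mean", {
  td <- withr::local_tempdir()
  set.seed(11)
  px <- array(sample.int(500, 3 * 3 * 8 * 8, replace = TRUE), c(3, 3, 8, 8))
  img <- calibrated_image(px, 0.5)
  path <- file.path(td, "stack.tif")
  write_image(img, path)
  back <- load_image(path)
  expect_identical(dim(back$pixels)[1], 3L)       # no projection at load
  expect_equal(back$pixels, img$pixels)

  # the [1, 5, 3] stack example, per channel and pixel
  stack <- calibrated_image(array(c(1, 5, 3), c(3, 1, 1, 1)), 1)
  expect_equal(as.numeric(project_zstack(stack, "max")$pixels), 5)
  expect_equal(as.numeric(project_zstack(stack, "mean")$pixels), 3)

  pmax_img <- project_zstack(img, "max")
  pmean_img <- project_zstack(img, "mean")
  expect_true(all(pmax_img$pixels >= pmean_img$pixels))   # max dominates mean
  for (cc in 1:3) {
    expect_equal(matrix(pmax_img$pixels[1, cc, , ], 8),
                 apply(px[, cc, , ], c(2, 3), max))
    expect_equal(matrix(pmean_img$pixels[1, cc, , ], 8),
                 apply(px[, cc, , ], c(2, 3), mean))
  }

  # z = 1 input is returned unchanged by either method
  flat <- calibrated_image(matrix(1:16, 4), 1)
  expect_equal(project_zstack(flat, "max")$pixels, flat$pixels)
  expect_equal(project_zstack(flat, "mean")$pixels, flat$pixels)
  expect_error(project_zstack(flat, "median"), class = "cytoring_config_error")
})

test_that("anisotropic file calibration is rejected, not averaged", {
  # hand-build a TIFF whose X and Y resolution differ
  td <- withr::local_tempdir()
  path <- file.path(td, "aniso.tif")
  cytoring:::write_tiff(list(matrix(0, 4, 4)), path, bits = 8, pixels_per_um = 2)
  raw <- readBin(path, "raw", file.info(path)$size)
  # YResolution rational numerator lives 8 bytes after XResolution's
  xres_off <- 8L
  raw[(xres_off + 9):(xres_off + 12)] <- writeBin(3000000L, raw(), size = 4,
                                                  endian = "little")
  writeBin(raw, path)
  expect_error(load_image(path), class = "cytoring_calibration_error")
})

test_that("rasterize_roi uses boundary-inclusive pixel-center semantics", {
  img <- calibrated_image(matrix(0, 10, 10), 1)
  expect_equal(sum(rasterize_roi(roi_full(), img)), 100)  # sentinel contract

  sq <- roi_polygon(rbind(c(0, 0), c(0, 4), c(4, 4), c(4, 0)))
  mask <- rasterize_roi(sq, img)
  expect_equal(sum(mask), 25)                     # 5 x 5 centers incl. boundary
  expect_true(all(which(mask, arr.ind = TRUE) <= 5))

  # vertex-order reversal leaves the mask unchanged
  sq_rev <- roi_polygon(rbind(c(4, 0), c(4, 4), c(0, 4), c(0, 0)))
  expect_identical(rasterize_roi(sq_rev, img), mask)

  expect_error(roi_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "cytoring_roi_error")      # collinear: zero area
  expect_error(roi_polygon(rbind(c(0, 0), c(0, 1))), class = "cytoring_roi_error")
  expect_error(roi_polygon(rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0))),
               class = "cytoring_roi_error")      # self-intersecting bow-tie
})

test_that("ImageJ .roi polygon files parse to the same mask", {
  td <- withr::local_tempdir()
  path <- file.path(td, "poly.roi")
  # minimal ImageJ ROI: header (64 bytes) + x coords + y coords, big-endian
  con <- file(path, "wb")
  writeBin(charToRaw("Iout"), con)
  writeBin(as.integer(c(228)), con, size = 2, endian = "big")   # version
  writeBin(as.integer(0), con, size = 2, endian = "big")        # type: polygon
  writeBin(as.integer(c(2, 3, 9, 8)), con, size = 2, endian = "big") # top,left,bottom,right
  writeBin(as.integer(3), con, size = 2, endian = "big")        # n coordinates
  writeBin(raw(64 - 18), con)                                   # pad header
  writeBin(as.integer(c(0, 5, 0)), con, size = 2, endian = "big")  # x offsets
  writeBin(as.integer(c(0, 0, 6)), con, size = 2, endian = "big")  # y offsets
  close(con)
  roi <- read_imagej_roi(path)
  expect_equal(roi$vertices, cbind(c(2, 2, 8), c(3, 8, 3)), ignore_attr = TRUE)
})

test_that("a third-party reader (tifffile) parses our TIFF identically", {
  td <- withr::local_tempdir()
  set.seed(5)
  px <- array(sample.int(4096, 2 * 12 * 10, replace = TRUE) - 1L, c(1, 2, 12, 10))
  img <- calibrated_image(px, 0.5)
  path <- file.path(td, "oracle.tif")
  write_image(img, path)
  script <- paste(
    "import tifffile, numpy as np, sys",
    sprintf("a = tifffile.imread(%s)", deparse(path)),
    "print(a.shape, a.dtype, int(a.sum()))",
    sep = "; ")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  expect_equal(attr(out, "status"), NULL)
  expect_match(paste(out, collapse = " "),
               sprintf("\\(2, 12, 10\\) uint16 %d", sum(px)))
})
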