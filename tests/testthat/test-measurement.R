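make_two_channel <- function(ny = 16, nx = 16, cal = 0.5, fill = NULL) {
  if (is.null(fill)) {
    fill <- array(runif(2 * ny * nx, 0, 300), c(1, 2, ny, nx))
  }
  calibrated_image(fill, cal)
}

test_that("region statistics match hand arithmetic", {
  px <- array(7, c(1, 1, 8, 8))
  img <- calibrated_image(px, 0.5)
  mat <- matrix(0L, 8, 8); mat[2:3, 2:6] <- 1L    # 10-pixel label
  tbl <- measure_cells(img, label_map(mat, 0.5))
  expect_equal(tbl$area_px, 10)
  expect_equal(tbl$mean_intensity, 7)
  expect_equal(tbl$integrated_intensity, 70)
  expect_equal(tbl$min_intensity, 7)
  expect_equal(tbl$max_intensity, 7)
  expect_equal(tbl$area_um2, 10 * 0.25)

  vals <- matrix(0, 4, 4); vals[1, 1] <- 3; vals[1, 2] <- 5
  img2 <- calibrated_image(vals, 1)
  m2 <- matrix(0L, 4, 4); m2[1, 1:2] <- 1L
  t2 <- measure_cells(img2, label_map(m2, 1))
  expect_equal(t2$mean_intensity, 4)
  expect_equal(t2$integrated_intensity, 8)
  expect_equal(t2$min_intensity, 3)
  expect_equal(t2$max_intensity, 5)
  expect_true(t2$touches_border)
})

test_that("overlapping independent footprints each measure their full pixel set", {
  img <- calibrated_image(matrix(10, 16, 16), 0.5)
  mat <- matrix(0L, 16, 16); mat[8, 6] <- 1L; mat[8, 9] <- 2L
  lm <- label_map(mat, 0.5)
  fp <- expand_labels(lm, expansion_settings(1.0, "independent"))
  shared <- intersect(fp$footprints[[1]], fp$footprints[[2]])
  expect_gt(length(shared), 0)
  tbl <- measure_cells(img, fp)
  for (L in 1:2) {
    n <- length(fp$footprints[[L]])
    expect_equal(tbl$integrated_intensity[tbl$label == L], 10 * n)
  }
})

test_that("measurement agrees with brute-force accumulation on random fixtures", {
  set.seed(31)
  for (rep in 1:10) {
    img <- make_two_channel()
    lm <- random_label_map(16, 16, k = sample(1:4, 1))
    tbl <- measure_cells(img, lm)
    for (L in seq_len(lm$n_labels)) {
      idx <- which(lm$labels == L)
      for (cc in 1:2) {
        vals <- channel_matrix(img, cc)[idx]
        row <- tbl[tbl$label == L & tbl$channel == cc, ]
        expect_equal(row$mean_intensity, mean(vals))
        expect_equal(row$integrated_intensity, sum(vals))
        expect_equal(row$min_intensity, min(vals))
        expect_equal(row$max_intensity, max(vals))
        expect_equal(row$integrated_intensity, row$mean_intensity * row$area_px)
        expect_lte(row$min_intensity, row$mean_intensity)
        expect_gte(row$max_intensity, row$mean_intensity)
      }
    }
  }
})

test_that("with-enlargement dominates without-enlargement in area and IntDen", {
  set.seed(77)
  img <- make_two_channel()
  lm <- random_label_map(16, 16, k = 3)
  fp <- expand_labels(lm, expansion_settings(1.0))
  wo <- measure_cells(img, lm)
  wi <- measure_cells(img, fp)
  m <- merge(as.data.frame(wo), as.data.frame(wi), by = c("label", "channel"),
             suffixes = c("_wo", "_wi"))
  expect_true(all(m$area_px_wi >= m$area_px_wo))
  expect_true(all(m$integrated_intensity_wi >= m$integrated_intensity_wo))
})

test_that("empty regions get NaN sentinels plus a warning, never zero", {
  img <- calibrated_image(matrix(5, 8, 8), 1)
  fp <- structure(list(
    footprints = list(1:4, integer(0)), dim = c(8L, 8L),
    mode = "independent", distance_um = 1, pixel_size_um = 1, n_labels = 2L),
    class = "ExpandedFootprints")
  expect_warning(tbl <- measure_cells(img, fp),
                 class = "cytoring_empty_region_warning")
  row <- tbl[tbl$label == 2, ]
  expect_equal(row$area_px, 0)
  expect_true(is.nan(row$mean_intensity))
  expect_true(is.nan(row$integrated_intensity))
})

test_that("paired CSV writer/reader round-trips and pairs correctly", {
  td <- withr::local_tempdir()
  set.seed(13)
  img <- make_two_channel()
  lm <- random_label_map(16, 16, k = 3)
  fp <- expand_labels(lm, expansion_settings(1.0))
  wo <- measure_cells(img, lm, sample_id = "s1")
  wi <- measure_cells(img, fp, sample_id = "s1")

  paths <- write_measurement_csvs(wo, wi, td)
  expect_length(paths, 4)                         # 2 channels x 2 states
  for (p in paths) {
    expect_equal(nrow(utils::read.csv(p)), lm$n_labels)
  }

  pairs <- read_measurement_csvs(td)
  expect_length(pairs, 1)
  got <- pairs[["s1"]]
  ord <- function(df) {
    df <- as.data.frame(df)[order(df$label, df$channel), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(got$without), ord(wo), tolerance = 1e-9)
  expect_equal(ord(got$with_enl), ord(wi), tolerance = 1e-9)

  # disjoint label sets refuse to pair
  wi_bad <- wi
  wi_bad$label <- wi_bad$label + 10
  expect_error(write_measurement_csvs(wo, wi_bad, td),
               class = "cytoring_pairing_error")
})

test_that("orphan files warn and are excluded; empty directories are fine", {
  td <- withr::local_tempdir()
  expect_identical(read_measurement_csvs(td), list())

  set.seed(14)
  img <- make_two_channel()
  lm <- random_label_map(16, 16, k = 2)
  fp <- expand_labels(lm, expansion_settings(1.0))
  write_measurement_csvs(measure_cells(img, lm, sample_id = "s2"),
                         measure_cells(img, fp, sample_id = "s2"), td)
  orphan <- file.path(td, "s9_ch1_without_enlargement.csv")
  file.copy(file.path(td, "s2_ch1_without_enlargement.csv"), orphan)
  w <- expect_warning(pairs <- read_measurement_csvs(td),
                      class = "cytoring_unpaired_file_warning")
  expect_match(conditionMessage(w), "s9_ch1_without_enlargement.csv")
  expect_named(pairs, "s2")

  writeLines("label,oops\n1,2", file.path(td, "bad_ch1_without_enlargement.csv"))
  writeLines("label,oops\n1,2", file.path(td, "bad_ch1_with_enlargement.csv"))
  expect_error(suppressWarnings(read_measurement_csvs(td)),
               class = "cytoring_parse_error")
})
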