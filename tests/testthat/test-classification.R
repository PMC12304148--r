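two_marker_config <- function(tA = 40, tB = 50, mode = "independent") {
  classification_config(
    channels = list(list(channel = 2, name = "A", threshold = tA),
                    list(channel = 3, name = "B", threshold = tB)),
    expansion = list(distance_um = 1.0, mode = mode))
}

test_that("ring intensity follows the paired-measurement identity", {
  wo <- fake_measurement_table(1, 2, area_px = 10, intden = 100, mean = 10,
                               state = "without")
  wi <- fake_measurement_table(1, 2, area_px = 15, intden = 250, mean = 250 / 15,
                               state = "with")
  ci <- compute_cell_intensity(wo, wi, method = "ring")
  expect_equal(ci$new_mean, 30)                   # (250-100)/(15-10)
  expect_false(ci$degenerate)

  em <- compute_cell_intensity(wo, wi, method = "expanded_mean")
  expect_equal(em$new_mean, 250 / 15)
})

test_that("uniform images give ring mean equal to the constant", {
  img <- calibrated_image(array(42, c(1, 2, 16, 16)), 0.5)
  set.seed(3)
  lm <- random_label_map(16, 16, k = 3)
  fp <- expand_labels(lm, expansion_settings(1.0))
  ci <- compute_cell_intensity(measure_cells(img, lm), measure_cells(img, fp))
  expect_equal(ci$new_mean, rep(42, nrow(ci)))
})

test_that("ring intensity matches the per-pixel oracle on random fixtures", {
  set.seed(8)
  for (rep in 1:10) {
    img <- calibrated_image(array(runif(2 * 24 * 24, 0, 255), c(1, 2, 24, 24)), 0.5)
    lm <- random_label_map(24, 24, k = sample(2:5, 1))
    fp <- expand_labels(lm, expansion_settings(1.0))
    ci <- compute_cell_intensity(measure_cells(img, lm), measure_cells(img, fp))
    for (L in seq_len(lm$n_labels)) {
      for (cc in 1:2) {
        want <- oracle_ring_mean(channel_matrix(img, cc), lm$labels,
                                 fp$footprints[[L]], L)
        got <- ci$new_mean[ci$label == L & ci$channel == cc]
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("degenerate (clipped) cells fall back to the nucleus mean with a flag", {
  wo <- fake_measurement_table(1:2, 2, area_px = c(10, 8), intden = c(100, 80),
                               mean = c(10, 10), state = "without")
  wi <- fake_measurement_table(1:2, 2, area_px = c(15, 8), intden = c(250, 80),
                               mean = c(250 / 15, 10), state = "with")
  w <- expect_warning(ci <- compute_cell_intensity(wo, wi),
                      class = "cytoring_degenerate_cell_warning")
  expect_equal(ci$degenerate, c(FALSE, TRUE))
  expect_equal(ci$new_mean[2], 10)                # nucleus-mean fallback

  # unpaired rows are an error
  wo2 <- fake_measurement_table(1, 2, 10, 100, 10, "without")
  wi2 <- fake_measurement_table(2, 2, 15, 250, 250 / 15, "with")
  expect_error(compute_cell_intensity(wo2, wi2), class = "cytoring_pairing_error")

  # corrupted tables with a negative ring sum are data-integrity errors
  wi3 <- fake_measurement_table(1, 2, 15, 50, 50 / 15, "with")
  expect_error(compute_cell_intensity(wo2, wi3),
               class = "cytoring_data_integrity_error")
})

test_that("threshold derivation multiplies by the configured factor", {
  expect_equal(derive_threshold(250, 0.6), 150)
  expect_equal(derive_threshold(66.67, 0.6), 40, tolerance = 0.01 / 40)
  expect_equal(derive_threshold(123.4, 1.0), 123.4)
  expect_error(derive_threshold(0), class = "cytoring_domain_error")
  expect_error(derive_threshold(-5), class = "cytoring_domain_error")
})

test_that("positivity is strictly greater than the threshold", {
  cfg <- classification_config(
    channels = list(list(channel = 2, name = "C-peptide", threshold = 40)))
  ci <- data.frame(label = 1:2, channel = 2, new_mean = c(55, 40),
                   degenerate = FALSE)
  cls <- classify_cells(ci, cfg)
  expect_equal(as.vector(cls$positive[, 1]), c(TRUE, FALSE))  # tie is negative
})

test_that("nested thresholds on one channel give nested positives", {
  cfg <- classification_config(
    channels = list(list(channel = 3, name = "Glucagon", threshold = 50),
                    list(channel = 3, name = "High glucagon", threshold = 150)))
  set.seed(2)
  ci <- data.frame(label = 1:40, channel = 3,
                   new_mean = runif(40, 0, 300), degenerate = FALSE)
  cls <- classify_cells(ci, cfg)
  expect_true(all(!cls$positive[, 2] | cls$positive[, 1]))  # high => base

  # disabled entries never classify; zero enabled entries is invalid
  expect_error(classification_config(
    channels = list(list(channel = 2, name = "X", threshold = 1, enabled = FALSE))),
    class = "cytoring_config_error")
  # enabled channel missing from intensities
  cfg2 <- two_marker_config()
  ci2 <- data.frame(label = 1, channel = 2, new_mean = 10, degenerate = FALSE)
  expect_error(classify_cells(ci2, cfg2), class = "cytoring_config_error")
})

test_that("summaries count the worked 10-cell example exactly", {
  cfg <- two_marker_config()
  # 4 cells positive only for ch2(A), 3 only for ch3(B), 1 both, 2 neither
  new_mean2 <- c(rep(100, 4), rep(0, 3), 100, 0, 0)
  new_mean3 <- c(rep(0, 4), rep(100, 3), 100, 0, 0)
  ci <- rbind(data.frame(label = 1:10, channel = 2, new_mean = new_mean2,
                         degenerate = FALSE),
              data.frame(label = 1:10, channel = 3, new_mean = new_mean3,
                         degenerate = FALSE))
  s <- summarize_sample(classify_cells(ci, cfg), cfg, "worked")
  expect_equal(s$total_cells, 10)
  expect_equal(s$markers$positive, c(5, 4))
  expect_equal(s$markers$pct_positive, c(50, 40))
  expect_equal(s$markers$exclusive, c(4, 3))
  expect_equal(s$combos$combo, "A+B")
  expect_equal(s$combos$count, 1)
  expect_equal(s$negative, 2)
  expect_partition_conserved(s)

  # all-negative and single-cell-multi-positive corner cases
  ci0 <- ci; ci0$new_mean <- 0
  s0 <- summarize_sample(classify_cells(ci0, cfg), cfg)
  expect_equal(s0$markers$positive, c(0, 0))
  expect_equal(s0$negative, 10)

  ci1 <- rbind(data.frame(label = 1, channel = 2, new_mean = 99, degenerate = FALSE),
               data.frame(label = 1, channel = 3, new_mean = 99, degenerate = FALSE))
  s1 <- summarize_sample(classify_cells(ci1, cfg), cfg)
  expect_equal(s1$markers$exclusive, c(0, 0))
  expect_equal(s1$combos$count, 1)
})

test_that("partition conservation holds on randomized classifications", {
  cfg <- classification_config(
    channels = list(list(channel = 2, name = "A", threshold = 50),
                    list(channel = 3, name = "B", threshold = 50),
                    list(channel = 4, name = "C", threshold = 50)))
  set.seed(123)
  for (rep in 1:50) {
    n <- sample(1:40, 1)
    ci <- do.call(rbind, lapply(2:4, function(cc) {
      data.frame(label = seq_len(n), channel = cc,
                 new_mean = runif(n, 0, 100), degenerate = FALSE)
    }))
    s <- summarize_sample(classify_cells(ci, cfg), cfg)
    expect_partition_conserved(s)
  }
})

test_that("ring mean ignores pixels outside every expanded footprint", {
  set.seed(4)
  px <- array(runif(2 * 20 * 20, 0, 100), c(1, 2, 20, 20))
  img <- calibrated_image(px, 0.5)
  lm <- random_label_map(20, 20, k = 2)
  fp <- expand_labels(lm, expansion_settings(1.0))
  ci <- compute_cell_intensity(measure_cells(img, lm), measure_cells(img, fp))

  outside <- matrix(TRUE, 20, 20)
  for (L in seq_len(lm$n_labels)) outside[fp$footprints[[L]]] <- FALSE
  px2 <- px
  for (cc in 1:2) {
    m <- matrix(px2[1, cc, , ], 20)
    m[outside] <- m[outside] + 500
    px2[1, cc, , ] <- m
  }
  img2 <- calibrated_image(px2, 0.5)
  ci2 <- compute_cell_intensity(measure_cells(img2, lm), measure_cells(img2, fp))
  expect_equal(ci2$new_mean, ci$new_mean)
})

test_that("YAML config round-trips losslessly", {
  td <- withr::local_tempdir()
  cfg <- classification_config(
    channels = list(
      list(channel = 2, name = "C-peptide (SC-islets)", threshold = 40),
      list(channel = 3, name = "Glucagon (SC-islets)", threshold = 50),
      list(channel = 3, name = "High glucagon (SC-islets)", threshold = 150,
           enabled = FALSE)),
    intensity_method = "ring",
    expansion = list(distance_um = 1.0, mode = "independent"),
    segmentation = list(backend = "classical", smooth_sigma_um = 0.25),
    nuclear_channel = 1, note = "round-trip fixture")
  path <- file.path(td, "cfg.yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)

  # the shipped reference config parses
  ref <- read_config(system.file("extdata", "islet_thresholds.yaml",
                                 package = "cytoring"))
  expect_s3_class(ref, "ClassificationConfig")
  expect_equal(ref$channels[[1]]$threshold, 40)
})

test_that("summary CSV writes stable columns and round-trips counts", {
  td <- withr::local_tempdir()
  cfg <- two_marker_config()
  set.seed(6)
  mk_summary <- function(sid, n) {
    ci <- do.call(rbind, lapply(2:3, function(cc) {
      data.frame(label = seq_len(n), channel = cc,
                 new_mean = runif(n, 0, 120), degenerate = FALSE)
    }))
    summarize_sample(classify_cells(ci, cfg), cfg, sid)
  }
  s1 <- mk_summary("nc_1", 30); s2 <- mk_summary("mut_1", 25)
  path <- file.path(td, "summary.csv")
  write_summary_csv(list(s1, s2), path)
  df <- read_summary_csv(path)
  expect_equal(nrow(df), 2)
  expect_equal(df$total_cells, c(30, 25))
  expect_equal(df$pos_A, c(s1$markers$positive[1], s2$markers$positive[1]))
  expect_equal(df$negative, c(s1$negative, s2$negative))
  expect_equal(df$pct_B, c(s1$markers$pct_positive[2], s2$markers$pct_positive[2]),
               tolerance = 1e-9)

  # mismatched marker sets refuse a shared schema
  cfg_other <- classification_config(
    channels = list(list(channel = 2, name = "Z", threshold = 10)))
  ci <- data.frame(label = 1:3, channel = 2, new_mean = 50, degenerate = FALSE)
  s3 <- summarize_sample(classify_cells(ci, cfg_other), cfg_other, "odd")
  expect_error(write_summary_csv(list(s1, s3), path),
               class = "cytoring_column_mismatch_error")

  # zero-cell samples report NA percentages
  ci_empty <- data.frame(label = integer(0), channel = integer(0),
                         new_mean = numeric(0), degenerate = logical(0))
  s_empty <- summarize_sample(classify_cells(ci_empty, cfg), cfg, "empty")
  expect_equal(s_empty$total_cells, 0)
  expect_true(is.na(s_empty$pct_negative))
})
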