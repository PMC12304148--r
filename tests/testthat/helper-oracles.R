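# Independent brute-force oracles used by unit, property and acceptance
# tests. These deliberately take the dumbest correct path (full-grid
# distance maps, per-pixel set arithmetic) so that agreement with the
# package's bbox-scan implementations is meaningful.

# Per-label squared-distance maps: d2[[L]][y+1, x+1] is the squared
# pixel-center distance from (y, x) to the nearest pixel of label L.
oracle_distance_maps <- function(label_mat) {
  ny <- nrow(label_mat); nx <- ncol(label_mat)
  K <- max(label_mat)
  gy2 <- function(py) (seq_len(ny) - 1 - py)^2
  gx2 <- function(px) (seq_len(nx) - 1 - px)^2
  lapply(seq_len(K), function(L) {
    idx <- which(label_mat == L)
    d2 <- matrix(Inf, ny, nx)
    for (i in idx) {
      py <- (i - 1) %% ny
      px <- (i - 1) %/% ny
      d2 <- pmin(d2, outer(gy2(py), gx2(px), "+"))
    }
    d2
  })
}

# Brute-force expansion under both modes; returns per-label sorted linear
# pixel index sets (supersets of the nuclei).
oracle_expand <- function(label_mat, radius_px, mode) {
  d2 <- oracle_distance_maps(label_mat)
  K <- length(d2)
  r2 <- radius_px^2
  if (mode == "independent") {
    lapply(seq_len(K), function(L) sort(which(d2[[L]] <= r2)))
  } else {
    ny <- nrow(label_mat); nx <- ncol(label_mat)
    assign_lab <- integer(ny * nx)
    best <- matrix(Inf, ny, nx)
    for (L in seq_len(K)) {               # ascending ids: strict < ties to smaller
      take <- d2[[L]] <= r2 & d2[[L]] < best
      assign_lab[take] <- L
      best[take] <- d2[[L]][take]
    }
    own <- label_mat > 0
    assign_lab[own] <- label_mat[own]
    lapply(seq_len(K), function(L) sort(which(assign_lab == L)))
  }
}

# Random small disjoint label map: k blobs from nearest-center rasterization.
random_label_map <- function(ny = 32, nx = 32, k = 3, pixel_size_um = 0.5) {
  cy <- runif(k, 2, ny - 3); cx <- runif(k, 2, nx - 3)
  r <- runif(k, 1, 4)
  mat <- matrix(0L, ny, nx)
  best <- matrix(Inf, ny, nx)
  for (i in seq_len(k)) {
    d2 <- outer((seq_len(ny) - 1 - cy[i])^2, (seq_len(nx) - 1 - cx[i])^2, "+")
    take <- d2 <= r[i]^2 & d2 < best
    mat[take] <- i
    best[take] <- d2[take]
  }
  mat <- cytoring:::relabel_contiguous(mat)
  label_map(mat, pixel_size_um)
}

# Direct per-pixel ring mean over footprint-minus-nucleus pixels.
oracle_ring_mean <- function(chan_mat, label_mat, footprint_idx, label_id) {
  ring <- setdiff(footprint_idx, which(label_mat == label_id))
  if (length(ring) == 0) NA_real_ else mean(chan_mat[ring])
}

# Minimal MeasurementTable built from raw column values (for arithmetic
# contract tests that need no image).
fake_measurement_table <- function(label, channel, area_px, intden, mean,
                                   state, sample_id = "s", cal = 0.5) {
  df <- data.frame(label = label, channel = channel, area_px = area_px,
                   area_um2 = area_px * cal^2, mean_intensity = mean,
                   integrated_intensity = intden, min_intensity = mean,
                   max_intensity = mean, centroid_y = 0, centroid_x = 0,
                   touches_border = FALSE, pixel_size_um = cal)
  cytoring:::new_measurement_table(df, sample_id, state, cal)
}

# Two-marker noiseless simulation parameters in the ground-truth-recovery
# regime: positive shells at twice the classification threshold (200 vs
# 100), negatives at a quarter of it.
recovery_params <- function(seed, n_cells = 50, spacing = 1.0, frac = c(0.5, 0.3)) {
  simulation_params(
    n_cells = n_cells, noise_sd = 0, min_spacing_um = spacing, seed = seed,
    markers = list(
      list(name = "A", frac_positive = frac[1], pos_mean = 200, pos_sd = 0,
           neg_mean = 25, neg_sd = 0),
      list(name = "B", frac_positive = frac[2], pos_mean = 200, pos_sd = 0,
           neg_mean = 25, neg_sd = 0)))
}

recovery_config <- function(mode = "independent", threshold = 100) {
  classification_config(
    channels = list(list(channel = 2, name = "A", threshold = threshold),
                    list(channel = 3, name = "B", threshold = threshold)),
    expansion = list(distance_um = 1.0, mode = mode))
}

# Partition-conservation check on a SampleSummary (invariant 1).
expect_partition_conserved <- function(s) {
  expect_equal(sum(s$markers$exclusive) + sum(s$combos$count) + s$negative,
               s$total_cells)
  # each marker's positive count decomposes into exclusive + combos
  for (i in seq_len(nrow(s$markers))) {
    m <- s$markers$name[i]
    in_combo <- vapply(s$combos$combo, function(k) {
      m %in% strsplit(k, "+", fixed = TRUE)[[1]]
    }, logical(1))
    expect_equal(s$markers$exclusive[i] + sum(s$combos$count[in_combo]),
                 s$markers$positive[i])
  }
}
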