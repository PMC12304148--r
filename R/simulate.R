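#' Parameters for the synthetic image generator
#'
#' The generator emulates densely packed islet-like fields: elliptical
#' nuclei rendered on the nuclear channel, annular cytoplasmic shells of
#' per-cell marker intensity on each marker channel, a constant background
#' level and additive Gaussian noise clipped at zero. Defaults describe a
#' realistic confocal field of an islet section: 256 x 256 px at 0.5 um/px,
#' 50 cells with nucleus radii 2.5-4 um packed to a 1 um edge-to-edge gap,
#' 1.5 um cytoplasmic shells, marker intensities on an 8-bit-like scale
#' (positive shells around 200, negative around 25 over background 5).
#'
#' @param width,height image size in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param n_cells number of cells to place.
#' @param nucleus_radius_um length-2 range of nucleus semi-major axes (um).
#' @param axis_ratio_range length-2 range of minor/major axis ratios.
#' @param min_spacing_um minimum edge-to-edge nucleus gap (um); negative
#'   values allow near-contact or overlapping packing.
#' @param shell_thickness_um cytoplasmic shell thickness (um).
#' @param markers list of marker-channel specs, each a list with `name`,
#'   `frac_positive`, `pos_mean`, `pos_sd`, `neg_mean`, `neg_sd`.
#' @param nuclear_intensity nuclear-channel intensity inside nuclei.
#' @param background constant background level on all channels.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed; fixes the full output bit-identically.
#' @return a `SimulationParams` object.
#' @export
simulation_params <- function(width = 256L, height = 256L,
                              pixel_size_um = 0.5,
                              n_cells = 50L,
                              nucleus_radius_um = c(2.5, 4),
                              axis_ratio_range = c(0.75, 1),
                              min_spacing_um = 1.0,
                              shell_thickness_um = 1.5,
                              markers = list(
                                list(name = "markerA", frac_positive = 0.5,
                                     pos_mean = 200, pos_sd = 10,
                                     neg_mean = 25, neg_sd = 5),
                                list(name = "markerB", frac_positive = 0.3,
                                     pos_mean = 200, pos_sd = 10,
                                     neg_mean = 25, neg_sd = 5)
                              ),
                              nuclear_intensity = 200,
                              background = 5,
                              noise_sd = 2,
                              seed = 1L) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  stopifnot_scalar_pos(shell_thickness_um, "shell_thickness_um")
  if (n_cells < 1L) cyto_abort("n_cells must be >= 1", "cytoring_config_error")
  if (length(nucleus_radius_um) != 2L || any(nucleus_radius_um <= 0)) {
    cyto_abort("nucleus_radius_um must be a positive length-2 range",
               "cytoring_config_error")
  }
  if (noise_sd < 0 || background < 0) {
    cyto_abort("background and noise_sd must be non-negative", "cytoring_config_error")
  }
  for (mk in markers) {
    if (is.null(mk$name) || is.null(mk$frac_positive) ||
        mk$frac_positive < 0 || mk$frac_positive > 1) {
      cyto_abort("each marker needs a name and frac_positive in [0, 1]",
                 "cytoring_config_error")
    }
  }
  if (length(markers) > 4L) {
    cyto_abort("at most 4 marker channels (5 channels incl. nuclear)",
               "cytoring_config_error")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 nucleus_radius_um = nucleus_radius_um,
                 axis_ratio_range = axis_ratio_range,
                 min_spacing_um = min_spacing_um,
                 shell_thickness_um = shell_thickness_um,
                 markers = markers, nuclear_intensity = nuclear_intensity,
                 background = background, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

# Rasterize the nucleus LabelMap from cell geometry; pixels claimed by
# several (overlapping) ellipses go to the nearer center, ties to the
# smaller cell id, keeping labels pairwise disjoint.
render_nuclei <- function(cells, ny, nx) {
  lab <- matrix(0L, ny, nx)
  best_d2 <- matrix(Inf, ny, nx)
  for (i in seq_len(nrow(cells))) {
    a <- cells$a_px[i]; b <- cells$b_px[i]; th <- cells$theta[i]
    cy <- cells$center_y[i]; cx <- cells$center_x[i]
    r <- ceiling(a) + 1L
    ys <- max(floor(cy - r), 0):min(ceiling(cy + r), ny - 1L)
    xs <- max(floor(cx - r), 0):min(ceiling(cx + r), nx - 1L)
    gy <- rep(ys, times = length(xs)); gx <- rep(xs, each = length(ys))
    dy <- gy - cy; dx <- gx - cx
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(inside)) next
    gi <- gx[inside] * ny + gy[inside] + 1L
    d2 <- dy[inside]^2 + dx[inside]^2
    take <- lab[gi] == 0L | d2 < best_d2[gi]
    lab[gi[take]] <- i
    best_d2[gi[take]] <- d2[take]
  }
  lab
}

# Shell pixel sets: per cell, pixels whose distance to that cell's nucleus
# pixel set lies in (0, shell_px], excluding all nucleus pixels.
render_shells <- function(lab, n_cells, shell_px, ny, nx) {
  lm <- label_map(lab, 1)                 # calibration irrelevant here
  fp <- expand_labels(lm, expansion_settings(shell_px, "independent"),
                      pixel_size_um = 1)
  any_nucleus <- lab > 0L
  lapply(seq_len(n_cells), function(i) {
    s <- fp$footprints[[i]]
    s[!any_nucleus[s]]
  })
}

simulate_scene <- function(params, cells, positive) {
  ny <- params$height; nx <- params$width
  cal <- params$pixel_size_um
  n <- nrow(cells)
  n_markers <- length(params$markers)

  lab <- render_nuclei(cells, ny, nx)
  if (!all(seq_len(n) %in% lab)) {
    cyto_abort("internal: a nucleus rendered empty", "cytoring_packing_infeasible_error")
  }
  shells <- render_shells(lab, n, params$shell_thickness_um / cal, ny, nx)

  # per-cell drawn shell intensities (clipped at 0)
  intens <- matrix(0, n, n_markers)
  for (j in seq_len(n_markers)) {
    mk <- params$markers[[j]]
    mu <- ifelse(positive[, j], mk$pos_mean, mk$neg_mean)
    sd <- ifelse(positive[, j], mk$pos_sd, mk$neg_sd)
    intens[, j] <- pmax(0, stats::rnorm(n, mu, sd))
  }

  pixels <- array(0, c(1L, 1L + n_markers, ny, nx))
  nuc <- matrix(params$background, ny, nx)
  nuc[lab > 0L] <- params$nuclear_intensity
  pixels[1, 1, , ] <- nuc
  for (j in seq_len(n_markers)) {
    ch <- matrix(params$background, ny, nx)
    for (i in seq_len(n)) {
      s <- shells[[i]]
      ch[s] <- pmax(ch[s], intens[i, j])
    }
    pixels[1, j + 1L, , ] <- ch
  }
  if (params$noise_sd > 0) {
    noise <- array(stats::rnorm(length(pixels), 0, params$noise_sd), dim(pixels))
    pixels <- pmax(pixels + noise, 0)
  }
  marker_names <- vapply(params$markers, `[[`, character(1), "name")
  image <- calibrated_image(pixels, cal,
                            channel_names = c("nuclear", marker_names),
                            nuclear_channel = 1L)
  truth_sets <- apply(positive, 1, function(r) {
    paste(marker_names[r], collapse = "+")
  })
  ground_truth <- structure(list(
    cells = data.frame(cell = seq_len(n),
                       center_y = cells$center_y, center_x = cells$center_x,
                       radius_major_um = cells$a_px * cal,
                       radius_minor_um = cells$b_px * cal,
                       theta = cells$theta,
                       positive_set = truth_sets,
                       stringsAsFactors = FALSE),
    positive = positive,
    marker_names = marker_names,
    labels = label_map(lab, cal),
    shell_intensity = intens),
    class = "GroundTruth")
  list(image = image, ground_truth = ground_truth)
}

#' Simulate a calibrated multi-channel image with known ground truth
#'
#' Nucleus centers are placed by rejection sampling honoring the minimum
#' spacing (an error reports the achieved count if packing is infeasible),
#' nuclei are rendered as filled ellipses on channel 1, and each marker
#' channel carries annular cytoplasmic shells with per-cell intensities
#' drawn from the positive or negative distribution. The same seed yields
#' bit-identical output.
#'
#' @param params a `SimulationParams` object.
#' @return list with `image` (a `CalibratedImage`) and `ground_truth` (cell
#'   geometry, true positive-marker sets and the true nucleus `LabelMap`).
#' @export
simulate_image <- function(params = simulation_params()) {
  with_seed(params$seed, {
    cal <- params$pixel_size_um
    n <- params$n_cells
    shell_px <- params$shell_thickness_um / cal
    spacing_px <- params$min_spacing_um / cal

    a_px <- stats::runif(n, params$nucleus_radius_um[1], params$nucleus_radius_um[2]) / cal
    q <- stats::runif(n, params$axis_ratio_range[1], params$axis_ratio_range[2])
    b_px <- a_px * q
    theta <- stats::runif(n, 0, pi)

    cy <- numeric(n); cx <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 2000L * n
    while (placed < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      i <- placed + 1L
      margin <- a_px[i] + shell_px + 1
      ty <- stats::runif(1, margin, params$height - 1 - margin)
      tx <- stats::runif(1, margin, params$width - 1 - margin)
      ok <- TRUE
      if (placed > 0L) {
        d <- sqrt((cy[seq_len(placed)] - ty)^2 + (cx[seq_len(placed)] - tx)^2)
        ok <- all(d >= a_px[i] + a_px[seq_len(placed)] + spacing_px)
      }
      if (ok) {
        cy[i] <- ty; cx[i] <- tx
        placed <- i
      }
    }
    if (placed < n) {
      stop(structure(
        class = c("cytoring_packing_infeasible_error", "cytoring_error",
                  "error", "condition"),
        list(message = sprintf("could only place %d of %d cells under the spacing constraint",
                               placed, n),
             call = sys.call(-1), achieved = placed)))
    }
    cells <- data.frame(center_y = cy, center_x = cx, a_px = a_px,
                        b_px = b_px, theta = theta)

    positive <- matrix(FALSE, n, length(params$markers))
    for (j in seq_along(params$markers)) {
      k <- round(params$markers[[j]]$frac_positive * n)
      if (k > 0L) positive[sample.int(n, k), j] <- TRUE
    }
    simulate_scene(params, cells, positive)
  })
}

#' Construct an adjacency scenario of single-positive cell pairs
#'
#' Builds pairs of adjacent cells, one positive for marker A only and one
#' for marker B only, at a controlled edge-to-edge nucleus gap, with pairs
#' isolated from each other. When the gap is small, a 1 um independent-mode
#' expansion of the A-only cell straddles the neighbour's B shell -- the
#' mechanism that overestimates double-positive (bihormonal) counts.
#' Exclusive-mode expansion partitions the interspace at the midline and
#' mitigates it. The ground-truth positive sets are all single-marker.
#'
#' @param params a `SimulationParams` with exactly 2 markers
#'   (`frac_positive` is ignored; positivity is assigned by construction).
#' @param n_pairs number of cell pairs.
#' @param pair_gap_um edge-to-edge nucleus gap within a pair (um).
#' @return as [simulate_image()].
#' @export
adjacency_scenario <- function(params = simulation_params(),
                               n_pairs = 6L, pair_gap_um = 0.5) {
  if (length(params$markers) != 2L) {
    cyto_abort("adjacency_scenario needs exactly two markers", "cytoring_config_error")
  }
  with_seed(params$seed, {
    cal <- params$pixel_size_um
    shell_px <- params$shell_thickness_um / cal
    n <- 2L * n_pairs
    a_px <- stats::runif(n, params$nucleus_radius_um[1], params$nucleus_radius_um[2]) / cal
    b_px <- a_px                          # circular nuclei: gap is exact
    theta <- rep(0, n)

    # pair anchors on a coarse grid, far enough apart to be independent
    pitch <- 2 * (max(a_px) + shell_px) + 4 * (1 / cal) + 8
    margin <- max(a_px) * 2 + shell_px + pitch / 2
    slots_y <- floor((params$height - 2 * margin) / pitch) + 1L
    slots_x <- floor((params$width - 2 * margin) / pitch) + 1L
    if (slots_y * slots_x < n_pairs) {
      cyto_abort(sprintf("image too small for %d isolated pairs", n_pairs),
                 "cytoring_packing_infeasible_error")
    }
    slot <- sample.int(slots_y * slots_x, n_pairs)
    sy <- margin + ((slot - 1L) %% slots_y) * pitch
    sx <- margin + ((slot - 1L) %/% slots_y) * pitch

    cy <- numeric(n); cx <- numeric(n)
    for (p in seq_len(n_pairs)) {
      i <- 2L * p - 1L; j <- 2L * p
      phi <- stats::runif(1, 0, 2 * pi)
      dist_px <- a_px[i] + a_px[j] + pair_gap_um / cal
      cy[i] <- sy[p] - dist_px / 2 * sin(phi)
      cx[i] <- sx[p] - dist_px / 2 * cos(phi)
      cy[j] <- sy[p] + dist_px / 2 * sin(phi)
      cx[j] <- sx[p] + dist_px / 2 * cos(phi)
    }
    cells <- data.frame(center_y = cy, center_x = cx, a_px = a_px,
                        b_px = b_px, theta = theta)
    positive <- matrix(FALSE, n, 2L)
    positive[seq(1L, n, by = 2L), 1L] <- TRUE   # odd cells: A only
    positive[seq(2L, n, by = 2L), 2L] <- TRUE   # even cells: B only
    simulate_scene(params, cells, positive)
  })
}
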