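#' Labeled nucleus map
#'
#' Integer image on the `(y, x)` grid: 0 is background, nuclei carry labels
#' `1..K` forming a contiguous range with no gaps, each label non-empty and
#' pixel sets pairwise disjoint. Calibration is inherited from the source
#' image.
#'
#' @param labels integer matrix.
#' @param pixel_size_um positive scalar, micrometres per pixel.
#' @return an object of class `LabelMap`.
#' @export
label_map <- function(labels, pixel_size_um) {
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um", "cytoring_calibration_error")
  if (any(labels < 0L)) {
    cyto_abort("labels must be non-negative", "cytoring_labelmap_error")
  }
  present <- sort(unique(labels[labels > 0L]))
  k <- length(present)
  if (k > 0L && !identical(present, seq_len(k))) {
    cyto_abort("labels must form a contiguous range 1..K", "cytoring_labelmap_error")
  }
  structure(list(labels = labels, pixel_size_um = pixel_size_um, n_labels = k),
            class = "LabelMap")
}

#' @export
print.LabelMap <- function(x, ...) {
  cat(sprintf("LabelMap: %d label(s) on %d x %d px @ %g um/px\n",
              x$n_labels, nrow(x$labels), ncol(x$labels), x$pixel_size_um))
  invisible(x)
}

# Renumber arbitrary positive ids to 1..K in row-major (y, x) first-pixel
# order; deterministic.
relabel_contiguous <- function(mat) {
  ids <- unique(mat[mat > 0L])
  if (length(ids) == 0L) return(matrix(0L, nrow(mat), ncol(mat)))
  ny <- nrow(mat)
  idx <- which(mat > 0L)
  y <- (idx - 1L) %% ny
  x <- (idx - 1L) %/% ny
  scan_key <- y * ncol(mat) + x
  first_seen <- tapply(scan_key, mat[idx], min)
  ord <- names(sort(first_seen))
  lookup <- integer(max(as.integer(ord)))
  lookup[as.integer(ord)] <- seq_along(ord)
  out <- matrix(0L, nrow(mat), ncol(mat))
  out[idx] <- lookup[mat[idx]]
  out
}

# Separable Gaussian smoothing with replicate-edge padding.
gaussian_smooth <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  ny <- nrow(mat); nx <- ncol(mat)
  clampi <- function(i, n) pmin(pmax(i, 1L), n)
  tmp <- matrix(0, ny, nx)
  for (o in -r:r) {                       # along y
    tmp <- tmp + k[o + r + 1L] * mat[clampi(seq_len(ny) + o, ny), , drop = FALSE]
  }
  out <- matrix(0, ny, nx)
  for (o in -r:r) {                       # along x
    out <- out + k[o + r + 1L] * tmp[, clampi(seq_len(nx) + o, nx), drop = FALSE]
  }
  out
}

# Otsu threshold on 256 bins spanning [min, max] of the supplied values;
# binning is relative to the data range, so the returned threshold scales
# with any positive rescaling of the input (ratio-based method).
otsu_threshold <- function(vals) {
  vals <- vals[is.finite(vals)]
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) return(hi)
  nbins <- 256L
  bins <- pmin(floor((vals - lo) / (hi - lo) * nbins), nbins - 1L)
  counts <- tabulate(bins + 1L, nbins)
  p <- counts / sum(counts)
  centers <- lo + (seq_len(nbins) - 0.5) / nbins * (hi - lo)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  t_bin <- which.max(between)             # first max: deterministic tie-break
  lo + t_bin / nbins * (hi - lo)
}

# 8-connected components by iterative label-max propagation; deterministic.
connected_components <- function(fg) {
  ny <- nrow(fg); nx <- ncol(fg)
  lab <- matrix(0, ny, nx)
  lab[fg] <- which(fg)                    # unique seed ids
  shift <- function(m, dy, dx) {
    out <- matrix(0, ny, nx)
    ys <- seq_len(ny); xs <- seq_len(nx)
    sy <- ys - dy; sx <- xs - dx
    oky <- sy >= 1L & sy <= ny; okx <- sx >= 1L & sx <= nx
    out[ys[oky], xs[okx]] <- m[sy[oky], sx[okx]]
    out
  }
  offsets <- expand.grid(dy = -1:1, dx = -1:1)
  offsets <- offsets[!(offsets$dy == 0 & offsets$dx == 0), ]
  repeat {
    nb <- lab
    for (i in seq_len(nrow(offsets))) {
      nb <- pmax(nb, shift(lab, offsets$dy[i], offsets$dx[i]))
    }
    nb[!fg] <- 0
    if (all(nb == lab)) break
    lab <- nb
  }
  relabel_contiguous(lab)
}

# Exact Euclidean distance (px) from each pixel of a component to the
# nearest non-component pixel, computed by brute force within the padded
# bounding box. Components are nucleus-sized, so this stays cheap.
component_distance_transform <- function(comp_idx, ny, nx) {
  y <- (comp_idx - 1L) %% ny
  x <- (comp_idx - 1L) %/% ny
  y0 <- max(min(y) - 1L, 0L); y1 <- min(max(y) + 1L, ny - 1L)
  x0 <- max(min(x) - 1L, 0L); x1 <- min(max(x) + 1L, nx - 1L)
  box_y <- rep(y0:y1, times = x1 - x0 + 1L)
  box_x <- rep(x0:x1, each = y1 - y0 + 1L)
  box_idx <- box_x * ny + box_y + 1L
  is_comp <- box_idx %in% comp_idx
  bg_y <- box_y[!is_comp]; bg_x <- box_x[!is_comp]
  # image-border pixels may have no background neighbour inside the box;
  # treat outside-of-image as background at distance 1
  d <- vapply(seq_along(y), function(i) {
    d2 <- if (length(bg_y)) min((bg_y - y[i])^2 + (bg_x - x[i])^2) else Inf
    border <- min(y[i] + 1L, x[i] + 1L, ny - y[i], nx - x[i])
    min(sqrt(d2), border)
  }, numeric(1))
  list(y = y, x = x, dist = d)
}

# Split a merged component into per-seed fragments: seeds are distance
# maxima, greedily suppressed within min_sep_px (sorted by depth, then scan
# order); pixels go to the nearest seed, ties to the earlier seed.
split_component <- function(comp_idx, ny, nx, min_sep_px) {
  dt <- component_distance_transform(comp_idx, ny, nx)
  ord <- order(-dt$dist, dt$y, dt$x)
  seeds <- integer(0)
  for (i in ord) {
    if (length(seeds) == 0L ||
        all((dt$y[seeds] - dt$y[i])^2 + (dt$x[seeds] - dt$x[i])^2 >= min_sep_px^2)) {
      # only genuine local maxima (not slope pixels) start new objects
      nb <- abs(dt$y - dt$y[i]) <= 1L & abs(dt$x - dt$x[i]) <= 1L
      if (all(dt$dist[nb] <= dt$dist[i])) seeds <- c(seeds, i)
    }
  }
  if (length(seeds) <= 1L) return(rep(1L, length(comp_idx)))
  sy <- dt$y[seeds]; sx <- dt$x[seeds]
  assign <- vapply(seq_along(dt$y), function(i) {
    which.min((sy - dt$y[i])^2 + (sx - dt$x[i])^2)
  }, integer(1))
  assign
}

#' Segment nuclei on the nuclear channel
#'
#' The default `classical` backend is fully deterministic: the ROI-masked
#' nuclear channel is Gaussian-smoothed, thresholded (Otsu by default, on
#' range-relative bins so the result is invariant to positive intensity
#' rescaling), 8-connected components are extracted, merged clumps are split
#' by seeds on the exact Euclidean distance transform, and objects below a
#' minimum area are removed. The `stardist` backend is an adapter seam for
#' the published 2-D nuclei model; in this build no StarDist runtime is
#' available and requesting it raises a backend-unavailable error that
#' instructs fallback to `classical`.
#'
#' Nuclei touching the image border are kept (they are flagged downstream in
#' measurement); dropping them would silently change total cell counts.
#'
#' @param image single-plane `CalibratedImage` (project a stack first).
#' @param roi_mask logical `(y, x)` matrix, or `NULL` for full frame.
#' @param backend `"classical"` or `"stardist"`.
#' @param params backend parameters. For `classical`:
#'   `smooth_sigma_um` (default 0.25), `threshold_method` (`"otsu"` or
#'   `"fixed"`), `threshold_value` (for `"fixed"`), `min_area_um2`
#'   (default 4), `split_touching` (default TRUE),
#'   `split_min_distance_um` (default 4).
#' @return a `LabelMap` of nuclei.
#' @export
segment_nuclei <- function(image, roi_mask = NULL,
                           backend = c("classical", "stardist"),
                           params = list()) {
  backend <- match.arg(backend)
  if (backend == "stardist") {
    cyto_abort(paste("StarDist backend is not available in this installation;",
                     "re-run with backend = 'classical'"),
               "cytoring_backend_unavailable_error")
  }
  if (dim(image$pixels)[1] != 1L) {
    cyto_abort("segment_nuclei needs a single-plane image; call project_zstack first",
               "cytoring_config_error")
  }
  p <- utils::modifyList(list(
    smooth_sigma_um = 0.25,
    threshold_method = "otsu",
    threshold_value = NA_real_,
    min_area_um2 = 4,
    split_touching = TRUE,
    split_min_distance_um = 4
  ), params)
  cal <- image$pixel_size_um
  nuc <- channel_matrix(image, image$nuclear_channel)
  ny <- nrow(nuc); nx <- ncol(nuc)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, ny, nx)
  if (!identical(dim(roi_mask), dim(nuc))) {
    cyto_abort("roi_mask grid does not match the image", "cytoring_roi_error")
  }
  masked <- nuc
  masked[!roi_mask] <- 0

  sm <- gaussian_smooth(masked, p$smooth_sigma_um / cal)
  thr <- switch(p$threshold_method,
    otsu = otsu_threshold(sm[roi_mask]),
    fixed = {
      if (!is.finite(p$threshold_value)) {
        cyto_abort("threshold_method 'fixed' needs threshold_value",
                   "cytoring_config_error")
      }
      p$threshold_value
    },
    cyto_abort(sprintf("unknown threshold_method '%s'", p$threshold_method),
               "cytoring_config_error")
  )
  fg <- sm > thr & roi_mask
  if (!any(fg)) {
    cyto_warn("segmentation found no nuclei (all background)",
              "cytoring_empty_segmentation_warning")
    return(label_map(matrix(0L, ny, nx), cal))
  }
  comp <- connected_components(fg)
  out <- matrix(0L, ny, nx)
  next_id <- 1L
  for (k in seq_len(max(comp))) {
    idx <- which(comp == k)
    parts <- if (isTRUE(p$split_touching)) {
      split_component(idx, ny, nx, p$split_min_distance_um / cal)
    } else {
      rep(1L, length(idx))
    }
    for (s in sort(unique(parts))) {
      out[idx[parts == s]] <- next_id
      next_id <- next_id + 1L
    }
  }
  out <- relabel_contiguous(out)
  lm <- label_map(out, cal)
  lm <- filter_labels(lm, p$min_area_um2)
  if (lm$n_labels == 0L) {
    cyto_warn("segmentation found no nuclei after area filtering",
              "cytoring_empty_segmentation_warning")
  }
  lm
}

#' Remove labels below a physical area threshold
#'
#' Labels whose pixel area times calibration squared falls below
#' `min_area_um2` are removed; survivors are renumbered to a contiguous
#' `1..K'` preserving their original order.
#'
#' @param labels a `LabelMap`.
#' @param min_area_um2 non-negative area threshold in square micrometres.
#' @param pixel_size_um optional calibration override (defaults to the
#'   LabelMap's own).
#' @return a filtered `LabelMap`.
#' @export
filter_labels <- function(labels, min_area_um2, pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- labels$pixel_size_um
  if (!is.numeric(min_area_um2) || min_area_um2 < 0) {
    cyto_abort("min_area_um2 must be non-negative", "cytoring_config_error")
  }
  mat <- labels$labels
  if (labels$n_labels == 0L) return(labels)
  areas <- tabulate(mat[mat > 0L], labels$n_labels) * pixel_size_um^2
  keep <- which(areas >= min_area_um2)
  lookup <- integer(labels$n_labels)
  lookup[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(mat), ncol(mat))
  pos <- mat > 0L
  out[pos] <- lookup[mat[pos]]
  label_map(out, labels$pixel_size_um)
}

# per-label linear pixel index sets of a LabelMap
label_pixel_sets <- function(labels) {
  mat <- labels$labels
  if (labels$n_labels == 0L) return(list())
  idx <- which(mat > 0L)
  split(idx, mat[idx])[as.character(seq_len(labels$n_labels))]
}
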