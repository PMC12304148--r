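#' Expansion settings
#'
#' @param distance_um positive expansion distance in micrometres
#'   (default 1.0, the distance used throughout the pipeline to reach the
#'   perinuclear cytoplasm).
#' @param mode `"independent"` (per-label dilation, neighbouring footprints
#'   may overlap -- faithful to per-ROI enlargement in interactive tools,
#'   including its double-positive failure mode) or `"exclusive"` (dilated
#'   territory partitioned to the nearest label; ties at exactly equal
#'   distance go to the smaller label id).
#' @return an `ExpansionSettings` object.
#' @export
expansion_settings <- function(distance_um = 1.0,
                               mode = c("independent", "exclusive")) {
  stopifnot_scalar_pos(distance_um, "distance_um")
  mode <- match.arg(mode)
  structure(list(distance_um = distance_um, mode = mode),
            class = "ExpansionSettings")
}

#' Expand nucleus labels by a physical distance
#'
#' Converts `distance_um` to a pixel radius (`distance_um / pixel_size_um`,
#' kept fractional -- no rounding) and grows each label under pixel-center
#' Euclidean distance with the `<=` comparator. In `independent` mode a
#' background pixel joins label L's footprint iff its distance to the
#' nearest pixel of L is within the radius, regardless of other labels, so
#' neighbouring footprints may overlap. In `exclusive` mode each background
#' pixel within reach of any label is assigned only to the nearest label
#' (ties to the smaller id), so footprints are pairwise disjoint and their
#' union equals the independent-mode union. Footprints are clipped at the
#' image bounds and are always supersets of their nucleus.
#'
#' @param labels a `LabelMap`.
#' @param settings an `ExpansionSettings` object.
#' @param pixel_size_um optional calibration override.
#' @return an `ExpandedFootprints` object: per-label linear pixel-index
#'   sets plus grid and provenance metadata.
#' @export
expand_labels <- function(labels, settings = expansion_settings(),
                          pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- labels$pixel_size_um
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um", "cytoring_calibration_error")
  mat <- labels$labels
  ny <- nrow(mat); nx <- ncol(mat)
  radius_px <- settings$distance_um / pixel_size_um
  r2 <- radius_px^2
  rc <- ceiling(radius_px)
  sets <- label_pixel_sets(labels)

  # per-label candidate scan restricted to the dilated bounding box;
  # exact squared pixel-center distances (integer arithmetic) against r2
  reach <- vector("list", length(sets))
  for (L in seq_along(sets)) {
    idx <- sets[[L]]
    y <- (idx - 1L) %% ny
    x <- (idx - 1L) %/% ny
    y0 <- max(min(y) - rc, 0L); y1 <- min(max(y) + rc, ny - 1L)
    x0 <- max(min(x) - rc, 0L); x1 <- min(max(x) + rc, nx - 1L)
    cy <- rep(y0:y1, times = x1 - x0 + 1L)
    cx <- rep(x0:x1, each = y1 - y0 + 1L)
    cidx <- cx * ny + cy + 1L
    outside <- !(cidx %in% idx)
    cy <- cy[outside]; cx <- cx[outside]; cidx <- cidx[outside]
    if (length(cidx)) {
      d2 <- rep(Inf, length(cidx))
      for (j in seq_along(idx)) {
        d2 <- pmin(d2, (cy - y[j])^2 + (cx - x[j])^2)
      }
      keep <- d2 <= r2
      reach[[L]] <- list(idx = cidx[keep], d2 = d2[keep])
    } else {
      reach[[L]] <- list(idx = integer(0), d2 = numeric(0))
    }
  }

  footprints <- vector("list", length(sets))
  if (settings$mode == "independent") {
    for (L in seq_along(sets)) {
      footprints[[L]] <- sort(c(sets[[L]], reach[[L]]$idx))
    }
  } else {
    best_d2 <- rep(Inf, ny * nx)
    best_lab <- integer(ny * nx)
    nucleus_of <- integer(ny * nx)
    for (L in seq_along(sets)) nucleus_of[sets[[L]]] <- L
    for (L in seq_along(sets)) {          # ascending label order: ties -> smaller id
      ri <- reach[[L]]$idx; rd <- reach[[L]]$d2
      take <- rd < best_d2[ri]
      best_d2[ri[take]] <- rd[take]
      best_lab[ri[take]] <- L
    }
    best_lab[nucleus_of > 0L] <- 0L       # nucleus pixels never reassigned
    for (L in seq_along(sets)) {
      footprints[[L]] <- sort(c(sets[[L]], which(best_lab == L)))
    }
  }
  structure(list(footprints = footprints, dim = c(ny, nx),
                 mode = settings$mode, distance_um = settings$distance_um,
                 pixel_size_um = pixel_size_um, n_labels = length(sets)),
            class = "ExpandedFootprints")
}

#' @export
print.ExpandedFootprints <- function(x, ...) {
  cat(sprintf("ExpandedFootprints: %d label(s), %g um (%s mode) on %d x %d px\n",
              x$n_labels, x$distance_um, x$mode, x$dim[1], x$dim[2]))
  invisible(x)
}

#' Interspace (ring) mask of one expanded cell
#'
#' The annulus between a nucleus and its expanded footprint -- the proxy for
#' the perinuclear cytoplasm. May be empty for a footprint fully clipped at
#' the image border or for sub-pixel expansion radii.
#'
#' @param footprints an `ExpandedFootprints` object.
#' @param labels the `LabelMap` the footprints were grown from.
#' @param label_id label of interest.
#' @return logical `(y, x)` matrix.
#' @export
ring_mask <- function(footprints, labels, label_id) {
  label_id <- as.integer(label_id)
  if (label_id < 1L || label_id > footprints$n_labels) {
    cyto_abort(sprintf("label %d does not exist (1..%d)", label_id,
                       footprints$n_labels), "cytoring_missing_label_error")
  }
  mask <- matrix(FALSE, footprints$dim[1], footprints$dim[2])
  mask[footprints$footprints[[label_id]]] <- TRUE
  mask[labels$labels == label_id] <- FALSE
  mask
}
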