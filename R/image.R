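#' Calibrated multi-channel image
#'
#' The package's canonical image container: a non-negative intensity array in
#' fixed `(z, channel, y, x)` order together with an isotropic in-plane pixel
#' calibration in micrometres per pixel. Between 1 and 5 channels are
#' supported; the nuclear counterstain (typically DAPI) is channel 1 by
#' convention but any channel may be designated.
#'
#' @param pixels numeric array. Accepted shapes: `(y, x)` (single plane,
#'   single channel), `(channel, y, x)` (single plane) or the canonical
#'   `(z, channel, y, x)`.
#' @param pixel_size_um positive scalar, micrometres per pixel (isotropic).
#' @param channel_names optional character vector, one name per channel.
#' @param nuclear_channel index of the nuclear channel (default 1).
#' @return an object of class `CalibratedImage`.
#' @export
calibrated_image <- function(pixels, pixel_size_um, channel_names = NULL,
                             nuclear_channel = 1L) {
  d <- dim(pixels)
  if (is.null(d) || length(d) == 2L) {
    pixels <- array(pixels, c(1L, 1L, dim(as.matrix(pixels))))
  } else if (length(d) == 3L) {
    pixels <- array(pixels, c(1L, d))
  } else if (length(d) != 4L) {
    cyto_abort("pixels must be a (y,x), (channel,y,x) or (z,channel,y,x) array",
               "cytoring_input_format_error")
  }
  d <- dim(pixels)
  n_channels <- d[2]
  if (n_channels < 1L || n_channels > 5L) {
    cyto_abort(sprintf("images with %d channels are not supported (limit is 5)",
                       n_channels), "cytoring_channel_limit_error")
  }
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um", "cytoring_calibration_error")
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    cyto_abort("pixel intensities must be finite and non-negative",
               "cytoring_input_format_error")
  }
  nuclear_channel <- as.integer(nuclear_channel)
  if (nuclear_channel < 1L || nuclear_channel > n_channels) {
    cyto_abort(sprintf("nuclear_channel %d does not address a channel (1..%d)",
                       nuclear_channel, n_channels), "cytoring_config_error")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(n_channels))
  }
  if (length(channel_names) != n_channels) {
    cyto_abort("channel_names length must equal the number of channels",
               "cytoring_config_error")
  }
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel_names = as.character(channel_names),
                 nuclear_channel = nuclear_channel),
            class = "CalibratedImage")
}

#' @export
print.CalibratedImage <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("CalibratedImage: %d z-plane(s), %d channel(s), %d x %d px @ %g um/px\n",
              d[1], d[2], d[3], d[4], x$pixel_size_um))
  cat("channels:", paste(x$channel_names, collapse = ", "),
      sprintf("(nuclear: %d)\n", x$nuclear_channel))
  invisible(x)
}

#' @export
dim.CalibratedImage <- function(x) dim(x$pixels)

img_ny <- function(image) dim(image$pixels)[3]
img_nx <- function(image) dim(image$pixels)[4]
n_channels <- function(image) dim(image$pixels)[2]

#' Extract one channel of a single-plane image as a matrix
#'
#' @param image a `CalibratedImage` with z = 1.
#' @param channel channel index.
#' @return numeric `(y, x)` matrix.
#' @export
channel_matrix <- function(image, channel) {
  channel <- as.integer(channel)
  if (channel < 1L || channel > n_channels(image)) {
    cyto_abort(sprintf("channel %d out of range", channel), "cytoring_config_error")
  }
  if (dim(image$pixels)[1] != 1L) {
    cyto_abort("image has z > 1; project it first", "cytoring_config_error")
  }
  matrix(image$pixels[1, channel, , ], nrow = img_ny(image))
}

#' Load a calibrated multi-channel TIFF
#'
#' Reads an uncompressed grayscale multi-page TIFF and normalizes it to the
#' canonical `(z, channel, y, x)` layout. Page order follows the ImageJ
#' hyperstack convention (channel fastest, then slice); a multi-page file
#' without hyperstack metadata is interpreted as one page per channel,
#' single plane. Calibration precedence is: explicit `pixel_size_um`
#' argument, then TIFF resolution tags (with the physical unit taken from
#' ImageJ metadata, or from the ResolutionUnit tag), then a
#' calibration-missing error -- the 1 um expansion downstream needs a real
#' physical scale and the loader refuses to guess one. Anisotropic in-plane
#' calibration is rejected.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um optional positive scalar overriding file metadata.
#' @param nuclear_channel nuclear channel index (default 1).
#' @param channel_names optional channel names.
#' @return a `CalibratedImage`.
#' @export
load_image <- function(path, pixel_size_um = NULL, nuclear_channel = 1L,
                       channel_names = NULL) {
  tif <- read_tiff(path)
  n_pages <- length(tif$pages)
  ij <- parse_imagej_description(tif$meta$description)

  n_ch <- if (!is.null(ij$channels)) as.integer(ij$channels) else n_pages
  n_z <- if (!is.null(ij$slices)) as.integer(ij$slices) else 1L
  if (!is.null(ij$channels) || !is.null(ij$slices)) {
    if (n_ch * n_z != n_pages) {
      cyto_abort(sprintf("TIFF metadata declares %d channels x %d slices but file has %d pages",
                         n_ch, n_z, n_pages), "cytoring_input_format_error")
    }
  }
  if (n_ch > 5L) {
    cyto_abort(sprintf("images with %d channels are not supported (limit is 5)", n_ch),
               "cytoring_channel_limit_error")
  }

  if (is.null(pixel_size_um)) {
    xres <- tif$meta$x_resolution
    yres <- tif$meta$y_resolution
    if (is.null(xres) || xres <= 0) {
      cyto_abort(sprintf("no pixel calibration: pass pixel_size_um or use a TIFF with resolution metadata (%s)",
                         path), "cytoring_calibration_missing_error")
    }
    if (!is.null(yres) && yres > 0 && abs(xres - yres) / xres > 1e-6) {
      cyto_abort("anisotropic in-plane calibration is not supported",
                 "cytoring_calibration_error")
    }
    unit <- ij$unit
    per_um <- if (!is.null(unit) && unit %in% c("micron", "um", "µm", "micrometer")) {
      xres
    } else if (!is.null(tif$meta$resolution_unit) && tif$meta$resolution_unit == 2) {
      xres / 25400                       # pixels per inch -> pixels per um
    } else if (!is.null(tif$meta$resolution_unit) && tif$meta$resolution_unit == 3) {
      xres / 10000                       # pixels per cm -> pixels per um
    } else {
      # ResolutionUnit "none": assume the resolution is in pixels per micron,
      # the convention our own writer (and ImageJ) uses
      xres
    }
    pixel_size_um <- 1 / per_um
  }

  h <- nrow(tif$pages[[1]]); w <- ncol(tif$pages[[1]])
  pixels <- array(0, c(n_z, n_ch, h, w))
  for (z in seq_len(n_z)) {
    for (cc in seq_len(n_ch)) {
      pixels[z, cc, , ] <- tif$pages[[(z - 1L) * n_ch + cc]]
    }
  }
  calibrated_image(pixels, pixel_size_um, channel_names = channel_names,
                   nuclear_channel = nuclear_channel)
}

#' Write a calibrated image to a multi-page TIFF
#'
#' Pixel values are rounded to the nearest integer and must fit the chosen
#' bit depth. Integer-valued images round-trip bit-exactly through
#' [load_image()].
#'
#' @param image a `CalibratedImage`.
#' @param path output path.
#' @param bits bit depth, 8 or 16 (default 16).
#' @return the path, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  d <- dim(image$pixels)
  pages <- vector("list", d[1] * d[2])
  for (z in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      pages[[(z - 1L) * d[2] + cc]] <- round(matrix(image$pixels[z, cc, , ], nrow = d[3]))
    }
  }
  desc <- paste0("ImageJ=1.54f\nimages=", d[1] * d[2],
                 "\nchannels=", d[2],
                 "\nslices=", d[1],
                 "\nhyperstack=true\nmode=grayscale\nunit=micron\n")
  write_tiff(pages, path, bits = bits, description = desc,
             pixels_per_um = 1 / image$pixel_size_um)
  invisible(path)
}

#' Z-project a focal stack to a single plane
#'
#' Collapses the z axis by pixelwise maximum or arithmetic mean, per channel.
#' A single-plane image is returned unchanged under either method.
#'
#' @param image a `CalibratedImage`.
#' @param method `"max"` or `"mean"`.
#' @return a single-plane `CalibratedImage`.
#' @export
project_zstack <- function(image, method = c("max", "mean")) {
  if (!is.character(method) || !all(method %in% c("max", "mean"))) {
    cyto_abort(sprintf("unknown projection method '%s'", paste(method, collapse = ",")),
               "cytoring_config_error")
  }
  method <- match.arg(method)
  d <- dim(image$pixels)
  if (d[1] == 1L) return(image)
  out <- array(0, c(1L, d[2], d[3], d[4]))
  for (cc in seq_len(d[2])) {
    planes <- matrix(image$pixels[, cc, , ], nrow = d[1])
    out[1, cc, , ] <- if (method == "max") {
      apply(planes, 2, max)
    } else {
      colMeans(planes)
    }
  }
  calibrated_image(out, image$pixel_size_um, image$channel_names,
                   image$nuclear_channel)
}

#' Polygonal region of interest
#'
#' Vertices are `(y, x)` pixel coordinates, 0-based, pixel-center semantics.
#' The polygon must be simple (non-self-intersecting) with at least 3
#' distinct vertices and non-zero area.
#'
#' @param vertices numeric matrix with columns `(y, x)`, or a list of
#'   length-2 vectors.
#' @return an object of class `RegionOfInterest`.
#' @export
roi_polygon <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, lapply(vertices, as.numeric))
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) {
    cyto_abort("ROI vertices must be a two-column (y, x) matrix", "cytoring_roi_error")
  }
  # drop a repeated closing vertex
  n <- nrow(vertices)
  if (n >= 2L && all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  if (nrow(unique(vertices)) < 3L) {
    cyto_abort("ROI polygon needs at least 3 distinct vertices", "cytoring_roi_error")
  }
  y <- vertices[, 1]; x <- vertices[, 2]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (abs(area2) < .Machine$double.eps * 16) {
    cyto_abort("ROI polygon has zero area (collinear vertices)", "cytoring_roi_error")
  }
  if (polygon_self_intersects(vertices)) {
    cyto_abort("ROI polygon is self-intersecting", "cytoring_roi_error")
  }
  structure(list(vertices = vertices, full_frame = FALSE),
            class = "RegionOfInterest")
}

#' Full-frame region of interest sentinel
#'
#' @return a `RegionOfInterest` covering the whole image.
#' @export
roi_full <- function() {
  structure(list(vertices = NULL, full_frame = TRUE), class = "RegionOfInterest")
}

# proper-crossing test between non-adjacent edges; shared endpoints allowed
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- function(i) rbind(v[i, ], v[if (i == n) 1L else i + 1L, ])
  orient <- function(a, b, c) {
    sign((b[2] - a[2]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[2] - a[2]))
  }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next
      s1 <- seg(i); s2 <- seg(j)
      o1 <- orient(s1[1, ], s1[2, ], s2[1, ])
      o2 <- orient(s1[1, ], s1[2, ], s2[2, ])
      o3 <- orient(s2[1, ], s2[2, ], s1[1, ])
      o4 <- orient(s2[1, ], s2[2, ], s1[2, ])
      if (o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rasterize a region of interest to a pixel mask
#'
#' A pixel belongs to the mask when its center lies inside the polygon;
#' centers exactly on the boundary are included. The full-frame sentinel
#' yields an all-true mask.
#'
#' @param roi a `RegionOfInterest`.
#' @param image a `CalibratedImage` supplying the grid.
#' @return logical `(y, x)` matrix.
#' @export
rasterize_roi <- function(roi, image) {
  ny <- img_ny(image); nx <- img_nx(image)
  if (roi$full_frame) return(matrix(TRUE, ny, nx))
  gx <- rep(seq_len(nx) - 1L, each = ny)
  gy <- rep(seq_len(ny) - 1L, times = nx)
  inside <- sp::point.in.polygon(gx, gy, roi$vertices[, 2], roi$vertices[, 1])
  matrix(inside > 0, ny, nx)
}

#' Read an ImageJ .roi file (polygon type)
#'
#' Minimal parser for the ImageJ ROI binary format, polygon ROIs only.
#'
#' @param path path to a `.roi` file.
#' @return a `RegionOfInterest`.
#' @export
read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout") {
    cyto_abort(sprintf("not an ImageJ .roi file: %s", path), "cytoring_roi_error")
  }
  be16 <- function(off, n = 1L, signed = TRUE) {
    readBin(raw[(off + 1):(off + 2L * n)], "integer", n = n, size = 2L,
            signed = signed, endian = "big")
  }
  type <- be16(6L)
  if (type != 0L) {                      # 0 = polygon
    cyto_abort("only polygon .roi files are supported", "cytoring_roi_error")
  }
  top <- be16(8L); left <- be16(10L)
  n_coords <- be16(16L, signed = FALSE)
  xs <- be16(64L, n = n_coords)
  ys <- be16(64L + 2L * n_coords, n = n_coords)
  roi_polygon(cbind(ys + top, xs + left))
}
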