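# Minimal baseline TIFF support.
#
# The deployment target has no TIFF-capable R package, so the package carries
# its own reader/writer for the subset of baseline TIFF the pipeline needs:
# uncompressed, single-sample-per-pixel (grayscale) pages, 8- or 16-bit
# unsigned integers, little- or big-endian, multiple strips, ImageJ-style
# hyperstack metadata (images/channels/slices/unit) and X/YResolution tags
# for pixel calibration. Anything else is rejected with a structured error
# rather than guessed at.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

u32 <- function(x) {
  x <- as.numeric(x)
  ifelse(x < 0, x + 4294967296, x)
}

read_tiff_values <- function(raw, offset, type, count, endian) {
  # offset is 0-based into `raw`
  size <- TIFF_TYPE_SIZES[type]
  bytes <- raw[(offset + 1):(offset + size * count)]
  if (type == 3L) {                                   # SHORT
    readBin(bytes, "integer", n = count, size = 2L, signed = FALSE, endian = endian)
  } else if (type == 4L) {                            # LONG
    u32(readBin(bytes, "integer", n = count, size = 4L, endian = endian))
  } else if (type == 5L) {                            # RATIONAL
    v <- u32(readBin(bytes, "integer", n = 2L * count, size = 4L, endian = endian))
    v[seq(1L, 2L * count, by = 2L)] / v[seq(2L, 2L * count, by = 2L)]
  } else if (type == 2L) {                            # ASCII
    rawToChar(bytes[bytes != as.raw(0L)])
  } else if (type == 1L) {                            # BYTE
    as.integer(bytes)
  } else {
    cyto_abort(sprintf("unsupported TIFF tag type %d", type),
               "cytoring_input_format_error")
  }
}

# Parse a TIFF file into a list of pages (numeric matrices, [y, x]) plus
# metadata (description string, x/y resolution in pixels per unit,
# resolution unit code).
read_tiff <- function(path) {
  if (!file.exists(path)) {
    cyto_abort(sprintf("file not found: %s", path), "cytoring_input_format_error")
  }
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) {
    cyto_abort(sprintf("not a TIFF file (too short): %s", path),
               "cytoring_input_format_error")
  }
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else {
    cyto_abort(sprintf("not a TIFF file (bad byte-order mark): %s", path),
               "cytoring_input_format_error")
  }
  magic <- readBin(raw[3:4], "integer", size = 2L, signed = FALSE, endian = endian)
  if (magic != 42L) {
    cyto_abort(sprintf("not a TIFF file (bad magic number): %s", path),
               "cytoring_input_format_error")
  }
  ifd_offset <- u32(readBin(raw[5:8], "integer", size = 4L, endian = endian))

  pages <- list()
  meta <- list(description = NULL, x_resolution = NULL, y_resolution = NULL,
               resolution_unit = NULL)
  while (ifd_offset != 0) {
    n_tags <- readBin(raw[(ifd_offset + 1):(ifd_offset + 2)], "integer",
                      size = 2L, signed = FALSE, endian = endian)
    tags <- list()
    for (i in seq_len(n_tags)) {
      base <- ifd_offset + 2L + (i - 1L) * 12L
      entry <- raw[(base + 1):(base + 12)]
      id <- readBin(entry[1:2], "integer", size = 2L, signed = FALSE, endian = endian)
      type <- readBin(entry[3:4], "integer", size = 2L, signed = FALSE, endian = endian)
      count <- u32(readBin(entry[5:8], "integer", size = 4L, endian = endian))
      if (!(type %in% c(1L, 2L, 3L, 4L, 5L))) next
      nbytes <- TIFF_TYPE_SIZES[type] * count
      value_offset <- if (nbytes <= 4) base + 8L else
        u32(readBin(entry[9:12], "integer", size = 4L, endian = endian))
      tags[[as.character(id)]] <- read_tiff_values(raw, value_offset, type, count, endian)
    }
    tag <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    width <- tag(256); height <- tag(257)
    if (is.null(width) || is.null(height)) {
      cyto_abort("TIFF page missing width/length tags", "cytoring_input_format_error")
    }
    bits <- tag(258, 8L)[1]
    if (!(bits %in% c(8L, 16L))) {
      cyto_abort(sprintf("unsupported TIFF bit depth %d (only 8/16-bit supported)", bits),
                 "cytoring_input_format_error")
    }
    if (tag(259, 1L) != 1L) {
      cyto_abort("compressed TIFFs are not supported", "cytoring_input_format_error")
    }
    if (tag(277, 1L) != 1L) {
      cyto_abort("multi-sample (interleaved colour) TIFFs are not supported; use one page per channel",
                 "cytoring_input_format_error")
    }
    fmt <- tag(339, 1L)
    if (fmt != 1L) {
      cyto_abort("only unsigned-integer TIFF sample data is supported",
                 "cytoring_input_format_error")
    }
    strip_offsets <- tag(273)
    strip_counts <- tag(279)
    if (is.null(strip_offsets) || is.null(strip_counts)) {
      cyto_abort("TIFF page missing strip tags", "cytoring_input_format_error")
    }
    data_bytes <- raw(0)
    for (s in seq_along(strip_offsets)) {
      data_bytes <- c(data_bytes,
                      raw[(strip_offsets[s] + 1):(strip_offsets[s] + strip_counts[s])])
    }
    n_px <- width * height
    vals <- if (bits == 8L) {
      as.numeric(readBin(data_bytes, "integer", n = n_px, size = 1L,
                         signed = FALSE, endian = endian))
    } else {
      as.numeric(readBin(data_bytes, "integer", n = n_px, size = 2L,
                         signed = FALSE, endian = endian))
    }
    if (length(vals) < n_px) {
      cyto_abort("TIFF strip data truncated", "cytoring_input_format_error")
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals[seq_len(n_px)], nrow = width))
    if (is.null(meta$description)) meta$description <- tag(270)
    if (is.null(meta$x_resolution)) meta$x_resolution <- tag(282)
    if (is.null(meta$y_resolution)) meta$y_resolution <- tag(283)
    if (is.null(meta$resolution_unit)) meta$resolution_unit <- tag(296)
    ifd_offset <- u32(readBin(raw[(ifd_offset + 3L + n_tags * 12L):
                                  (ifd_offset + 6L + n_tags * 12L)],
                              "integer", size = 4L, endian = endian))
  }
  if (length(pages) == 0L) {
    cyto_abort("TIFF file contains no images", "cytoring_input_format_error")
  }
  list(pages = pages, meta = meta)
}

tiff_tag_entry <- function(id, type, count, value_or_offset) {
  # returns list used by writer; value_or_offset is the 4-byte field content
  list(id = id, type = type, count = count, value = value_or_offset)
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2L, endian = "little")
write_u32 <- function(con, x) {
  x <- as.numeric(x)
  x <- ifelse(x >= 2147483648, x - 4294967296, x)
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}

# Write grayscale pages (list of [y, x] matrices of non-negative integers) as
# an uncompressed little-endian baseline TIFF. `pixels_per_um` fills the
# X/YResolution tags; `description` carries ImageJ-style hyperstack metadata.
write_tiff <- function(pages, path, bits = 16L, description = NULL,
                       pixels_per_um = NULL) {
  stopifnot(length(pages) >= 1L)
  bits <- as.integer(bits)
  if (!(bits %in% c(8L, 16L))) {
    cyto_abort("bits must be 8 or 16", "cytoring_config_error")
  }
  maxval <- 2^bits - 1
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  for (p in pages) {
    if (nrow(p) != h || ncol(p) != w) {
      cyto_abort("all TIFF pages must share one grid", "cytoring_config_error")
    }
    if (any(!is.finite(p)) || any(p < 0) || any(p > maxval) ||
        any(p != round(p))) {
      cyto_abort(sprintf("pixel values must be integers in [0, %d] for %d-bit TIFF output",
                         maxval, bits), "cytoring_config_error")
    }
  }
  n_pages <- length(pages)
  bytes_per_px <- bits / 8L
  page_bytes <- h * w * bytes_per_px

  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0L)) else raw(0)
  if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0L))

  header_len <- 8L
  desc_offset <- header_len
  rational_offset <- desc_offset + length(desc_raw)
  has_res <- !is.null(pixels_per_um)
  rational_len <- if (has_res) 16L else 0L
  data_offset0 <- rational_offset + rational_len
  data_offsets <- data_offset0 + (seq_len(n_pages) - 1L) * page_bytes

  make_tags <- function(page_i) {
    tags <- list(
      tiff_tag_entry(256L, 4L, 1L, w),
      tiff_tag_entry(257L, 4L, 1L, h),
      tiff_tag_entry(258L, 3L, 1L, bits),
      tiff_tag_entry(259L, 3L, 1L, 1L),
      tiff_tag_entry(262L, 3L, 1L, 1L)
    )
    if (page_i == 1L && length(desc_raw) > 0L) {
      tags <- c(tags, list(tiff_tag_entry(270L, 2L, length(desc_raw), desc_offset)))
    }
    tags <- c(tags, list(
      tiff_tag_entry(273L, 4L, 1L, data_offsets[page_i]),
      tiff_tag_entry(277L, 3L, 1L, 1L),
      tiff_tag_entry(278L, 4L, 1L, h),
      tiff_tag_entry(279L, 4L, 1L, page_bytes)
    ))
    if (has_res) {
      tags <- c(tags, list(
        tiff_tag_entry(282L, 5L, 1L, rational_offset),
        tiff_tag_entry(283L, 5L, 1L, rational_offset + 8L)
      ))
    }
    c(tags, list(
      tiff_tag_entry(296L, 3L, 1L, 1L),   # unit "none"; physical unit in description
      tiff_tag_entry(339L, 3L, 1L, 1L)
    ))
  }
  tag_sets <- lapply(seq_len(n_pages), make_tags)
  ifd_lens <- vapply(tag_sets, function(t) 2L + 12L * length(t) + 4L, integer(1))
  ifd_offsets <- data_offset0 + n_pages * page_bytes + c(0L, cumsum(ifd_lens))[seq_len(n_pages)]

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_u16(con, 42L)
  write_u32(con, ifd_offsets[1])
  if (length(desc_raw) > 0L) writeBin(desc_raw, con)
  if (has_res) {
    # pixels per micron as a rational with fixed denominator for determinism
    denom <- 1000000
    num <- round(pixels_per_um * denom)
    write_u32(con, num); write_u32(con, denom)
    write_u32(con, num); write_u32(con, denom)
  }
  for (p in pages) {
    vals <- as.integer(t(p))            # row-major
    writeBin(vals, con, size = bytes_per_px, endian = "little")
  }
  for (i in seq_len(n_pages)) {
    tags <- tag_sets[[i]]
    write_u16(con, length(tags))
    for (tg in tags) {
      write_u16(con, tg$id)
      write_u16(con, tg$type)
      write_u32(con, tg$count)
      if (tg$type == 3L && TIFF_TYPE_SIZES[tg$type] * tg$count <= 4L) {
        write_u16(con, tg$value); write_u16(con, 0L)
      } else {
        write_u32(con, tg$value)
      }
    }
    write_u32(con, if (i < n_pages) ifd_offsets[i + 1L] else 0L)
  }
  invisible(path)
}

# Parse ImageJ-style description lines ("key=value") into a named list.
parse_imagej_description <- function(desc) {
  if (is.null(desc) || !nzchar(desc)) return(list())
  lines <- strsplit(desc, "\n", fixed = TRUE)[[1]]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)=(.*)$", ln))[[1]]
    if (length(kv) == 3L) out[[kv[2]]] <- kv[3]
  }
  out
}
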