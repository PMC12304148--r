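MEASUREMENT_COLUMNS <- c("label", "channel", "area_px", "area_um2",
                         "mean_intensity", "integrated_intensity",
                         "min_intensity", "max_intensity",
                         "centroid_y", "centroid_x", "touches_border",
                         "pixel_size_um")

new_measurement_table <- function(df, sample_id, enlargement_state, pixel_size_um) {
  structure(df, sample_id = sample_id, enlargement_state = enlargement_state,
            pixel_size_um = pixel_size_um,
            class = c("MeasurementTable", "data.frame"))
}

#' Measure per-cell, per-channel region statistics
#'
#' One row per (label, channel): pixel area, physical area, mean, integrated
#' (summed), min and max intensity, centroid (0-based pixel coordinates) and
#' a border-contact flag. Regions may be a nucleus `LabelMap` ("without
#' enlargement") or `ExpandedFootprints` ("with enlargement"); overlapping
#' independent-mode footprints are each measured over their full own pixel
#' set, so shared pixels contribute to every footprint that covers them. An
#' empty region yields an area-0 row with NaN intensity sentinels (never 0,
#' which would silently classify as negative) and a warning.
#'
#' @param image single-plane `CalibratedImage`.
#' @param regions a `LabelMap` or `ExpandedFootprints` on the same grid.
#' @param channels channel indices to measure (default: all).
#' @param sample_id sample identifier recorded in the table metadata.
#' @return a `MeasurementTable` (data frame with metadata attributes
#'   `sample_id`, `enlargement_state`, `pixel_size_um`).
#' @export
measure_cells <- function(image, regions, channels = seq_len(n_channels(image)),
                          sample_id = "sample") {
  if (dim(image$pixels)[1] != 1L) {
    cyto_abort("measure_cells needs a single-plane image; call project_zstack first",
               "cytoring_config_error")
  }
  channels <- as.integer(channels)
  if (any(channels < 1L | channels > n_channels(image))) {
    cyto_abort("channel index out of range", "cytoring_config_error")
  }
  if (inherits(regions, "LabelMap")) {
    sets <- label_pixel_sets(regions)
    state <- "without"
    grid <- dim(regions$labels)
  } else if (inherits(regions, "ExpandedFootprints")) {
    sets <- regions$footprints
    state <- "with"
    grid <- regions$dim
  } else {
    cyto_abort("regions must be a LabelMap or ExpandedFootprints",
               "cytoring_config_error")
  }
  ny <- img_ny(image); nx <- img_nx(image)
  if (!identical(as.integer(grid), c(ny, nx))) {
    cyto_abort("regions grid does not match the image", "cytoring_config_error")
  }
  cal <- image$pixel_size_um
  k <- length(sets)
  rows <- vector("list", k * length(channels))
  empties <- integer(0)
  ci <- 0L
  chan_mats <- lapply(channels, function(cc) channel_matrix(image, cc))
  for (L in seq_len(k)) {
    idx <- sets[[L]]
    a <- length(idx)
    if (a == 0L) empties <- c(empties, L)
    y <- (idx - 1L) %% ny
    x <- (idx - 1L) %/% ny
    border <- a > 0L && (min(y) == 0L || min(x) == 0L ||
                         max(y) == ny - 1L || max(x) == nx - 1L)
    for (j in seq_along(channels)) {
      vals <- chan_mats[[j]][idx]
      ci <- ci + 1L
      rows[[ci]] <- data.frame(
        label = L, channel = channels[j], area_px = a, area_um2 = a * cal^2,
        mean_intensity = if (a) mean(vals) else NaN,
        integrated_intensity = if (a) sum(vals) else NaN,
        min_intensity = if (a) min(vals) else NaN,
        max_intensity = if (a) max(vals) else NaN,
        centroid_y = if (a) mean(y) else NaN,
        centroid_x = if (a) mean(x) else NaN,
        touches_border = border, pixel_size_um = cal)
    }
  }
  if (length(empties)) {
    cyto_warn(sprintf("empty region(s) for label(s) %s: intensity set to NaN",
                      paste(empties, collapse = ", ")),
              "cytoring_empty_region_warning")
  }
  df <- if (ci) do.call(rbind, rows[seq_len(ci)]) else {
    as.data.frame(stats::setNames(rep(list(numeric(0)), length(MEASUREMENT_COLUMNS)),
                                  MEASUREMENT_COLUMNS))
  }
  rownames(df) <- NULL
  new_measurement_table(df, sample_id, state, cal)
}

measurement_state <- function(tbl) attr(tbl, "enlargement_state")
measurement_sample <- function(tbl) attr(tbl, "sample_id")

csv_file_name <- function(sample_id, channel, state) {
  sprintf("%s_ch%d_%s_enlargement.csv", sample_id, channel, state)
}

#' Write paired without/with-enlargement measurement CSVs
#'
#' Per measured channel c, writes `{sample}_ch{c}_without_enlargement.csv`
#' and `{sample}_ch{c}_with_enlargement.csv` into `out_dir`: comma-separated,
#' header row, one data row per label in ascending label order, C-locale
#' numeric formatting.
#'
#' @param without `MeasurementTable` over the nucleus regions.
#' @param with_enl `MeasurementTable` over the expanded footprints.
#' @param out_dir output directory (created if missing).
#' @param sample_id sample identifier used in file names (defaults to the
#'   tables' own).
#' @return named character vector of the files written, invisibly.
#' @export
write_measurement_csvs <- function(without, with_enl, out_dir,
                                   sample_id = measurement_sample(without)) {
  if (!setequal(unique(without$label), unique(with_enl$label)) ||
      !setequal(unique(without$channel), unique(with_enl$channel))) {
    cyto_abort("without/with tables do not pair: label or channel sets differ",
               "cytoring_pairing_error")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) cyto_abort(sprintf("cannot create directory %s", out_dir),
                        "cytoring_io_error")
  }
  paths <- character(0)
  for (tbl in list(without, with_enl)) {
    state <- measurement_state(tbl)
    for (cc in sort(unique(tbl$channel))) {
      sub <- tbl[tbl$channel == cc, , drop = FALSE]
      sub <- sub[order(sub$label), , drop = FALSE]
      path <- file.path(out_dir, csv_file_name(sample_id, cc, state))
      ok <- tryCatch({
        utils::write.csv(as.data.frame(sub), path, row.names = FALSE,
                         quote = FALSE, fileEncoding = "UTF-8")
        TRUE
      }, error = function(e) FALSE)
      if (!ok) cyto_abort(sprintf("cannot write %s", path), "cytoring_io_error")
      paths[sprintf("ch%d_%s", cc, state)] <- path
    }
  }
  invisible(paths)
}

parse_csv_file_name <- function(fname) {
  m <- regmatches(fname, regexec("^(.*)_ch([0-9]+)_(without|with)_enlargement\\.csv$",
                                 fname))[[1]]
  if (length(m) != 4L) return(NULL)
  list(sample_id = m[2], channel = as.integer(m[3]), state = m[4])
}

read_one_measurement_csv <- function(path, sample_id, state) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   cyto_abort(sprintf("malformed CSV %s: %s", path, conditionMessage(e)),
                              "cytoring_parse_error")
                 })
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    cyto_abort(sprintf("malformed CSV %s: missing column(s) %s", path,
                       paste(missing_cols, collapse = ", ")),
               "cytoring_parse_error")
  }
  new_measurement_table(df[, MEASUREMENT_COLUMNS], sample_id, state,
                        df$pixel_size_um[1])
}

#' Read a directory of paired measurement CSVs
#'
#' Files are matched by the `{sample}_ch{k}_{without|with}_enlargement.csv`
#' naming scheme and paired on (sample, channel); unpaired files trigger a
#' warning naming them and are excluded. Rows from all channels of one
#' sample are combined into one table pair per sample.
#'
#' @param dir directory to scan.
#' @return named list (by sample id) of `list(without =, with_enl =)`
#'   `MeasurementTable` pairs; empty list for an empty directory.
#' @export
read_measurement_csvs <- function(dir) {
  files <- list.files(dir, pattern = "_enlargement\\.csv$")
  parsed <- Filter(Negate(is.null), lapply(files, parse_csv_file_name))
  names(parsed) <- Filter(function(f) !is.null(parse_csv_file_name(f)), files)
  if (length(parsed) == 0L) return(list())
  keys <- vapply(parsed, function(p) sprintf("%s|%d", p$sample_id, p$channel), character(1))
  out <- list()
  orphans <- character(0)
  for (key in unique(keys)) {
    members <- parsed[keys == key]
    fnames <- names(members)
    states <- vapply(members, `[[`, character(1), "state")
    if (!setequal(states, c("without", "with"))) {
      orphans <- c(orphans, fnames)
      next
    }
    sample_id <- members[[1]]$sample_id
    channel <- members[[1]]$channel
    wo <- read_one_measurement_csv(file.path(dir, fnames[states == "without"]),
                                   sample_id, "without")
    wi <- read_one_measurement_csv(file.path(dir, fnames[states == "with"]),
                                   sample_id, "with")
    if (is.null(out[[sample_id]])) {
      out[[sample_id]] <- list(without = wo, with_enl = wi)
    } else {
      out[[sample_id]]$without <- new_measurement_table(
        rbind(as.data.frame(out[[sample_id]]$without), as.data.frame(wo)),
        sample_id, "without", attr(wo, "pixel_size_um"))
      out[[sample_id]]$with_enl <- new_measurement_table(
        rbind(as.data.frame(out[[sample_id]]$with_enl), as.data.frame(wi)),
        sample_id, "with", attr(wi, "pixel_size_um"))
    }
  }
  if (length(orphans)) {
    cyto_warn(sprintf("unpaired measurement file(s) excluded: %s",
                      paste(sort(orphans), collapse = ", ")),
              "cytoring_unpaired_file_warning")
  }
  out
}
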