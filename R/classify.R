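#' Classification configuration
#'
#' Per-marker threshold entries plus pipeline options, round-trippable to
#' YAML so a configuration can be reused across analyses for consistency.
#' Each entry names a marker, the image channel it lives on and a
#' non-negative intensity threshold; a channel may carry several entries
#' with different thresholds (e.g. a "high-expressing" population on the
#' same channel with a higher cutoff). The comparator is fixed to
#' strictly-greater: a cell is positive when its new mean intensity exceeds
#' the threshold; ties classify negative.
#'
#' @param channels list of entries, each a list with `channel` (index),
#'   `name`, `threshold` (>= 0) and optional `enabled` (default TRUE).
#' @param intensity_method `"ring"` (default: mean over the interspace
#'   annulus, derived from the paired measurements) or `"expanded_mean"`
#'   (mean over the whole expanded footprint).
#' @param expansion list with `distance_um` and `mode` (see
#'   [expansion_settings()]).
#' @param segmentation list of [segment_nuclei()] backend settings
#'   (`backend` plus params).
#' @param nuclear_channel nuclear channel index (excluded from
#'   classification; it only drives segmentation).
#' @param roi optional list with `vertices` (list of `(y, x)` pairs).
#' @param projection z-projection method for stacks, `"max"` or `"mean"`.
#' @param pixel_size_um optional calibration override applied to every
#'   loaded image (um/px).
#' @param note free-text provenance note.
#' @return a `ClassificationConfig` object.
#' @export
classification_config <- function(channels,
                                  intensity_method = c("ring", "expanded_mean"),
                                  expansion = list(distance_um = 1.0,
                                                   mode = "independent"),
                                  segmentation = list(backend = "classical"),
                                  nuclear_channel = 1L,
                                  roi = NULL,
                                  projection = c("max", "mean"),
                                  pixel_size_um = NULL,
                                  note = NULL) {
  intensity_method <- match.arg(intensity_method)
  projection <- match.arg(projection)
  if (!is.null(pixel_size_um)) {
    stopifnot_scalar_pos(pixel_size_um, "pixel_size_um", "cytoring_calibration_error")
  }
  if (!is.list(channels) || length(channels) == 0L) {
    cyto_abort("config needs at least one channel entry", "cytoring_config_error")
  }
  entries <- lapply(channels, function(e) {
    if (is.null(e$channel) || is.null(e$name) || is.null(e$threshold)) {
      cyto_abort("each channel entry needs channel, name and threshold",
                 "cytoring_config_error")
    }
    if (!is.numeric(e$threshold) || e$threshold < 0) {
      cyto_abort(sprintf("threshold for '%s' must be >= 0", e$name),
                 "cytoring_config_error")
    }
    list(channel = as.integer(e$channel), name = as.character(e$name),
         threshold = as.numeric(e$threshold),
         enabled = if (is.null(e$enabled)) TRUE else isTRUE(e$enabled))
  })
  nms <- vapply(entries, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    cyto_abort("channel entry names must be unique", "cytoring_config_error")
  }
  if (!any(vapply(entries, `[[`, logical(1), "enabled"))) {
    cyto_abort("at least one channel entry must be enabled", "cytoring_config_error")
  }
  structure(list(channels = entries, intensity_method = intensity_method,
                 expansion = expansion, segmentation = segmentation,
                 nuclear_channel = as.integer(nuclear_channel),
                 roi = roi, projection = projection,
                 pixel_size_um = pixel_size_um, note = note),
            class = "ClassificationConfig")
}

enabled_entries <- function(config) {
  Filter(function(e) isTRUE(e$enabled), config$channels)
}

#' Write a classification configuration to YAML
#' @param config a `ClassificationConfig`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' Read a classification configuration from YAML
#' @param path YAML file written by [write_config()] (or by hand, same keys).
#' @return a `ClassificationConfig`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    cyto_abort(sprintf("config file not found: %s", path), "cytoring_config_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    cyto_abort(sprintf("cannot parse YAML config %s: %s", path,
                       conditionMessage(e)), "cytoring_config_error")
  })
  if (is.null(raw$channels)) {
    cyto_abort(sprintf("config %s has no 'channels' block", path),
               "cytoring_config_error")
  }
  classification_config(
    channels = raw$channels,
    intensity_method = if (is.null(raw$intensity_method)) "ring" else raw$intensity_method,
    expansion = if (is.null(raw$expansion)) list(distance_um = 1.0, mode = "independent") else raw$expansion,
    segmentation = if (is.null(raw$segmentation)) list(backend = "classical") else raw$segmentation,
    nuclear_channel = if (is.null(raw$nuclear_channel)) 1L else raw$nuclear_channel,
    roi = raw$roi,
    projection = if (is.null(raw$projection)) "max" else raw$projection,
    pixel_size_um = raw$pixel_size_um,
    note = raw$note
  )
}

#' Derive a positivity threshold from a representative intensity
#'
#' Thresholds are set from a manually measured intensity judged
#' representative of the cell type, scaled by a fixed factor (default 0.6)
#' to tolerate expression heterogeneity below the representative level.
#'
#' @param representative_intensity positive scalar.
#' @param factor scale factor, default 0.6.
#' @return the threshold, `representative_intensity * factor`.
#' @export
derive_threshold <- function(representative_intensity, factor = 0.6) {
  if (!is.numeric(representative_intensity) || length(representative_intensity) != 1L ||
      !is.finite(representative_intensity) || representative_intensity <= 0) {
    cyto_abort("representative_intensity must be a single positive number",
               "cytoring_domain_error")
  }
  representative_intensity * factor
}

#' Derive each cell's new mean intensity from paired measurements
#'
#' The `ring` method recovers the mean over the interspace annulus without
#' re-touching pixels, via the paired-measurement identity
#' `(IntDen_with - IntDen_without) / (Area_with - Area_without)`. The
#' `expanded_mean` method takes the with-enlargement mean directly. When the
#' expansion added no pixels (footprint fully clipped, or sub-pixel radius)
#' the ring is empty: the cell is flagged degenerate and falls back to its
#' nucleus mean, with a warning.
#'
#' @param without nucleus `MeasurementTable`.
#' @param with_enl expanded-footprint `MeasurementTable`.
#' @param method `"ring"` (default) or `"expanded_mean"`.
#' @return a `CellIntensity` data frame: `label`, `channel`, `new_mean`,
#'   `degenerate`.
#' @export
compute_cell_intensity <- function(without, with_enl,
                                   method = c("ring", "expanded_mean")) {
  method <- match.arg(method)
  wo <- as.data.frame(without)[, c("label", "channel", "area_px",
                                   "integrated_intensity", "mean_intensity")]
  wi <- as.data.frame(with_enl)[, c("label", "channel", "area_px",
                                    "integrated_intensity", "mean_intensity")]
  m <- merge(wo, wi, by = c("label", "channel"), suffixes = c("_wo", "_wi"),
             all = TRUE)
  if (any(is.na(m$area_px_wo)) || any(is.na(m$area_px_wi))) {
    cyto_abort("without/with tables do not pair row-for-row on (label, channel)",
               "cytoring_pairing_error")
  }
  d_area <- m$area_px_wi - m$area_px_wo
  if (any(d_area < 0)) {
    cyto_abort("with-enlargement area smaller than nucleus area: corrupted tables",
               "cytoring_data_integrity_error")
  }
  degenerate <- d_area == 0
  new_mean <- numeric(nrow(m))
  if (method == "ring") {
    d_int <- m$integrated_intensity_wi - m$integrated_intensity_wo
    new_mean[!degenerate] <- d_int[!degenerate] / d_area[!degenerate]
    if (any(new_mean[!degenerate] < -1e-9, na.rm = TRUE)) {
      cyto_abort("negative ring mean: impossible for non-negative pixels, tables corrupted",
                 "cytoring_data_integrity_error")
    }
  } else {
    new_mean[!degenerate] <- m$mean_intensity_wi[!degenerate]
  }
  new_mean[degenerate] <- m$mean_intensity_wo[degenerate]
  if (any(degenerate)) {
    cyto_warn(sprintf("empty interspace for %d (label, channel) pair(s); falling back to nucleus mean",
                      sum(degenerate)), "cytoring_degenerate_cell_warning")
  }
  out <- data.frame(label = m$label, channel = m$channel,
                    new_mean = new_mean, degenerate = degenerate)
  out <- out[order(out$label, out$channel), ]
  rownames(out) <- NULL
  class(out) <- c("CellIntensity", "data.frame")
  out
}

#' Classify cells against per-marker thresholds
#'
#' A cell is positive for an enabled marker entry iff its new mean intensity
#' on that entry's channel strictly exceeds the entry's threshold.
#' Degenerate-flagged intensities classify with their fallback value and
#' propagate the flag.
#'
#' @param intensities a `CellIntensity` from [compute_cell_intensity()].
#' @param config a `ClassificationConfig`.
#' @return a `CellClassification`: label vector, marker names, and logical
#'   positive/degenerate matrices (labels x markers).
#' @export
classify_cells <- function(intensities, config) {
  entries <- enabled_entries(config)
  labels <- sort(unique(intensities$label))
  markers <- vapply(entries, `[[`, character(1), "name")
  positive <- matrix(FALSE, length(labels), length(entries),
                     dimnames = list(NULL, markers))
  degenerate <- positive
  for (j in seq_along(entries)) {
    e <- entries[[j]]
    sub <- intensities[intensities$channel == e$channel, , drop = FALSE]
    if (!all(labels %in% sub$label)) {
      cyto_abort(sprintf("enabled channel %d ('%s') missing from intensities",
                         e$channel, e$name), "cytoring_config_error")
    }
    sub <- sub[match(labels, sub$label), , drop = FALSE]
    positive[, j] <- !is.na(sub$new_mean) & sub$new_mean > e$threshold
    degenerate[, j] <- sub$degenerate
  }
  structure(list(labels = labels, markers = markers, positive = positive,
                 degenerate = degenerate),
            class = "CellClassification")
}

combo_key <- function(marker_idx, markers) {
  paste(markers[sort(marker_idx)], collapse = "+")
}

#' Summarize a classified sample
#'
#' Counts the total cells, the cells positive for each enabled marker
#' (single- and multi-positive alike), the exclusively-single-positive cells
#' per marker, each observed marker combination of size >= 2, and the cells
#' negative for every marker, with percentages of the total. Exclusive
#' singles, exact combinations and all-negative cells partition the total.
#' With zero cells, counts are zero and percentages are NA (undefined).
#'
#' @param classification a `CellClassification`.
#' @param config the `ClassificationConfig` used (fixes marker order).
#' @param sample_id sample identifier.
#' @return a `SampleSummary` object.
#' @export
summarize_sample <- function(classification, config, sample_id = "sample") {
  markers <- classification$markers
  pos <- classification$positive
  total <- length(classification$labels)
  pct <- function(n) if (total > 0) 100 * n / total else rep(NA_real_, length(n))

  n_pos <- if (total) colSums(pos) else stats::setNames(rep(0, length(markers)), markers)
  set_keys <- if (total) {
    apply(pos, 1, function(r) combo_key(which(r), markers))
  } else {
    character(0)
  }
  n_per_set <- table(set_keys)
  exclusive <- vapply(markers, function(m) {
    n <- n_per_set[m]
    if (is.na(n)) 0L else as.integer(n)
  }, integer(1))
  combo_names <- setdiff(names(n_per_set), c(markers, ""))
  # order combos lexicographically by marker indices in config order
  combo_idx <- lapply(combo_names, function(k) match(strsplit(k, "+", fixed = TRUE)[[1]], markers))
  ord <- order(vapply(combo_idx, function(ix) paste(sprintf("%03d", sort(ix)), collapse = ""),
                      character(1)))
  combos <- data.frame(
    combo = combo_names[ord],
    count = vapply(combo_names[ord], function(k) as.integer(n_per_set[k]), integer(1)),
    stringsAsFactors = FALSE)
  combos$pct <- pct(combos$count)
  rownames(combos) <- NULL
  neg_i <- match("", names(n_per_set))
  negative <- if (is.na(neg_i)) 0L else as.integer(n_per_set[[neg_i]])

  structure(list(
    sample_id = sample_id, total_cells = total,
    markers = data.frame(name = markers,
                         positive = as.integer(n_pos),
                         pct_positive = pct(as.numeric(n_pos)),
                         exclusive = exclusive,
                         pct_exclusive = pct(as.numeric(exclusive)),
                         stringsAsFactors = FALSE, row.names = NULL),
    combos = combos,
    negative = negative, pct_negative = pct(negative)),
    class = "SampleSummary")
}

#' @export
print.SampleSummary <- function(x, ...) {
  cat(sprintf("SampleSummary '%s': %d cell(s)\n", x$sample_id, x$total_cells))
  for (i in seq_len(nrow(x$markers))) {
    cat(sprintf("  %s: %d positive (%.1f%%), %d exclusive\n",
                x$markers$name[i], x$markers$positive[i],
                x$markers$pct_positive[i], x$markers$exclusive[i]))
  }
  for (i in seq_len(nrow(x$combos))) {
    cat(sprintf("  %s: %d (%.1f%%)\n", x$combos$combo[i], x$combos$count[i],
                x$combos$pct[i]))
  }
  cat(sprintf("  negative for all: %d\n", x$negative))
  invisible(x)
}

sanitize_column <- function(x) gsub("[^A-Za-z0-9]+", ".", x)

#' Write sample summaries to a single CSV
#'
#' One row per sample. Column order: total cells, then per-marker positive
#' counts and percentages in config order, then exclusive counts, then
#' marker combinations (union over samples, lexicographic by marker index),
#' then all-negative counts. All samples must share one marker set.
#'
#' @param summaries list of `SampleSummary` objects (>= 1).
#' @param out_path output CSV path.
#' @return the path, invisibly.
#' @export
write_summary_csv <- function(summaries, out_path) {
  if (length(summaries) == 0L) {
    cyto_abort("no summaries to write", "cytoring_config_error")
  }
  marker_sets <- lapply(summaries, function(s) s$markers$name)
  if (!all(vapply(marker_sets, identical, logical(1), marker_sets[[1]]))) {
    cyto_abort("summaries have different enabled channel sets; cannot share a schema",
               "cytoring_column_mismatch_error")
  }
  markers <- marker_sets[[1]]
  all_combos <- unique(unlist(lapply(summaries, function(s) s$combos$combo)))
  combo_rank <- vapply(all_combos, function(k) {
    ix <- match(strsplit(k, "+", fixed = TRUE)[[1]], markers)
    paste(sprintf("%03d", sort(ix)), collapse = "")
  }, character(1))
  all_combos <- all_combos[order(combo_rank)]

  rows <- lapply(summaries, function(s) {
    row <- list(sample_id = s$sample_id, total_cells = s$total_cells)
    for (i in seq_along(markers)) {
      m <- sanitize_column(markers[i])
      row[[paste0("pos_", m)]] <- s$markers$positive[i]
      row[[paste0("pct_", m)]] <- s$markers$pct_positive[i]
    }
    for (i in seq_along(markers)) {
      m <- sanitize_column(markers[i])
      row[[paste0("excl_", m)]] <- s$markers$exclusive[i]
      row[[paste0("pct_excl_", m)]] <- s$markers$pct_exclusive[i]
    }
    for (k in all_combos) {
      kk <- sanitize_column(k)
      hit <- match(k, s$combos$combo)
      row[[paste0("combo_", kk)]] <- if (is.na(hit)) 0L else s$combos$count[hit]
      row[[paste0("pct_combo_", kk)]] <- if (is.na(hit)) {
        if (s$total_cells > 0) 0 else NA_real_
      } else {
        s$combos$pct[hit]
      }
    }
    row$negative <- s$negative
    row$pct_negative <- s$pct_negative
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) cyto_abort(sprintf("cannot write %s", out_path), "cytoring_io_error")
  invisible(out_path)
}

#' Read a summary CSV written by [write_summary_csv()]
#' @param path CSV path.
#' @return a data frame, one row per sample.
#' @export
read_summary_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the per-cell classification debug table
#'
#' One row per cell: label, per-marker new mean intensity and positive
#' calls, the positive set, and the degenerate flag.
#'
#' @param classification a `CellClassification`.
#' @param intensities the matching `CellIntensity`.
#' @param config the `ClassificationConfig` used.
#' @param out_path output CSV path.
#' @return the path, invisibly.
#' @export
write_cell_csv <- function(classification, intensities, config, out_path) {
  entries <- enabled_entries(config)
  labels <- classification$labels
  df <- data.frame(label = labels)
  for (j in seq_along(entries)) {
    e <- entries[[j]]
    sub <- intensities[intensities$channel == e$channel, , drop = FALSE]
    sub <- sub[match(labels, sub$label), , drop = FALSE]
    df[[paste0("mean_", sanitize_column(e$name))]] <- sub$new_mean
    df[[paste0("pos_", sanitize_column(e$name))]] <- classification$positive[, j]
  }
  df$positive_set <- apply(classification$positive, 1, function(r) {
    paste(classification$markers[r], collapse = "+")
  })
  df$degenerate <- apply(classification$degenerate, 1, any)
  utils::write.csv(df, out_path, row.names = FALSE, quote = FALSE)
  invisible(out_path)
}
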