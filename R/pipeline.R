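#' Quantify marker expression for a given nucleus label map
#'
#' The analysis core shared by the command-line stages: expand the labels by
#' the configured distance, measure every channel over the nuclei and over
#' the expanded footprints, derive each cell's new mean intensity, classify
#' against the configured thresholds and summarize the populations.
#' Deterministic for fixed inputs.
#'
#' @param image single-plane `CalibratedImage`.
#' @param labels nucleus `LabelMap` (from [segment_nuclei()] or ground
#'   truth).
#' @param config a `ClassificationConfig`.
#' @param sample_id sample identifier.
#' @return list with `without`, `with_enl` (`MeasurementTable`s),
#'   `intensities`, `classification` and `summary`.
#' @export
quantify_labels <- function(image, labels, config, sample_id = "sample") {
  settings <- expansion_settings(
    distance_um = if (is.null(config$expansion$distance_um)) 1.0 else config$expansion$distance_um,
    mode = if (is.null(config$expansion$mode)) "independent" else config$expansion$mode)
  fp <- expand_labels(labels, settings)
  without <- measure_cells(image, labels, sample_id = sample_id)
  with_enl <- measure_cells(image, fp, sample_id = sample_id)
  intensities <- compute_cell_intensity(without, with_enl,
                                        method = config$intensity_method)
  classification <- classify_cells(intensities, config)
  summary <- summarize_sample(classification, config, sample_id)
  list(without = without, with_enl = with_enl, footprints = fp,
       intensities = intensities, classification = classification,
       summary = summary)
}

config_roi <- function(config) {
  if (is.null(config$roi)) return(roi_full())
  roi_polygon(config$roi$vertices)
}

measure_one_image <- function(path, config, out_dir, pixel_size_um = NULL) {
  sample_id <- sub("\\.[Tt][Ii][Ff][Ff]?$", "", basename(path))
  cal <- if (!is.null(pixel_size_um)) pixel_size_um else config$pixel_size_um
  image <- load_image(path, pixel_size_um = cal,
                      nuclear_channel = config$nuclear_channel)
  image <- project_zstack(image, config$projection)
  roi_mask <- rasterize_roi(config_roi(config), image)
  seg <- config$segmentation
  backend <- if (is.null(seg$backend)) "classical" else seg$backend
  labels <- segment_nuclei(image, roi_mask, backend = backend,
                           params = seg[setdiff(names(seg), "backend")])
  settings <- expansion_settings(
    distance_um = if (is.null(config$expansion$distance_um)) 1.0 else config$expansion$distance_um,
    mode = if (is.null(config$expansion$mode)) "independent" else config$expansion$mode)
  fp <- expand_labels(labels, settings)
  without <- measure_cells(image, labels, sample_id = sample_id)
  with_enl <- measure_cells(image, fp, sample_id = sample_id)
  write_measurement_csvs(without, with_enl, out_dir, sample_id = sample_id)
}

write_manifest <- function(manifest, out_dir, name = "manifest.json") {
  path <- file.path(out_dir, name)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  file.rename(tmp, path)                  # atomic on one filesystem
  invisible(path)
}

#' Batch-measure images into paired CSVs
#'
#' Per image: load, z-project if needed, apply the configured ROI, segment
#' nuclei, expand, measure both states and write the paired CSVs. Files are
#' processed in isolation: a failure on one image is recorded in the run
#' manifest and processing continues; the returned status is 0 when all
#' files succeeded, 2 on partial failure.
#'
#' @param inputs character vector of TIFF paths (>= 1).
#' @param config a `ClassificationConfig` or a YAML path.
#' @param out_dir output directory for CSVs and `manifest.json`.
#' @param pixel_size_um optional calibration override for all inputs.
#' @return invisibly, list with `status`, `manifest`.
#' @export
cmd_measure <- function(inputs, config, out_dir, pixel_size_um = NULL) {
  if (length(inputs) == 0L) {
    cyto_abort("no input images given", "cytoring_usage_error")
  }
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "ClassificationConfig")) {
    cyto_abort("config must be a ClassificationConfig or a YAML path",
               "cytoring_config_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  warnings_seen <- character(0)
  files <- list()
  for (path in inputs) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch({
        paths <- measure_one_image(path, config, out_dir, pixel_size_um)
        list(status = "ok", csv_files = as.character(basename(paths)))
      }, error = function(e) {
        list(status = "failed", error = conditionMessage(e))
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            sprintf("%s: %s", basename(path), conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    res$input <- path
    res$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    files[[length(files) + 1L]] <- res
  }
  n_failed <- sum(vapply(files, function(f) f$status == "failed", logical(1)))
  manifest <- list(
    tool = "cytoring",
    version = as.character(utils::packageVersion("cytoring")),
    stage = "measure",
    config = unclass(config),
    inputs = as.list(inputs),
    files = files,
    warnings = as.list(warnings_seen),
    n_failed = n_failed
  )
  write_manifest(manifest, out_dir, "measure_manifest.json")
  status <- if (n_failed == length(inputs)) 1L else if (n_failed > 0L) 2L else 0L
  invisible(list(status = status, manifest = manifest))
}

#' Classify a directory of paired measurement CSVs into a summary
#'
#' Reads all without/with pairs, computes per-cell new mean intensities,
#' classifies them against the configured thresholds and writes one summary
#' row per sample. Rerunning on identical inputs produces byte-identical
#' output.
#'
#' @param csv_dir directory of measurement CSVs.
#' @param config a `ClassificationConfig` or YAML path.
#' @param out_path path of the summary CSV to write.
#' @param cells_dir optional directory for per-cell debug CSVs.
#' @return invisibly, list with `status`, `summaries`.
#' @export
cmd_classify <- function(csv_dir, config, out_path, cells_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "ClassificationConfig")) {
    cyto_abort("config must be a ClassificationConfig or a YAML path",
               "cytoring_config_error")
  }
  warnings_seen <- character(0)
  pairs <- withCallingHandlers(
    read_measurement_csvs(csv_dir),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (length(pairs) == 0L) {
    cyto_abort(sprintf("no valid measurement pairs found in %s", csv_dir),
               "cytoring_empty_input_error")
  }
  summaries <- vector("list", length(pairs))
  sample_ids <- sort(names(pairs))        # stable order
  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]
    pair <- pairs[[sid]]
    res <- withCallingHandlers({
      intens <- compute_cell_intensity(pair$without, pair$with_enl,
                                       method = config$intensity_method)
      cls <- classify_cells(intens, config)
      if (!is.null(cells_dir)) {
        if (!dir.exists(cells_dir)) dir.create(cells_dir, recursive = TRUE)
        write_cell_csv(cls, intens, config,
                       file.path(cells_dir, paste0(sid, "_cells.csv")))
      }
      summarize_sample(cls, config, sample_id = sid)
    }, warning = function(w) {
      warnings_seen <<- c(warnings_seen, sprintf("%s: %s", sid, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    summaries[[i]] <- res
  }
  write_summary_csv(summaries, out_path)
  manifest <- list(
    tool = "cytoring",
    version = as.character(utils::packageVersion("cytoring")),
    stage = "classify",
    config = unclass(config),
    inputs = as.list(sample_ids),
    summary_csv = out_path,
    warnings = as.list(warnings_seen),
    n_failed = 0L
  )
  write_manifest(manifest, dirname(out_path), "classify_manifest.json")
  invisible(list(status = 0L, summaries = summaries))
}

#' Measure and classify in one pass
#'
#' Composition of [cmd_measure()] and [cmd_classify()]: the summary is
#' written to `out_dir/summary.csv` and the paired CSVs plus manifest land
#' in `out_dir`.
#'
#' @inheritParams cmd_measure
#' @return invisibly, list with `status`, `summaries`.
#' @export
cmd_run <- function(inputs, config, out_dir, pixel_size_um = NULL) {
  meas <- cmd_measure(inputs, config, out_dir, pixel_size_um)
  cls <- cmd_classify(out_dir, config, file.path(out_dir, "summary.csv"))
  invisible(list(status = max(meas$status, cls$status),
                 summaries = cls$summaries))
}

#' Simulate an image to disk (TIFF + ground truth CSV + config YAML)
#'
#' @param out_dir output directory.
#' @param params a `SimulationParams`.
#' @param name base name for the emitted files.
#' @return invisibly, list of written paths.
#' @export
cmd_simulate <- function(out_dir, params = simulation_params(),
                         name = "simulated") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_image(params)
  tiff_path <- file.path(out_dir, paste0(name, ".tif"))
  write_image(sim$image, tiff_path)
  truth_path <- file.path(out_dir, paste0(name, "_ground_truth.csv"))
  utils::write.csv(sim$ground_truth$cells, truth_path, row.names = FALSE,
                   quote = FALSE)
  cfg <- classification_config(
    channels = lapply(seq_along(params$markers), function(j) {
      mk <- params$markers[[j]]
      list(channel = j + 1L, name = mk$name,
           threshold = derive_threshold((mk$pos_mean + mk$neg_mean) / 2),
           enabled = TRUE)
    }),
    nuclear_channel = 1L,
    note = sprintf("auto-generated for simulated image (seed %d)", params$seed))
  cfg_path <- file.path(out_dir, paste0(name, "_config.yaml"))
  write_config(cfg, cfg_path)
  invisible(list(tiff = tiff_path, ground_truth = truth_path,
                 config = cfg_path, simulation = sim))
}

cli_usage <- function() {
  paste(
    "usage: cytoring <command> [args]",
    "",
    "commands:",
    "  measure  --config <yaml> --out <dir> [--pixel-size-um <x>] <tiff> [...]",
    "  classify --config <yaml> --out <summary.csv> <csv-dir>",
    "  run      --config <yaml> --out <dir> [--pixel-size-um <x>] <tiff> [...]",
    "  simulate --out <dir> [--seed <int>] [--config <yaml-with-simulate-block>]",
    sep = "\n")
}

parse_cli_flags <- function(args) {
  flags <- list(); positional <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--config", "--out", "--pixel-size-um", "--seed", "--log-level")) {
      if (i == length(args)) {
        cyto_abort(sprintf("flag %s needs a value", a), "cytoring_usage_error")
      }
      flags[[sub("^--", "", a)]] <- args[i + 1L]
      i <- i + 2L
    } else if (startsWith(a, "--")) {
      cyto_abort(sprintf("unknown flag %s", a), "cytoring_usage_error")
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

#' Command-line entry point
#'
#' Dispatches the `measure`, `classify`, `run` and `simulate` subcommands.
#' Intended to be called from the launcher script with
#' `commandArgs(trailingOnly = TRUE)`; returns the process exit status
#' (0 success, 1 usage/config error, 2 partial batch failure).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
cyto_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L) {
      cyto_abort(cli_usage(), "cytoring_usage_error")
    }
    cmd <- args[1]
    parsed <- parse_cli_flags(args[-1])
    flags <- parsed$flags; pos <- parsed$positional
    need <- function(flag) {
      if (is.null(flags[[flag]])) {
        cyto_abort(sprintf("command '%s' requires --%s\n%s", cmd, flag, cli_usage()),
                   "cytoring_usage_error")
      }
      flags[[flag]]
    }
    px <- if (is.null(flags[["pixel-size-um"]])) NULL else as.numeric(flags[["pixel-size-um"]])
    switch(cmd,
      measure = {
        if (length(pos) == 0L) cyto_abort("measure: no input images", "cytoring_usage_error")
        cmd_measure(pos, need("config"), need("out"), pixel_size_um = px)$status
      },
      classify = {
        if (length(pos) != 1L) cyto_abort("classify: give one CSV directory", "cytoring_usage_error")
        cmd_classify(pos, need("config"), need("out"))$status
      },
      run = {
        if (length(pos) == 0L) cyto_abort("run: no input images", "cytoring_usage_error")
        cmd_run(pos, need("config"), need("out"), pixel_size_um = px)$status
      },
      simulate = {
        seed <- if (is.null(flags$seed)) 1L else as.integer(flags$seed)
        params <- simulation_params(seed = seed)
        cmd_simulate(need("out"), params)
        0L
      },
      cyto_abort(sprintf("unknown command '%s'\n%s", cmd, cli_usage()),
                 "cytoring_usage_error")
    )
  }, cytoring_error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
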