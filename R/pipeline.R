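# Table I/O and end-to-end orchestration.

window_table_columns <- c(
  "cell_id", "sector", "depth", "frame", "time_s"
)

#' Write a window series table to CSV
#'
#' Comma-separated, UTF-8, '.' decimal, header row; lossless round trip via
#' [read_window_table()].
#'
#' @param table Window series table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(table, path) {
  validate_window_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' Read a window series table from CSV
#'
#' @param path CSV written by [write_window_table()] (or conforming to its
#'   schema: `cell_id`, `sector`, `depth`, `frame`, `time_s` plus signal
#'   columns).
#' @return A validated tibble.
#' @export
read_window_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("input path does not exist: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_window_table(tab)
  tab
}

validate_window_table <- function(table) {
  missing_cols <- setdiff(window_table_columns, names(table))
  if (length(missing_cols)) {
    abort(sprintf("window table lacks required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- table |>
    group_by(.data$cell_id, .data$sector, .data$depth) |>
    summarise(mono = all(diff(.data$frame) > 0), .groups = "drop")
  if (any(!bad$mono)) {
    abort("frames must be strictly increasing within each (cell, sector, depth).")
  }
  if (anyDuplicated(table[c("cell_id", "sector", "depth", "frame")])) {
    abort("duplicate (cell_id, sector, depth, frame) keys.")
  }
  invisible(table)
}

#' Write an image stack as multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 32-bit float TIFF pages; calibration (pixel
#' size, frame interval, channel) goes to `<path>.json`.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- purrr::map(seq_len(n_frames(stack)), ~ get_frame(stack, .x))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         frame_interval_s = stack$frame_interval_s,
         channel = stack$channel),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path (JSON sidecar `<path>.json` supplies calibration if
#'   present).
#' @param pixel_size_um,frame_interval_s,channel Calibration fallbacks when
#'   no sidecar exists.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size_um = 0.2,
                             frame_interval_s = 10, channel = "unknown") {
  if (!file.exists(path)) abort(sprintf("input path does not exist: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixel_size_um <- meta$pixel_size_um %||% pixel_size_um
    frame_interval_s <- meta$frame_interval_s %||% frame_interval_s
    channel <- meta$channel %||% channel
  }
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  image_stack(arr, pixel_size_um, frame_interval_s, channel)
}

#' Run the simulate -> analyse pipeline into a run directory
#'
#' Orchestrates the synthetic end-to-end study: generates a window series
#' table from a [synth_config()], smooths and z-normalizes it, detects
#' protrusion/retraction events, builds the four anchor-aligned ensembles
#' with bootstrap confidence bands, and computes the pairwise lagged
#' cross-correlations. All stage outputs land in `out_dir` as CSV/JSON with
#' a provenance manifest recording the resolved configuration and seeds.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if needed).
#' @param smoothing_p Temporal smoothing parameter (default 0.5).
#' @param anchor_depth Depth window used in ensembles/correlations
#'   (default 2, i.e. 1--2 um from the edge).
#' @param n_boot Bootstrap resamples for ensemble CIs (default 200).
#' @return Invisibly, a list with the in-memory stage results
#'   (`table`, `events`, `ensembles`, `xcorr`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, smoothing_p = 0.5,
                         anchor_depth = 2, n_boot = 200) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- make_window_series(config)
  write_window_table(sim$table, file.path(out_dir, "window_series.csv"))
  readr::write_csv(sim$truth$event_schedule,
                   file.path(out_dir, "event_schedule_truth.csv"))

  events <- detect_events_table(sim$table, smoothing_p = smoothing_p)
  readr::write_csv(events, file.path(out_dir, "events.csv"))

  ztab <- znormalize_table(sim$table)
  anchors <- c("protrusion_onset", "protrusion_vmax",
               "retraction_onset", "retraction_vmax")
  ensembles <- list()
  for (a in anchors) {
    ok <- sum(events$type == sub("_(onset|vmax)$", "", a)) > 0
    if (!ok) next
    ens <- align_ensembles(ztab, events, "rac1", a, depths = anchor_depth)
    ens <- ensemble_mean_ci(ens, n_boot = n_boot,
                            seed = derive_seed(config$seed, a))
    ensembles[[a]] <- ens
    readr::write_csv(tidy(ens), file.path(out_dir, paste0("ensemble_", a, ".csv")))
  }

  xc <- NULL
  if (any(events$type == "protrusion")) {
    xc <- event_cross_correlation(ztab, events, "rac1", "traction_pa",
                                  anchor = "protrusion_onset",
                                  depth = anchor_depth)
    readr::write_csv(tidy(xc), file.path(out_dir, "xcorr_rac1_traction.csv"))
  }

  manifest <- list(
    package = "edgeforce",
    version = as.character(utils::packageVersion("edgeforce")),
    config = unclass(config),
    smoothing_p = smoothing_p,
    anchor_depth = anchor_depth,
    n_boot = n_boot,
    n_events = nrow(events),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(table = sim$table, truth = sim$truth, events = events,
                 ensembles = ensembles, xcorr = xc, manifest = manifest))
}
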