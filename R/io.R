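# Formats, configuration, orchestration and reproducibility plumbing.

#' Write a phase-stack series as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered time-major: all phase steps of timepoint 1, then
#' timepoint 2, and so on. TIFF samples hold values in `[0, 1]` at 32-bit
#' depth, so intensities are divided by a power-of-two scale recorded in the
#' sidecar; when the stack holds integer photon counts (the usual case under
#' shot noise) the sidecar flags it and [read_stack()] snaps samples back to
#' the integer grid, making the round trip bit-identical.
#'
#' @param stack a [phase_stack_series()].
#' @param path output TIFF path.
#' @param sidecar JSON sidecar path (default `path` + `.json`).
#' @param metadata optional list merged into the sidecar (scene, kinetics,
#'   ground truth, seed, ...).
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".json"),
                        metadata = list()) {
  stopifnot(inherits(stack, "phase_stack_series"))
  d <- dim(stack$intensities)
  mx <- max(stack$intensities)
  scale <- if (mx > 0) 2^ceiling(log2(mx + 1)) else 1
  pages <- vector("list", d[1] * d[2])
  idx <- 1L
  for (t in seq_len(d[1])) for (k in seq_len(d[2])) {
    pages[[idx]] <- stack$intensities[t, k, , ] / scale
    idx <- idx + 1L
  }
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32,
                                   reduce = FALSE))
  meta <- c(list(
    schema_version = "1.0",
    axes = c("time", "phase_step", "row", "col"),
    dims = d,
    n_timepoints = d[1], n_phase_steps = d[2],
    phase_angles = stack$phase_angles,
    modulation_frequency = stack$modulation_frequency,
    timepoints = stack$timepoints,
    intensity_scale = scale,
    integer_data = all(stack$intensities == round(stack$intensities))
  ), metadata)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(sidecar)
}

#' Read a phase-stack series from TIFF + JSON sidecar
#'
#' @param path TIFF path written by [write_stack()].
#' @param sidecar JSON sidecar path (default `path` + `.json`).
#' @return A [phase_stack_series()] with axis order normalized to
#'   (time, phase_step, row, col).
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar))
    stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("n_timepoints", "n_phase_steps", "phase_angles",
              "modulation_frequency", "timepoints", "intensity_scale"))
    if (is.null(meta[[f]])) stop("sidecar lacks required field: ", f)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nt <- meta$n_timepoints; nk <- meta$n_phase_steps
  if (length(pages) != nt * nk)
    stop(sprintf("axis mismatch: sidecar declares %d timepoints x %d steps = %d pages, TIFF holds %d",
                 nt, nk, nt * nk, length(pages)))
  nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
  arr <- array(0, dim = c(nt, nk, nr, nc))
  idx <- 1L
  for (t in seq_len(nt)) for (k in seq_len(nk)) {
    arr[t, k, , ] <- pages[[idx]] * meta$intensity_scale
    idx <- idx + 1L
  }
  if (isTRUE(meta$integer_data)) arr <- round(arr)
  if (anyNA(arr) || any(!is.finite(arr))) stop("stack contains NaN/non-finite pixels")
  phase_stack_series(arr, meta$phase_angles, meta$modulation_frequency,
                     meta$timepoints)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with `scene`, `acquisition`, `kinetics`,
#'   `calibration`, and optional `groups`/`analysis` blocks (see the demo
#'   config in `inst/extdata/demo_device.yaml`).
#' @return The configuration as a list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  yaml::read_yaml(path)
}

.scene_from_config <- function(cfg) {
  scene_config(
    image_shape = unlist(cfg$image_shape),
    pixel_size = cfg$pixel_size,
    chamber_centers = do.call(rbind, lapply(cfg$chamber_centers, unlist)),
    chamber_diameter = cfg$chamber_diameter %||% 200,
    chamber_height = cfg$chamber_height %||% 300,
    occupancy = unlist(cfg$occupancy),
    spheroid_diameter = cfg$spheroid_diameter %||% 115,
    rng_seed = cfg$rng_seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulate -> lifetime -> oxygen -> consumption pipeline
#'
#' Executes every stage on a configuration: simulate the device, write the
#' stack, detect chambers from the DC image of the first timepoint, assign
#' design-level occupancy (detected chambers matched to the configured
#' centers), run the per-timepoint empty-chamber-referenced oxygen
#' conversion, assemble series and metrics, and compare groups when exactly
#' two are assigned. Every artifact is listed in a manifest with md5
#' checksums; identical seed and config reproduce identical checksums.
#'
#' @param config a configuration list or path to a YAML file (see
#'   [read_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed overriding the config's.
#' @return Invisibly, a list with the simulation, chamber map, oxygen
#'   results, series, metrics, optional group comparison, and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  scene <- .scene_from_config(config$scene)
  acq <- do.call(acquisition_config, config$acquisition %||% list())
  kin <- do.call(kinetics_spec, config$kinetics %||% list())
  cal_cfg <- config$calibration %||% list(tau_n = 533, tau_a = 381, o2_a = 20.9)
  calib <- calibrate_kq(cal_cfg$tau_n, cal_cfg$tau_a, cal_cfg$o2_a %||% 20.9)

  sim <- simulate_device(scene, acq, kin, calib, seed = seed)
  stack_path <- file.path(out_dir, "phase_stack.tif")
  write_stack(sim$stack, stack_path,
              metadata = list(seed = seed, scene = unclass(scene),
                              kinetics = unclass(kin),
                              ground_truth = sim$ground_truth))

  dc <- demodulate(sim$stack, 1L)$dc
  chambers <- detect_chambers(dc, scene$chamber_diameter, scene$pixel_size,
                              min_score = config$analysis$min_score %||% 0.5)
  # design-level occupancy: match detections to configured centers
  cm <- chambers$chambers
  assign_idx <- vapply(seq_len(nrow(cm)), function(i) {
    which.min((scene$chamber_centers[, 1] - cm$center_row[i])^2 +
              (scene$chamber_centers[, 2] - cm$center_col[i])^2)
  }, integer(1))
  chambers <- set_occupancy(chambers, scene$occupancy[assign_idx])

  ox <- analyze_oxygen(sim$stack, chambers, calib)
  groups <- NULL
  if (!is.null(config$groups)) {
    groups <- unlist(config$groups)
    names(groups) <- as.character(match(as.integer(names(groups)), assign_idx))
    groups <- groups[!is.na(names(groups))]
  }
  series <- assemble_series(ox$chamber_means, groups)
  rate_window <- config$analysis$rate_window %||% 5L
  plateau_window <- config$analysis$plateau_window %||% 7L
  metrics <- if (nrow(series) &&
                 length(unique(series$timepoint_min)) >= rate_window + plateau_window) {
    metrics_by_chamber(series, rate_window = rate_window,
                       plateau_window = plateau_window)
  } else NULL

  comparison <- NULL
  grps <- unique(series$group)
  if (length(grps) == 2L) {
    comparison <- compare_groups(series[series$group == grps[1], ],
                                 series[series$group == grps[2], ])
  }

  utils::write.csv(ox$chamber_means, file.path(out_dir, "chamber_means.csv"),
                   row.names = FALSE)
  utils::write.csv(ox$reference, file.path(out_dir, "reference_lifetimes.csv"),
                   row.names = FALSE)
  if (!is.null(metrics))
    utils::write.csv(metrics, file.path(out_dir, "consumption_metrics.csv"),
                     row.names = FALSE)
  if (!is.null(comparison))
    utils::write.csv(comparison, file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE)

  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_json, auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    schema_version = "1.0", seed = seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    artifacts = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  unlink(cfg_json)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = sim, chambers = chambers, oxygen = ox, series = series,
                 metrics = metrics, comparison = comparison,
                 manifest = manifest))
}
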