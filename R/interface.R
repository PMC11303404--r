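# File I/O, run configuration, manifests, and the command-line interface.
#
# Stacks travel as multi-page 16-bit grayscale TIFF with a JSON sidecar
# carrying the frame rate and scene label; traces, ROIs and ground truth as
# CSV; calibrations and manifests as JSON; run configuration as YAML.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a frame stack as multi-page 16-bit TIFF
#'
#' Intensities are quantized to 16 bits (the acquisition depth); a JSON
#' sidecar stores the frame rate and scene label. Reading the file back
#' reproduces the quantized stack bit-identically.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path.
#' @return the (invisible) path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  q <- round(stack$frames * 65535) / 65535
  pages <- lapply(seq_len(dim(q)[3]), function(i) q[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(frame_rate_hz = stack$frame_rate_hz, scene_label = stack$scene_label),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a frame stack written by [write_stack()]
#'
#' @param path TIFF path; the frame-rate sidecar `<path>.json` (or explicit
#'   `frame_rate_hz`/`scene_label` arguments) must provide the metadata.
#' @param frame_rate_hz,scene_label overrides when no sidecar exists.
#' @return A [frame_stack()].
#' @export
read_stack <- function(path, frame_rate_hz = NULL, scene_label = NULL) {
  if (!file.exists(path)) stopf("no such stack: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2) {
    stopf("%s is not grayscale; convert RGB stacks to single-channel before reading", path)
  }
  meta <- list(frame_rate_hz = frame_rate_hz, scene_label = scene_label)
  if (file.exists(sidecar_path(path))) {
    sc <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    meta$frame_rate_hz <- meta$frame_rate_hz %||% sc$frame_rate_hz
    meta$scene_label <- meta$scene_label %||% sc$scene_label
  }
  if (is.null(meta$frame_rate_hz)) {
    stopf("no frame-rate annotation for %s: provide frame_rate_hz or a '%s' sidecar",
          path, basename(sidecar_path(path)))
  }
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  frame_stack(frames, meta$frame_rate_hz, meta$scene_label %||% "closed_eye")
}

#' Write / read session ground truth as CSV
#'
#' Columns: t_s, diameter_mm, gaze_x_px, gaze_y_px, blink.
#'
#' @param truth a `session_truth`.
#' @param path CSV path.
#' @return the (invisible) path, or for the reader a data.frame.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(t_s = truth$t_s, diameter_mm = truth$diameter_mm,
                   gaze_x_px = truth$gaze_x_px, gaze_y_px = truth$gaze_y_px,
                   blink = as.integer(truth$blink_mask))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) read.csv(path)

#' Write / read darkness traces as CSV
#'
#' Columns: t_s, value, roi_label.
#'
#' @param trace a [darkness_trace()] (writer) or CSV path (reader).
#' @param path CSV path.
#' @return invisible path / a [darkness_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "darkness_trace"))
  write.csv(data.frame(t_s = trace$t_s, value = trace$values,
                       roi_label = trace$roi_label),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  fs <- 1 / median(diff(df$t_s))
  darkness_trace(df$t_s, df$value, df$roi_label[1], fs)
}

#' Write / read circle ROIs as CSV
#'
#' Columns: label, cx, cy, r (0-based pixel coordinates).
#'
#' @param rois list of [circle_roi()] (writer) or CSV path (reader).
#' @param path CSV path.
#' @return invisible path / list of [circle_roi()].
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r) {
    data.frame(label = r$label, cx = r$center_px[1], cy = r$center_px[2], r = r$radius_px)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  df <- read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    circle_roi(c(df$cx[i], df$cy[i]), df$r[i], df$label[i])
  })
}

#' Write a linear calibration as JSON
#'
#' @param calib a `linear_calibration`.
#' @param path JSON path.
#' @param provenance optional named list (session id, windows used, ...).
#' @return invisible path; `read_calibration()` restores the object.
#' @export
write_calibration <- function(calib, path, provenance = list()) {
  stopifnot(inherits(calib, "linear_calibration"))
  jsonlite::write_json(c(unclass(calib), list(provenance = provenance)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = l$slope, intercept = l$intercept,
                 r2_fit = l$r2_fit, n = l$n),
            class = "linear_calibration")
}

# ---- run configuration ---------------------------------------------------

config_known_keys <- function() list(
  top = c("experiment", "seed", "frame_rate_hz", "session_duration_s",
          "n_stim", "isi_s", "isi_jitter_s", "first_onset_s", "stim_duration_s",
          "dwell_s", "baseline_s", "repeats", "padding_s",
          "blink_rate_hz", "blink_duration_s", "blink_gain",
          "kinetics", "geometry", "eyelid", "optics", "roi_radius_px"),
  kinetics = names(formals(plr_kinetics)),
  geometry = c("screen_distance_cm", "px_per_mm", "eye_radius_mm", "grid_cm"),
  eyelid = names(formals(eyelid_model)),
  optics = setdiff(names(formals(scene_optics)), "eye_center_px")
)

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; values override the session defaults. The
#' result is a [session_config()] plus the `seed` and `roi_radius_px`
#' entries used by the command-line interface.
#'
#' @param path YAML config path.
#' @return list(config = [session_config()], seed, roi_radius_px).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such config: %s", path)
  y <- yaml::read_yaml(path) %||% list()
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stopf("unknown config key(s) in %s: %s", where, paste(bad, collapse = ", "))
  }
  known <- config_known_keys()
  check_keys(y, known$top, "top level")
  for (sec in c("kinetics", "geometry", "eyelid", "optics")) {
    if (!is.null(y[[sec]])) check_keys(y[[sec]], known[[sec]], sec)
  }
  kin <- do.call(plr_kinetics, y$kinetics %||% list())
  geo_args <- y$geometry %||% list()
  if (!is.null(geo_args$grid_cm)) {
    g <- geo_args$grid_cm
    geo_args$target_offsets_cm <- rbind(
      c(-g, -g), c(0, -g), c(g, -g), c(-g, 0), c(0, 0), c(g, 0), c(-g, g), c(g, g))
    geo_args$grid_cm <- NULL
  }
  geo <- do.call(setup_geometry, geo_args)
  lid <- do.call(eyelid_model, y$eyelid %||% list())
  opt <- do.call(scene_optics, y$optics %||% list())
  fs <- y$frame_rate_hz %||% 31
  sched <- NULL
  if ((y$experiment %||% "plr") == "plr") {
    sched <- default_plr_schedule(
      n_stim = y$n_stim %||% 10, isi_s = y$isi_s %||% 20,
      isi_jitter_s = y$isi_jitter_s %||% 2, first_onset_s = y$first_onset_s %||% 10,
      stim_duration_s = y$stim_duration_s %||% 2,
      session_duration_s = y$session_duration_s %||% 240
    )
  }
  cfg <- session_config(
    experiment = y$experiment %||% "plr", schedule = sched, kinetics = kin,
    geometry = geo, eyelid = lid, optics = opt, frame_rate_hz = fs,
    blink_rate_hz = y$blink_rate_hz %||% 0.05,
    blink_duration_s = y$blink_duration_s %||% 0.2,
    blink_gain = y$blink_gain %||% 0.3,
    dwell_s = y$dwell_s %||% 5, baseline_s = y$baseline_s %||% 15,
    repeats = y$repeats %||% 2, padding_s = y$padding_s %||% 10
  )
  list(config = cfg, seed = as.integer(y$seed %||% 1L),
       roi_radius_px = y$roi_radius_px %||% 28)
}

#' Write a reproducibility manifest
#'
#' Records the config file hash, seed and package version next to a run's
#' outputs.
#'
#' @param dir output directory.
#' @param config_path path of the YAML config used (hashed), or NA.
#' @param seed seed used.
#' @return invisible manifest path.
#' @export
write_manifest <- function(dir, config_path = NA, seed = NA) {
  manifest <- list(
    package = "swirpupil",
    version = as.character(utils::packageVersion("swirpupil")),
    config_md5 = if (is.na(config_path)) NA else unname(tools::md5sum(config_path)),
    seed = seed
  )
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  invisible(p)
}

# ---- command-line interface ---------------------------------------------

cli_parse <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3)]] <- if (i < length(args) && !startsWith(args[i + 1], "--")) {
        i <- i + 1; args[i]
      } else TRUE
    }
    i <- i + 1
  }
  opts
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `analyze-plr`, `analyze-gaze`, `train-unet`
#' and `report` commands used by the `inst/cli/swirpupil.R` script. Each
#' command reads/writes one session directory and leaves a manifest.
#'
#' @param args character vector of command-line arguments,
#'   e.g. `c("simulate", "--config", "cfg.yaml", "--out", "sess1")`.
#' @return exit status (0 on success), invisibly.
#' @export
swir_cli <- function(args) {
  if (!length(args)) {
    message("usage: swirpupil <simulate|analyze-plr|analyze-gaze|train-unet|report> [--options]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- cli_parse(args[-1])
  status <- tryCatch({
    switch(
      cmd,
      "simulate" = cli_simulate(opts),
      "analyze-plr" = cli_analyze_plr(opts),
      "analyze-gaze" = cli_analyze_gaze(opts),
      "train-unet" = cli_train_unet(opts),
      "report" = cli_report(opts),
      stopf("unknown command: %s", cmd)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

cli_simulate <- function(opts) {
  if (is.null(opts$config) || is.null(opts$out)) stopf("simulate needs --config and --out")
  rc <- load_run_config(opts$config)
  seed <- as.integer(opts$seed %||% rc$seed)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  sess <- render_session(rc$config, seed)
  write_stack(sess$open, file.path(opts$out, "open.tiff"))
  write_stack(sess$closed, file.path(opts$out, "closed.tiff"))
  write_stack(sess$forehead, file.path(opts$out, "forehead.tiff"))
  write_truth(sess$truth, file.path(opts$out, "truth.csv"))
  file.copy(opts$config, file.path(opts$out, "config.yaml"), overwrite = TRUE)
  write_manifest(opts$out, opts$config, seed)
  invisible(sess)
}

cli_load_session <- function(dir) {
  rc <- load_run_config(file.path(dir, "config.yaml"))
  sess <- list(
    open = read_stack(file.path(dir, "open.tiff")),
    closed = read_stack(file.path(dir, "closed.tiff")),
    forehead = read_stack(file.path(dir, "forehead.tiff")),
    config = rc$config, roi_radius_px = rc$roi_radius_px
  )
  tr <- read_truth(file.path(dir, "truth.csv"))
  truth <- if (rc$config$experiment == "plr") {
    simulate_plr_diameter(rc$config$schedule, rc$config$kinetics, rc$config$frame_rate_hz)
  } else {
    simulate_gaze_path(rc$config$geometry, rc$config$dwell_s, rc$config$baseline_s,
                       rc$config$repeats, rc$config$frame_rate_hz, rc$config$padding_s,
                       rc$config$kinetics$baseline_diameter_mm)
  }
  truth$blink_mask <- tr$blink == 1
  sess$truth <- truth
  sess
}

cli_analyze_plr <- function(opts) {
  if (is.null(opts$dir)) stopf("analyze-plr needs --dir (a simulated session directory)")
  sess <- cli_load_session(opts$dir)
  res <- analyze_plr_session(sess, roi_radius_px = sess$roi_radius_px)
  write.csv(res$summary, file.path(opts$dir, "plr_summary.csv"), row.names = FALSE)
  jsonlite::write_json(res[c("robust", "concordance", "calibration_fit")],
                       file.path(opts$dir, "plr_stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}

cli_analyze_gaze <- function(opts) {
  if (is.null(opts$dir)) stopf("analyze-gaze needs --dir")
  sess <- cli_load_session(opts$dir)
  n_shuffles <- as.integer(opts[["shuffles"]] %||% 10000)
  res <- analyze_gaze_session(sess, n_shuffles = n_shuffles,
                              seed = as.integer(opts$seed %||% 1L))
  gz <- data.frame(t_s = sess$truth$t_s[res$frames_used],
                   open_x_dva = res$dva_open[res$frames_used, 1],
                   open_y_dva = res$dva_open[res$frames_used, 2],
                   closed_x_dva = res$dva_closed[res$frames_used, 1],
                   closed_y_dva = res$dva_closed[res$frames_used, 2])
  write.csv(gz, file.path(opts$dir, "gaze_dva.csv"), row.names = FALSE)
  jsonlite::write_json(list(calibration = res$calibration,
                            mae_mm = as.list(res$mae_mm),
                            mae_dva = as.list(res$mae_dva),
                            surrogate_p = res$surrogate$p),
                       file.path(opts$dir, "gaze_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("MAE x: %.3f mm (%.2f dva)  MAE y: %.3f mm (%.2f dva)  surrogate p = %.2g\n",
              res$mae_mm[1], res$mae_dva[1], res$mae_mm[2], res$mae_dva[2],
              res$surrogate$p))
  invisible(res)
}

cli_train_unet <- function(opts) {
  if (is.null(opts$dir)) stopf("train-unet needs --dir")
  sess <- cli_load_session(opts$dir)
  cfg <- unet_config(
    max_epochs = as.integer(opts[["epochs"]] %||% 200),
    patience_epochs = as.integer(opts[["patience"]] %||% 20),
    channels = as.integer(strsplit(opts[["channels"]] %||% "16,32,64", ",")[[1]]),
    seed = as.integer(opts$seed %||% 1L),
    train_stride = as.integer(opts[["train-stride"]] %||% 1),
    val_stride = as.integer(opts[["val-stride"]] %||% 1)
  )
  res <- unet_session_experiment(sess, cfg)
  jsonlite::write_json(
    list(mae_closed = res$mae_closed, mae_forehead = res$mae_forehead,
         split = res$split, epochs_closed = res$models$closed$epochs_run,
         epochs_forehead = res$models$forehead$epochs_run),
    file.path(opts$dir, "unet_stats.json"), auto_unbox = TRUE, digits = NA
  )
  cat(sprintf("diameter MAE closed-eye model: %.3f mm; forehead model: %.3f mm\n",
              res$mae_closed, res$mae_forehead))
  invisible(res)
}

cli_report <- function(opts) {
  if (is.null(opts$dir)) stopf("report needs --dir")
  files <- c("plr_stats.json", "gaze_stats.json", "unet_stats.json")
  out <- list()
  for (f in files) {
    p <- file.path(opts$dir, f)
    if (file.exists(p)) out[[sub(".json$", "", f)]] <- jsonlite::read_json(p, simplifyVector = TRUE)
  }
  if (!length(out)) stopf("no analysis outputs found in %s; run an analyze command first", opts$dir)
  txt <- jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(txt, file.path(opts$dir, "report.json"))
  cat(txt, "\n")
  invisible(out)
}
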