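# Configuration schema: known blocks and keys. Unknown keys are rejected
# so typos fail loudly rather than silently falling back to defaults.
config_schema <- function() {
  list(
    arena = c("wall_width", "wall_height", "panel_px_w", "panel_px_h",
              "viewer_xy", "viewer_eye_height", "n_walls"),
    stimulus = c("spatial_freq", "contrast_level", "channel", "speed",
                 "direction", "duration", "fps", "max_angle", "start_angle",
                 "fg", "bg", "centre_azimuth", "centre_elevation",
                 "all_panels"),
    analysis = c("v_min", "v_slow_max", "v_saccade_min", "smooth_window",
                 "max_saccade_duration", "f_min", "n_min",
                 "drop_isolated_saccades", "n_markers", "min_area",
                 "max_jump", "gap_limit", "sample_rate"),
    staircase = c("start", "step_mode", "step_factor", "step", "resolution",
                  "min_contrast", "sentinel", "max_trials", "n_repeats"),
    simulation = c("peak_freq", "peak_threshold", "bandwidth", "slope",
                   "guess", "lapse", "polarization_threshold",
                   "loom_response", "n_subjects", "gain", "noise_sd",
                   "saccade_amplitude", "trace_duration"),
    seed = NULL,
    output = c("dir")
  )
}

#' Default run configuration
#'
#' All lengths in cm, all angles in degrees, resolutions in px.
#'
#' @return A nested list of class `run_config` with `arena`, `stimulus`,
#'   `analysis`, `staircase`, `simulation`, `seed` and `output` blocks.
#' @export
default_config <- function() {
  structure(
    list(
      arena = list(wall_width = 38.5, wall_height = 30.0,
                   panel_px_w = 192L, panel_px_h = 148L,
                   viewer_xy = c(0, 0), viewer_eye_height = 15.0,
                   n_walls = 4L),
      stimulus = list(spatial_freq = 0.05, contrast_level = 1,
                      channel = "intensity", speed = 6, direction = "ccw",
                      duration = 5, fps = 30, max_angle = 34.5,
                      start_angle = 0.5, fg = 255, bg = 0,
                      centre_azimuth = 0, centre_elevation = 0,
                      all_panels = FALSE),
      analysis = list(v_min = 1, v_slow_max = NA, v_saccade_min = 30,
                      smooth_window = 0.2, max_saccade_duration = 0.5,
                      f_min = 0.3, n_min = 2L,
                      drop_isolated_saccades = FALSE, n_markers = 2L,
                      min_area = 4L, max_jump = 20, gap_limit = 5L,
                      sample_rate = 25),
      staircase = list(start = 1, step_mode = "multiplicative",
                       step_factor = 0.5, step = 0.1, resolution = 0.01,
                       min_contrast = 0.01, sentinel = 1.2,
                       max_trials = 50L, n_repeats = 1L),
      simulation = list(peak_freq = 0.07, peak_threshold = 0.11,
                        bandwidth = 0.8, slope = 20, guess = 0, lapse = 0,
                        polarization_threshold = Inf, loom_response = TRUE,
                        n_subjects = 9L, gain = 1, noise_sd = 0,
                        saccade_amplitude = 10, trace_duration = 30),
      seed = 1L,
      output = list(dir = ".")
    ),
    class = "run_config"
  )
}

validate_config <- function(cfg) {
  schema <- config_schema()
  unknown_top <- setdiff(names(cfg), names(schema))
  if (length(unknown_top))
    stop_polardrum(sprintf("unknown config key: `%s`", unknown_top[1]),
                   "schema_error")
  for (block in intersect(names(cfg), names(schema))) {
    keys <- schema[[block]]
    if (is.null(keys)) next
    unknown <- setdiff(names(cfg[[block]]), keys)
    if (length(unknown))
      stop_polardrum(sprintf("unknown config key: `%s$%s`", block, unknown[1]),
                     "schema_error")
  }
  st <- cfg$stimulus
  if (!is.null(st$contrast_level) &&
      (st$contrast_level < 0 || st$contrast_level > 1))
    stop_polardrum("config field `stimulus$contrast_level` must lie in [0, 1]",
                   "schema_error")
  if (!is.null(st$spatial_freq) && st$spatial_freq <= 0)
    stop_polardrum("config field `stimulus$spatial_freq` must be > 0",
                   "schema_error")
  if (!is.null(cfg$arena$wall_width) && cfg$arena$wall_width <= 0)
    stop_polardrum("config field `arena$wall_width` must be > 0",
                   "schema_error")
  if (!is.null(cfg$staircase$resolution) && cfg$staircase$resolution <= 0)
    stop_polardrum("config field `staircase$resolution` must be > 0",
                   "schema_error")
  invisible(cfg)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- utils::modifyList(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, validates it against the schema
#' (unknown keys are rejected, naming the offending key), and fills every
#' unspecified field with its documented default. The source path and its
#' MD5 hash are attached for provenance.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_polardrum(sprintf("config file not found: %s", path), "io_error")
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(user)
  cfg <- merge_config(unclass(default_config()), user)
  cfg <- structure(cfg, class = "run_config")
  validate_config(cfg)
  attr(cfg, "source") <- path
  attr(cfg, "hash") <- unname(tools::md5sum(path))
  cfg
}

#' Save a configuration to YAML
#'
#' @param cfg A `run_config` list.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write analysis results plus a run manifest
#'
#' Writes the tabular content of a result object to CSV and a
#' `manifest.json` recording the seed, config hash and package version, so
#' a run can be reproduced exactly. Outputs are byte-identical across
#' reruns with the same inputs (no timestamps).
#'
#' @param results A `csf_curve`, `nystagmus_seg`, `staircase_result`,
#'   data frame, or a named list of these.
#' @param dir Output directory (created if needed).
#' @param seed Seed used for the run, recorded in the manifest.
#' @param config Optional `run_config`; its hash is recorded.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(results, dir, seed = NULL, config = NULL) {
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir))
    stop_polardrum(sprintf("cannot create output directory: %s", dir), "io_error")
  paths <- character()
  write_one <- function(obj, stem) {
    if (inherits(obj, "csf_curve")) {
      p1 <- file.path(dir, paste0(stem, ".csv"))
      p2 <- file.path(dir, paste0(stem, "_summary.csv"))
      readr::write_csv(obj$individual, p1)
      readr::write_csv(obj$summary, p2)
      c(p1, p2)
    } else if (inherits(obj, "nystagmus_seg")) {
      p1 <- file.path(dir, paste0(stem, "_intervals.json"))
      jsonlite::write_json(obj$intervals, p1, digits = NA)
      p1
    } else if (inherits(obj, "staircase_result")) {
      p1 <- file.path(dir, paste0(stem, "_trials.csv"))
      readr::write_csv(obj$trials, p1)
      p1
    } else if (is.data.frame(obj)) {
      if (nrow(obj) == 0L)
        warning(sprintf("result `%s` is empty; writing header-only CSV", stem))
      p1 <- file.path(dir, paste0(stem, ".csv"))
      readr::write_csv(obj, p1)
      p1
    } else {
      stop_polardrum(sprintf("don't know how to report a <%s>", class(obj)[1]),
                     "io_error")
    }
  }
  if (is.list(results) && !is.data.frame(results) &&
      !inherits(results, c("csf_curve", "nystagmus_seg", "staircase_result"))) {
    if (is.null(names(results)))
      stop_polardrum("a list of results must be named", "io_error")
    for (nm in names(results)) paths <- c(paths, write_one(results[[nm]], nm))
  } else {
    paths <- c(paths, write_one(results, "results"))
  }
  manifest <- list(
    seed = seed,
    config_hash = if (!is.null(config)) attr(config, "hash") else NULL,
    package = "polardrum",
    version = as.character(utils::packageVersion("polardrum")),
    files = basename(paths)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mpath))
}

#' Write rendered frames as paired PNG sequences
#'
#' One 8-bit PNG per panel, channel and frame
#' (`panel{N}_{int|pol}_{frame:05d}.png`) plus a JSON sidecar with the
#' stimulus spec, geometry and frame timestamps.
#'
#' @param frames A `drum_frames` object.
#' @param dir Output directory.
#' @return Written file paths, invisibly.
#' @export
write_frames <- function(frames, dir) {
  stopifnot(inherits(frames, "drum_frames"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tag <- c(intensity = "int", polarization = "pol")
  for (i in seq_along(frames$frames)) {
    for (k in 1:4) {
      for (ch in c("intensity", "polarization")) {
        p <- file.path(dir, sprintf("panel%d_%s_%05d.png", k - 1, tag[[ch]], i))
        png::writePNG(frames$frames[[i]][[k]][[ch]] / 255, p)
        paths <- c(paths, p)
      }
    }
  }
  sidecar <- file.path(dir, "frames.json")
  jsonlite::write_json(
    list(spec = unclass(frames$spec), spec_class = class(frames$spec)[1],
         geometry = unclass(frames$geom), times = frames$times),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(paths, sidecar))
}

#' Read an image sequence directory as grayscale matrices
#'
#' @param dir Directory of PNG or TIFF frames (sorted by filename), or a
#'   multi-page TIFF file.
#' @param pattern Filename filter for the directory form.
#' @return A list of numeric matrices.
#' @export
read_image_sequence <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  to_gray <- function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  }
  if (file.exists(dir) && !dir.exists(dir)) {
    return(lapply(tiff::readTIFF(dir, all = TRUE), to_gray))
  }
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L)
    stop_polardrum(sprintf("no image frames found in %s", dir), "io_error")
  lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) to_gray(png::readPNG(f))
    else to_gray(tiff::readTIFF(f))
  })
}
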